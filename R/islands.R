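# --- oriented coordinate helpers --------------------------------------------
# Genomic islands integrate at tRNA genes: the intact gene stays at one end
# and a short copy of its 3'-terminal bases closes the island at the other.
# All scanning below runs in "oriented" space: offset 1 is the first base
# downstream of the tRNA 3' end along the tRNA's coding strand.

circ_substr <- function(seq, start, len) {
  L <- nchar(seq)
  start <- as.integer(wrap_pos(start, L))
  if (start + len - 1L <= L) return(substr(seq, start, start + len - 1L))
  paste0(substr(seq, start, L), substr(seq, 1L, start + len - 1L - L))
}

trna_3prime_end <- function(feat_row) {
  if (identical(feat_row$strand, "-")) feat_row$start else feat_row$end
}

oriented_coord <- function(anchor3, strand, offset, L) {
  if (identical(strand, "-")) as.integer(wrap_pos(anchor3 - offset, L))
  else as.integer(wrap_pos(anchor3 + offset, L))
}

# Downstream sequence (3' of the tRNA on its coding strand), length `len`.
oriented_window_seq <- function(genome, anchor3, strand, len) {
  L <- genome$length
  len <- min(len, L - 1L)
  if (identical(strand, "-")) {
    s <- circ_substr(genome$sequence, anchor3 - len, len)
    revcomp(s)
  } else {
    circ_substr(genome$sequence, anchor3 + 1L, len)
  }
}

# Interval covered by oriented offsets [o1, o2] (o1 <= o2).
oriented_interval <- function(anchor3, strand, o1, o2, L) {
  a <- oriented_coord(anchor3, strand, o1, L)
  b <- oriented_coord(anchor3, strand, o2, L)
  lo <- min(a, b); hi <- max(a, b)
  len <- o2 - o1 + 1L
  if (hi - lo + 1L == len) circular_interval(lo, hi, wraps = FALSE)
  else circular_interval(hi, lo, wraps = TRUE)
}

# --- typical tRNA-anchored islands -------------------------------------------

#' Detect tRNA-anchored genomic islands by 3'-terminal duplications
#'
#' For each tRNA gene, scans downstream (the 3' direction of the tRNA on
#' its coding strand) for exact occurrences of suffixes of the tRNA gene
#' sequence of at least `min_dup` bp on the same strand.  Each successive
#' duplication closes one island: island 1 runs from the base after the
#' intact tRNA 3' end to the last base of the first duplication, island 2
#' from the base after that to the next duplication, and so on (nested
#' islands at integration hotspots).  At each duplication site the longest
#' matching suffix is reported.  Islands with GC at or above the genome
#' mean are dropped when the GC filter is on, reflecting the atypical
#' (lower) base composition of horizontally acquired DNA.
#'
#' @param genome an [annotated_genome()] (must carry sequence and tRNA
#'   features with strands).
#' @param min_dup minimum duplication length in bp (default 14, the
#'   smallest duplication observed in finished genomes of this kind).
#' @param max_island maximum island length in bp (default 110000).
#' @param max_stack maximum islands stacked at one anchor (default 4).
#' @param gc_filter drop islands with GC >= genome average (default TRUE).
#' @return data.frame with one row per island: `name`, `anchor_id`,
#'   `anchor_label`, `strand`, `left_end`, `right_end`, `wraps`, `length`,
#'   `gc_pct`, `duplication_length`, `dup_start`, `dup_end`,
#'   `nesting_index`, `integrase_locus`.
#' @export
find_trna_anchored_islands <- function(genome, min_dup = 14L,
                                       max_island = 110000L, max_stack = 4L,
                                       gc_filter = TRUE) {
  stopifnot(inherits(genome, "annotated_genome"))
  trnas <- genome$features[genome$features$kind == "tRNA", , drop = FALSE]
  if (nrow(trnas) == 0L) stop("genome has no tRNA features")
  if (genome$length < 1L || nchar(genome$sequence) == 0L)
    stop("genome carries no sequence; island scanning needs the sequence")
  mean_gc <- gc_fraction(genome)
  L <- genome$length
  cds <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
  integrase_cds <- cds[grepl("integrase|recombinase", cds$product,
                             ignore.case = TRUE), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(trnas))) {
    tr <- trnas[i, ]
    tseq <- feature_seq(genome, tr)
    Lt <- nchar(tseq)
    if (Lt < min_dup) next
    anchor3 <- trna_3prime_end(tr)
    scan_len <- min(as.integer(max_stack) * as.integer(max_island), L - Lt - 1L)
    W <- oriented_window_seq(genome, anchor3, tr$strand, scan_len)
    s0 <- substr(tseq, Lt - min_dup + 1L, Lt)
    occ <- motif_starts_circular_linear(W, s0)
    if (!length(occ)) next
    prev_end <- 0L
    nesting <- 0L
    for (p in occ) {
      if (p <= prev_end) next
      dup_end <- p + min_dup - 1L
      if (dup_end - prev_end > max_island) break
      if (nesting >= max_stack) break
      # extend the suffix match leftwards (longest matching suffix)
      ext <- 0L
      max_ext <- min(p - 1L - prev_end, Lt - min_dup)
      while (ext < max_ext &&
             substr(W, p - ext - 1L, p - ext - 1L) ==
             substr(tseq, Lt - min_dup - ext, Lt - min_dup - ext))
        ext <- ext + 1L
      dup_len <- min_dup + ext
      nesting <- nesting + 1L
      ivl <- oriented_interval(anchor3, tr$strand, prev_end + 1L, dup_end, L)
      dup_ivl <- oriented_interval(anchor3, tr$strand, p - ext, dup_end, L)
      gc <- gc_fraction(genome, ivl)
      integ <- NA_character_
      if (nrow(integrase_cds)) {
        mid <- vapply(seq_len(nrow(integrase_cds)), function(j)
          interval_midpoint(feature_interval(integrase_cds[j, ]), L), integer(1))
        inside <- vapply(mid, function(p0) interval_contains(ivl, p0), logical(1))
        if (any(inside)) integ <- integrase_cds$feature_id[which(inside)[1]]
      }
      out[[length(out) + 1L]] <- data.frame(
        anchor_id = tr$feature_id,
        anchor_label = tr$product %||% NA_character_,
        strand = tr$strand,
        left_end = ivl$start, right_end = ivl$end, wraps = ivl$wraps,
        length = interval_length(ivl, L), gc_pct = gc,
        duplication_length = dup_len,
        dup_start = dup_ivl$start, dup_end = dup_ivl$end,
        nesting_index = nesting,
        integrase_locus = integ, stringsAsFactors = FALSE)
      prev_end <- dup_end
    }
  }
  if (!length(out)) return(empty_islands())
  res <- do.call(rbind, out)
  if (gc_filter) res <- res[res$gc_pct < mean_gc, , drop = FALSE]
  if (!nrow(res)) return(empty_islands())
  res <- res[order(res$left_end), , drop = FALSE]
  res <- cbind(name = sprintf("GI%02d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

empty_islands <- function() {
  data.frame(name = character(), anchor_id = character(),
             anchor_label = character(), strand = character(),
             left_end = integer(), right_end = integer(), wraps = logical(),
             length = integer(), gc_pct = numeric(),
             duplication_length = integer(), dup_start = integer(),
             dup_end = integer(), nesting_index = integer(),
             integrase_locus = character(), stringsAsFactors = FALSE)
}

# Exact motif starts in a linear string (no wrapping).
motif_starts_circular_linear <- function(seq, motif) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                   Biostrings::DNAString(seq), fixed = TRUE)
  as.integer(BiocGenerics::start(hits))
}

# --- duplication-free low-GC candidates --------------------------------------

# Grow a run of low-GC windows downstream of an oriented anchor point.
# Returns the grown length in bp (a multiple of `window`, possibly 0).
grow_low_gc <- function(genome, anchor3, strand, threshold, window = 5000L,
                        max_len = NULL) {
  L <- genome$length
  if (is.null(max_len)) max_len <- L %/% 2L
  total <- 0L
  while (total + window <= max_len) {
    a <- oriented_coord(anchor3, strand, total + 1L, L)
    chunk <- if (identical(strand, "-")) circ_substr(genome$sequence, a - window + 1L, window)
             else circ_substr(genome$sequence, a, window)
    gc <- gc_fraction(chunk)
    if (is.na(gc) || gc >= threshold) break
    total <- total + window
  }
  total
}

#' Nominate duplication-free low-GC candidate islands at tRNA genes
#'
#' Some islands have lost (or never had) the terminal duplication; they are
#' still recognisable as segments of depressed GC content adjacent to a
#' tRNA gene.  For each tRNA with no duplication-delimited island, grows a
#' run of consecutive windows downstream of the 3' end whose GC stays below
#' `genome mean - gc_margin`, and reports runs of at least `min_len` bp.
#'
#' @param genome an [annotated_genome()].
#' @param gc_margin GC depression in percentage points (default 2: clear of per-window GC noise at the default window).
#' @param min_len minimum candidate length in bp (default 10000).
#' @param window growth window in bp (default 5000).
#' @return data.frame: `anchor_id`, `anchor_label`, `strand`, `start`,
#'   `end`, `wraps`, `length`, `gc_pct`, `evidence`.
#' @export
find_candidate_low_gc_islands <- function(genome, gc_margin = 2, min_len = 10000L,
                                          window = 5000L) {
  mean_gc <- gc_fraction(genome)
  threshold <- mean_gc - gc_margin
  typical <- find_trna_anchored_islands(genome, gc_filter = FALSE)
  anchored <- unique(typical$anchor_id)
  trnas <- genome$features[genome$features$kind == "tRNA", , drop = FALSE]
  L <- genome$length
  out <- list()
  for (i in seq_len(nrow(trnas))) {
    tr <- trnas[i, ]
    if (tr$feature_id %in% anchored) next  # a typical island, not a candidate
    anchor3 <- trna_3prime_end(tr)
    grown <- grow_low_gc(genome, anchor3, tr$strand, threshold, window)
    if (grown < min_len) next
    ivl <- oriented_interval(anchor3, tr$strand, 1L, grown, L)
    out[[length(out) + 1L]] <- data.frame(
      anchor_id = tr$feature_id, anchor_label = tr$product %||% NA_character_,
      strand = tr$strand, start = ivl$start, end = ivl$end, wraps = ivl$wraps,
      length = interval_length(ivl, L), gc_pct = gc_fraction(genome, ivl),
      evidence = "low_gc_only", stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(anchor_id = character(), anchor_label = character(),
                      strand = character(), start = integer(), end = integer(),
                      wraps = logical(), length = integer(), gc_pct = numeric(),
                      evidence = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# --- distal partial tRNA copies ----------------------------------------------

#' Find distal partial copies of a tRNA 3'-terminal portion
#'
#' Genome-wide exact search (both strands) for copies of the last
#' `min_len` bases of a tRNA gene, extended to the longest matching suffix.
#' Hits extending to the full gene length (the intact gene and any
#' identical full copies) are excluded.  Minus-strand hits are reported
#' with descending coordinates (`start > end`), the convention used for
#' such relics in genome tables.
#'
#' @param genome an [annotated_genome()].
#' @param trna_seq the tRNA gene sequence on its coding strand.
#' @param min_len minimum copy length in bp (default 45).
#' @return data.frame: `start`, `end` (descending for minus strand),
#'   `strand`, `length`.
#' @export
find_partial_trna_copies <- function(genome, trna_seq, min_len = 45L) {
  trna_seq <- toupper(trna_seq)
  Lt <- nchar(trna_seq)
  if (Lt <= min_len) stop("trna_seq must be longer than min_len")
  suffix <- substr(trna_seq, Lt - min_len + 1L, Lt)
  L <- genome$length
  seq <- genome$sequence
  hits <- list()
  scan <- function(strand) {
    target <- if (strand == "+") suffix else revcomp(suffix)
    occ <- motif_starts_circular(seq, target)
    for (p in occ) {
      # measure the full suffix-match length around this occurrence
      if (strand == "+") {
        ext <- 0L
        while (ext < Lt - min_len) {
          g <- as.integer(wrap_pos(p - 1L - ext, L))
          if (substr(seq, g, g) != substr(trna_seq, Lt - min_len - ext, Lt - min_len - ext)) break
          ext <- ext + 1L
        }
        len <- min_len + ext
        if (len >= Lt) next  # intact gene (or a full identical copy)
        s <- as.integer(wrap_pos(p - ext, L))
        e <- as.integer(wrap_pos(p + min_len - 1L, L))
        hits[[length(hits) + 1L]] <<- data.frame(start = s, end = e,
                                                 strand = "+", length = len)
      } else {
        # occurrence of revcomp(suffix) at p..p+min_len-1: the copy's 3' end
        # is at genome position p (descending convention)
        ext <- 0L
        while (ext < Lt - min_len) {
          g <- as.integer(wrap_pos(p + min_len + ext, L))
          want <- revcomp(substr(trna_seq, Lt - min_len - ext, Lt - min_len - ext))
          if (substr(seq, g, g) != want) break
          ext <- ext + 1L
        }
        len <- min_len + ext
        if (len >= Lt) next
        s <- as.integer(wrap_pos(p + min_len - 1L + ext, L))
        e <- as.integer(wrap_pos(p, L))
        hits[[length(hits) + 1L]] <<- data.frame(start = s, end = e,
                                                 strand = "-", length = len)
      }
    }
  }
  scan("+"); scan("-")
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length = integer()))
  res <- do.call(rbind, hits)
  res <- res[order(pmin(res$start, res$end)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- split symbiosis island reconstruction -----------------------------------

#' Reconstruct a split symbiosis island
#'
#' Assembles the three-fragment picture of an ancestral symbiosis island
#' that was split by large-scale rearrangement: fragment A is the low-GC
#' region abutting the intact anchor tRNA (trnV) 3' end; fragment B is the
#' low-GC region adjacent to a distal partial copy of the trnV 3' terminus
#' (with a neighbouring integrase when annotated); fragment C is a
#' remaining region jointly flagged by insertion-sequence density and
#' overlap with a cluster of near-identical ("tier 1") genes.  Each
#' fragment must satisfy at least two of {low GC, IS density, tier-1
#' overlap}; fragments failing that are dropped with an explicit evidence
#' report.
#'
#' @param genome an [annotated_genome()].
#' @param islands_evidence typical islands from
#'   [find_trna_anchored_islands()] (used to avoid re-claiming them).
#' @param is_copies IS copies from [map_is_copies()].
#' @param tier1_loci loci from [cluster_tier1_loci()] (may have zero rows).
#' @param trnv_locus locus tag of the intact anchor tRNA-Val gene.
#' @param gc_margin GC depression in percentage points (default 2).
#' @param window growth window in bp (default 5000).
#' @param is_density_min minimum IS copies per 100 kb for the IS-density
#'   evidence flag (default 5).
#' @param partial_min_len minimum partial-copy length (default 45).
#' @return An object of class `symbiosis_island_set`: list with
#'   `fragments` (data.frame: name, start, end, wraps, length, gc_pct,
#'   is_count, tier1_overlap, evidence_n, kept), `anchor` (locus tag),
#'   `partial_trnv_hits`, `total_kb` (kept fragments), `complete`.
#' @export
assemble_symbiosis_islands <- function(genome, islands_evidence, is_copies,
                                       tier1_loci, trnv_locus,
                                       gc_margin = 2, window = 5000L,
                                       is_density_min = 5, partial_min_len = 45L) {
  f <- genome$features
  if (!trnv_locus %in% f$feature_id)
    stop("anchor tRNA locus ", trnv_locus, " not found in ", genome$id)
  tr <- f[f$feature_id == trnv_locus, ][1, ]
  L <- genome$length
  mean_gc <- gc_fraction(genome)
  threshold <- mean_gc - gc_margin
  tseq <- feature_seq(genome, tr)

  frag <- list()
  add_frag <- function(name, ivl) {
    if (is.null(ivl)) return(invisible(NULL))
    len <- interval_length(ivl, L)
    mids <- if (nrow(is_copies)) vapply(seq_len(nrow(is_copies)), function(i)
      interval_midpoint(circular_interval(is_copies$start[i], is_copies$end[i]),
                        L), integer(1)) else integer()
    is_count <- sum(vapply(mids, function(p) interval_contains(ivl, p), logical(1)))
    t1 <- FALSE
    if (!is.null(tier1_loci) && nrow(tier1_loci)) {
      t1 <- any(vapply(seq_len(nrow(tier1_loci)), function(i) {
        liv <- circular_interval(tier1_loci$start[i], tier1_loci$end[i],
                                 isTRUE(tier1_loci$wraps[i]))
        intervals_overlap(ivl, liv, L)
      }, logical(1)))
    }
    gc <- gc_fraction(genome, ivl)
    ev <- c(low_gc = gc < threshold + gc_margin,  # below genome mean
            is_density = is_count / len * 1e5 >= is_density_min,
            tier1_overlap = t1)
    frag[[name]] <<- data.frame(name = name, start = ivl$start, end = ivl$end,
                                wraps = ivl$wraps, length = len,
                                gc_pct = gc, is_count = is_count,
                                tier1_overlap = t1, evidence_n = sum(ev),
                                kept = sum(ev) >= 2L, stringsAsFactors = FALSE)
  }

  # fragment A: low-GC run from the intact trnV 3' end
  anchor3 <- trna_3prime_end(tr)
  grownA <- grow_low_gc(genome, anchor3, tr$strand, threshold, window)
  if (grownA >= window)
    add_frag("A", oriented_interval(anchor3, tr$strand, 1L, grownA, L))

  # fragment B: low-GC run next to a distal partial trnV copy
  partials <- find_partial_trna_copies(genome, tseq, partial_min_len)
  if (nrow(partials)) {
    ph <- partials[1, ]
    # the copy plays the role of a terminal duplication: the fragment lies on
    # the side of the copy corresponding to "upstream" of the 3' terminus
    p_anchor <- ph$start  # 3'-most base of the copy in descending convention
    p_strand <- ph$strand
    # try the direction away from the copy's 3' end first, then the other
    dirs <- if (p_strand == "-") c("+", "-") else c("-", "+")
    grown <- 0L; ivlB <- NULL
    for (d in dirs) {
      g <- grow_low_gc(genome, p_anchor, d, threshold, window)
      if (g > grown) {
        grown <- g
        ivlB <- oriented_interval(p_anchor, d, 1L, g, L)
      }
    }
    if (grown >= window) add_frag("B", ivlB)
  }

  # fragment C: densest remaining IS cluster, grown to its low-GC extent
  usedA <- frag[["A"]]; usedB <- frag[["B"]]
  in_used <- function(p) {
    (!is.null(usedA) && interval_contains(circular_interval(usedA$start, usedA$end, usedA$wraps), p)) ||
    (!is.null(usedB) && interval_contains(circular_interval(usedB$start, usedB$end, usedB$wraps), p))
  }
  if (nrow(is_copies)) {
    mids <- vapply(seq_len(nrow(is_copies)), function(i)
      interval_midpoint(circular_interval(is_copies$start[i], is_copies$end[i]), L),
      integer(1))
    free <- sort(mids[!vapply(mids, in_used, logical(1))])
    if (length(free)) {
      gaps <- diff(free)
      cl <- cumsum(c(TRUE, gaps > 20000L))
      sizes <- table(cl)
      bigcl <- as.integer(names(sizes)[which.max(sizes)])
      seedp <- free[cl == bigcl][1]
      # grow in both directions from the cluster's first copy
      gR <- grow_low_gc(genome, seedp - 1L, "+", threshold, window)
      gL <- grow_low_gc(genome, seedp, "-", threshold, window)
      if (gR + gL >= window) {
        s <- oriented_coord(seedp, "-", gL, L)
        e <- oriented_coord(seedp - 1L, "+", gR, L)
        ivlC <- if ((e - s + 1L) == gL + gR && e >= s)
          circular_interval(s, e) else circular_interval(s, e, wraps = TRUE)
        add_frag("C", ivlC)
      }
    }
  }

  fragments <- if (length(frag)) do.call(rbind, frag) else
    data.frame(name = character(), start = integer(), end = integer(),
               wraps = logical(), length = integer(), gc_pct = numeric(),
               is_count = integer(), tier1_overlap = logical(),
               evidence_n = integer(), kept = logical())
  rownames(fragments) <- NULL
  kept <- fragments[fragments$kept, , drop = FALSE]
  structure(list(fragments = fragments, anchor = trnv_locus,
                 partial_trnv_hits = partials,
                 total_kb = round_half_up(sum(kept$length) / 1000),
                 complete = nrow(kept) >= 3L),
            class = "symbiosis_island_set")
}

intervals_overlap <- function(a, b, L) {
  pts <- c(a$start, interval_midpoint(a, L), a$end)
  any(vapply(pts, function(p) interval_contains(b, p), logical(1))) ||
    any(vapply(c(b$start, b$end), function(p) interval_contains(a, p), logical(1)))
}

#' @export
print.symbiosis_island_set <- function(x, ...) {
  cat(sprintf("<symbiosis_island_set> anchor %s: %d fragment(s), %d kept, total %s kb%s\n",
              x$anchor, nrow(x$fragments), sum(x$fragments$kept), x$total_kb,
              if (x$complete) "" else " [incomplete: evidence report in $fragments]"))
  if (nrow(x$fragments)) print.data.frame(x$fragments, ...)
  invisible(x)
}
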