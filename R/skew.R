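#' GC-skew profile of a circular genome
#'
#' Computes per-window GC skew (G-C)/(G+C) along the chromosome, with
#' windows wrapping the circle, plus the cumulative sum of per-step-chunk
#' (G-C) counts used to localise the replication origin and terminus.  The
#' cumulative track is computed over disjoint step-sized chunks so its final
#' value equals the genome's total G-C.
#'
#' @param genome an [annotated_genome()].
#' @param window window size in bp (default 10000, the conventional choice
#'   for Mb-scale chromosomes).
#' @param step step between window starts; default `window/10`.
#' @return An object of class `skew_profile`: list with `window`, `step`,
#'   `values` (data.frame `midpoint`, `skew`), `cumulative` (data.frame
#'   `position`, `cum_gc`), `genome_length`.
#' @export
gc_skew_profile <- function(genome, window = 10000L, step = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (is.null(step)) step <- max(1L, as.integer(window / 10))
  window <- as.integer(window); step <- as.integer(step)
  if (window > genome$length) stop("window larger than genome")
  if (!(window >= step && step >= 1L)) stop("need window >= step >= 1")
  L <- genome$length
  v <- charToRaw(genome$sequence)
  isG <- as.integer(v == charToRaw("G"))
  isC <- as.integer(v == charToRaw("C"))
  n_win <- as.integer(ceiling(L / step))
  starts <- 1L + (seq_len(n_win) - 1L) * step
  # windowed counts on the circle via cumulative sums of the doubled tracks
  cg <- cumsum(c(isG, isG))
  cc <- cumsum(c(isC, isC))
  wg <- cg[starts + window - 1L] - c(0, cg)[starts]
  wc <- cc[starts + window - 1L] - c(0, cc)[starts]
  tot <- wg + wc
  skew <- ifelse(tot == 0, 0, (wg - wc) / tot)
  mid <- as.integer(wrap_pos(starts + window %/% 2L, L))
  # disjoint chunks for the cumulative track (last chunk truncated at L)
  chunk_ends <- pmin(starts + step - 1L, L)
  dg <- cg[chunk_ends] - c(0, cg)[starts]
  dc <- cc[chunk_ends] - c(0, cc)[starts]
  structure(list(window = window, step = step,
                 values = data.frame(midpoint = mid, skew = skew),
                 cumulative = data.frame(position = chunk_ends,
                                         cum_gc = cumsum(dg - dc)),
                 genome_length = L),
            class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf("<skew_profile> window %d bp, step %d bp, %d windows; final cumulative G-C = %d\n",
              x$window, x$step, nrow(x$values),
              tail(x$cumulative$cum_gc, 1)))
  invisible(x)
}

#' Locate replication origin and terminus candidates from GC skew
#'
#' The origin candidate is the position of the global minimum of the
#' cumulative GC-skew track (the point where the leading-strand G excess
#' begins to accumulate); the terminus candidate is the global maximum.
#' Extrema ties break to the smallest coordinate.  A flat profile yields an
#' explicit "no shift detected" result.
#'
#' @param profile a [gc_skew_profile()].
#' @return List with `origin`, `terminus` (bp, at the profile's step
#'   resolution; `NA` when undetected) and `detected` (logical).
#' @export
find_skew_shifts <- function(profile) {
  stopifnot(inherits(profile, "skew_profile"))
  cg <- profile$cumulative$cum_gc
  pos <- profile$cumulative$position
  if (max(cg) == min(cg))
    return(list(origin = NA_integer_, terminus = NA_integer_, detected = FALSE))
  list(origin = pos[which.min(cg)],
       terminus = pos[which.max(cg)],
       detected = TRUE)
}

#' Search a genome for a short motif with mismatches
#'
#' Finds all positions on both strands of the circular sequence whose
#' Hamming distance to `motif` is at most `max_mismatches` (used for the
#' 28-bp dif dimer-resolution site near the terminus).  Hits are ranked by
#' distance, then coordinate.
#'
#' @param genome an [annotated_genome()].
#' @param motif the query motif (IUPAC codes allowed).
#' @param max_mismatches maximum Hamming distance (default 4).
#' @return data.frame `start`, `end` (1-based inclusive top-strand
#'   coordinates; `end < start` when the hit wraps the origin), `strand`,
#'   `mismatches`.
#' @export
find_motif <- function(genome, motif, max_mismatches = 4L) {
  stopifnot(inherits(genome, "annotated_genome"))
  motif <- toupper(motif)
  if (grepl("[^ACGTRYSWKMBDHVN]", motif)) stop("motif has non-IUPAC characters: ", motif)
  m <- nchar(motif)
  if (m > genome$length) stop("motif longer than genome")
  L <- genome$length
  doubled <- paste0(genome$sequence, substr(genome$sequence, 1L, m - 1L))
  scan_one <- function(pat, strand) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                     Biostrings::DNAString(doubled),
                                     max.mismatch = max_mismatches, fixed = FALSE)
    st <- BiocGenerics::start(hits)
    keep <- st <= L
    st <- st[keep]
    if (!length(st)) return(NULL)
    mm <- vapply(seq_along(st), function(i) {
      sub <- substr(doubled, st[i], st[i] + m - 1L)
      hamming_iupac(pat, sub)
    }, integer(1))
    data.frame(start = st, end = as.integer(wrap_pos(st + m - 1L, L)),
               strand = strand, mismatches = mm, stringsAsFactors = FALSE)
  }
  res <- rbind(scan_one(motif, "+"), scan_one(revcomp(motif), "-"))
  if (is.null(res) || nrow(res) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  res <- res[order(res$mismatches, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Hamming distance with IUPAC-aware matching on the pattern side.
hamming_iupac <- function(pattern, subject) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  iupac <- Biostrings::IUPAC_CODE_MAP
  ok <- vapply(seq_along(p), function(i) {
    grepl(s[i], iupac[[p[i]]], fixed = TRUE)
  }, logical(1))
  sum(!ok)
}

#' Align the putative origin intergenic region between two genomes
#'
#' Extracts the intergenic region between a pair of anchor genes (the
#' conserved ortholog pair flanking the putative replication origin) in each
#' genome and aligns them locally, reporting percent identity and aligned
#' length.
#'
#' @param genomeA,genomeB [annotated_genome()] objects.
#' @param anchor_gene_pairs list with elements `A = c(left_tag, right_tag)`
#'   and `B = c(left_tag, right_tag)`.
#' @param scheme a [scoring_scheme()]; default nucleotide.
#' @return List with `identity_pct`, `aligned_length`, `intervalA`,
#'   `intervalB`, `alignment` (or `NULL` when nothing aligns).
#' @export
locate_origin_intergenic <- function(genomeA, genomeB, anchor_gene_pairs,
                                     scheme = scoring_scheme("nucleotide")) {
  get_intergenic <- function(genome, tags) {
    f <- genome$features
    for (tg in tags) if (!tg %in% f$feature_id)
      stop("anchor locus ", tg, " absent from ", genome$id)
    r1 <- f[f$feature_id == tags[1], ][1, ]
    r2 <- f[f$feature_id == tags[2], ][1, ]
    lo <- min(r1$end, r2$end) + 1L
    hi <- max(r1$start, r2$start) - 1L
    if (hi < lo) stop("anchors ", tags[1], "/", tags[2], " are adjacent or overlap")
    list(seq = substr(genome$sequence, lo, hi),
         interval = circular_interval(lo, hi))
  }
  a <- get_intergenic(genomeA, anchor_gene_pairs$A)
  b <- get_intergenic(genomeB, anchor_gene_pairs$B)
  hits <- align_local(a$seq, b$seq, scheme)
  if (nrow(hits) == 0L)
    return(list(identity_pct = NA_real_, aligned_length = 0L,
                intervalA = a$interval, intervalB = b$interval, alignment = NULL))
  best <- hits[1, ]
  list(identity_pct = best$identity_pct, aligned_length = best$aligned_length,
       intervalA = a$interval, intervalB = b$interval, alignment = best)
}
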