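# Deterministic synthetic genome pairs with planted, ledgered features.
#
# The generator emits the stated world the pipeline is tested against: a
# circular chromosome with a bidirectional GC-skew structure (origin and
# terminus arcs), a planted 28-bp terminus dif motif, tRNA genes, genomic
# islands delimited by duplicated tRNA 3' portions, IS-family copies, a
# three-fragment split symbiosis island anchored at trnV, and protein-coding
# genes; plus a partner genome diverged at a background per-site rate except
# inside the symbiosis fragments.  Everything planted is recorded with exact
# coordinates in a truth ledger.

#' Specification for a synthetic genome pair
#'
#' Defaults describe a 500-kb chromosome at 63.67% GC with background
#' divergence 0.08 (92% identity partner, matching the modal conservation
#' band of diverged conspecific strains) and symbiosis fragments of
#' 40 kb / 4 kb / 10 kb kept at >= 99% identity.  All planted feature
#' classes can be switched off (`island_plans = list()`,
#' `is_family_plans = NULL`, `symbiosis_plan = NULL`).
#'
#' @param seed RNG seed (all randomness flows from it).
#' @param genome_length chromosome length in bp.
#' @param background_gc background GC percentage.
#' @param skew_boundaries origin/terminus positions as fractions of length.
#' @param skew_bias per-arc G/C probability bias (skew amplitude ~ 2 bias / gc).
#' @param dif_motif 28-mer planted at the terminus.
#' @param trna_plan data.frame `label`, `strand`, `pos_frac` (NULL = default
#'   8-gene catalogue including the trnV-CAC symbiosis anchor).
#' @param trna_length tRNA gene length in bp.
#' @param island_plans list of `list(anchor = <trna row>, islands =
#'   list(list(length, dup, gc, integrase)))`.
#' @param is_family_plans list of `list(name, length, gc)`; NULL disables.
#' @param divergence background per-site substitution rate for the partner.
#' @param island_gc GC percentage of typical island content.
#' @param symbiosis_plan list with `sizes = c(A=,B=,C=)`, `rate` (per-site
#'   substitution rate inside fragments), `gc`, `partial_len`; NULL disables.
#' @param gene_plan list `count`, `min_len`, `max_len` for backbone genes.
#' @param min_dup duplication floor the detector will use (for the
#'   spurious-match sweep).
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       genome_length = 500000L,
                       background_gc = 63.67,
                       skew_boundaries = c(0.07, 0.59),
                       skew_bias = 0.03,
                       dif_motif = "GGTGCGCATAATGTATATTATGTTAAAT",
                       trna_plan = NULL,
                       trna_length = 76L,
                       island_plans = NULL,
                       is_family_plans = NULL,
                       divergence = 0.08,
                       island_gc = 59,
                       symbiosis_plan = NULL,
                       gene_plan = list(count = 60L, min_len = 300L, max_len = 3000L),
                       min_dup = 14L) {
  if (is.null(trna_plan)) trna_plan <- default_trna_plan()
  # NULL selects the default plan; FALSE (or an empty list) disables a class
  if (is.null(island_plans)) island_plans <- default_island_plans()
  if (isFALSE(island_plans)) island_plans <- list()
  if (is.null(is_family_plans)) is_family_plans <- default_is_family_plans()
  if (isFALSE(is_family_plans)) is_family_plans <- NULL
  if (is.null(symbiosis_plan)) symbiosis_plan <- default_symbiosis_plan()
  if (isFALSE(symbiosis_plan)) symbiosis_plan <- NULL
  spec <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
               background_gc = background_gc, skew_boundaries = skew_boundaries,
               skew_bias = skew_bias, dif_motif = toupper(dif_motif),
               trna_plan = trna_plan, trna_length = as.integer(trna_length),
               island_plans = island_plans, is_family_plans = is_family_plans,
               divergence = divergence, island_gc = island_gc,
               symbiosis_plan = symbiosis_plan, gene_plan = gene_plan,
               min_dup = as.integer(min_dup))
  validate_synth_spec(spec)
  structure(spec, class = "synth_spec")
}

default_trna_plan <- function() {
  data.frame(label = c("trnS-GGA", "trnK-CTT", "trnE-CTC", "trnL-CAA",
                       "trnV-CAC", "trnQ-TTG", "trnM-CAT", "trnI-CAT"),
             strand = c("+", "+", "+", "-", "+", "+", "+", "+"),
             pos_frac = c(0.04, 0.12, 0.40, 0.54, 0.70, 0.62, 0.92, 0.48),
             stringsAsFactors = FALSE)
}

default_island_plans <- function() {
  list(list(anchor = 2L, islands = list(list(length = 12000L, dup = 46L, integrase = TRUE),
                                        list(length = 8000L, dup = 45L, integrase = FALSE))),
       list(anchor = 3L, islands = list(list(length = 30000L, dup = 48L, integrase = TRUE))),
       list(anchor = 4L, islands = list(list(length = 5000L, dup = 14L, integrase = FALSE))))
}

default_is_family_plans <- function() {
  list(list(name = "ISSynA", length = 1200L, gc = 59),
       list(name = "ISSynB", length = 1200L, gc = 59))
}

default_symbiosis_plan <- function() {
  list(sizes = c(A = 40000L, B = 4000L, C = 10000L),
       rate = 0.002, gc = 59, partial_len = 45L,
       anchor_label = "trnV-CAC")
}

validate_synth_spec <- function(spec) {
  for (pl in spec$island_plans) {
    if (pl$anchor > nrow(spec$trna_plan)) stop("island plan anchors a missing tRNA")
    for (is_ in pl$islands) {
      if (is_$dup < 1L || is_$dup >= spec$trna_length)
        stop("duplication length must be in [1, tRNA length)")
      if (is_$length <= is_$dup) stop("island shorter than its duplication")
      if (isTRUE(is_$integrase) && is_$length < 1200L)
        stop("integrase annotation needs an island of at least 1200 bp")
    }
  }
  if (!is.null(spec$symbiosis_plan) &&
      !spec$symbiosis_plan$anchor_label %in% spec$trna_plan$label)
    stop("symbiosis anchor label missing from the tRNA plan")
  invisible(spec)
}

# --- sequence sampling -------------------------------------------------------

.bases <- c("A", "C", "G", "T")

rand_seq <- function(n, gc, g_bias = 0) {
  g <- gc / 100
  p <- c((1 - g) / 2, g / 2 - g_bias, g / 2 + g_bias, (1 - g) / 2)
  paste(sample(.bases, n, replace = TRUE, prob = p), collapse = "")
}

# Low-GC content with a per-kb guard: every 1-kb chunk is redrawn until its
# realized GC lies within 1.2 points of the target (and below `guard`), so
# windowed detection sees a uniformly depressed region with sharp boundaries
# and the region-level GC lands within a point of the plan.
guarded_low_gc_seq <- function(n, gc_target, guard) {
  chunks <- character(0)
  left <- n
  while (left > 0L) {
    m <- min(1000L, left)
    repeat {
      s <- rand_seq(m, gc_target)
      gc <- gc_fraction(s)
      if (gc < guard && abs(gc - gc_target) <= 1.2) break
    }
    chunks <- c(chunks, s)
    left <- left - m
  }
  paste(chunks, collapse = "")
}

# --- occupancy registry ------------------------------------------------------

new_registry <- function() new.env(parent = emptyenv())

reg_intervals <- function(reg) {
  if (is.null(reg$tab)) data.frame(start = integer(), end = integer(),
                                   what = character())
  else reg$tab
}

reg_free <- function(reg, s, e) {
  tab <- reg_intervals(reg)
  !any(tab$start <= e & tab$end >= s)
}

reg_claim <- function(reg, s, e, what) {
  if (!reg_free(reg, s, e))
    stop("infeasible packing: ", what, " at [", s, ", ", e,
         "] collides with a planted feature")
  reg$tab <- rbind(reg_intervals(reg),
                   data.frame(start = as.integer(s), end = as.integer(e),
                              what = what, stringsAsFactors = FALSE))
  invisible(NULL)
}

# --- oriented planting -------------------------------------------------------

write_at <- function(seqstr, start, content) {
  substr(seqstr, start, start + nchar(content) - 1L) <- content
  seqstr
}

# Write `content` (given in coding-strand orientation) at oriented offsets
# [o1, o1 + n - 1] downstream of anchor3 along `strand`.  Returns the top
# strand start of the written block and the new sequence.
write_oriented <- function(seqstr, anchor3, strand, o1, content) {
  n <- nchar(content)
  L <- nchar(seqstr)
  if (identical(strand, "-")) {
    s <- as.integer(wrap_pos(anchor3 - (o1 + n - 1L), L))
    top <- revcomp(content)
  } else {
    s <- as.integer(wrap_pos(anchor3 + o1, L))
    top <- content
  }
  if (s + n - 1L > L) stop("infeasible packing: planted feature would wrap the origin")
  list(seq = write_at(seqstr, s, top), start = s, end = s + n - 1L)
}

# --- main generator ----------------------------------------------------------

#' Generate a synthetic annotated genome pair with a truth ledger
#'
#' Builds genome A from the plan in `spec`, then derives genome B by
#' per-site substitution at the background divergence rate, reduced to the
#' symbiosis rate inside symbiosis fragments and suppressed inside planted
#' motifs (tRNAs, duplications, dif, partial tRNA copies).  Substitutions
#' that would create spurious restriction sites or tRNA-suffix matches are
#' reverted.  Output is byte-identical for identical spec + seed.
#'
#' @param spec a [synth_spec()].
#' @return List with `genomeA`, `genomeB` ([annotated_genome()] objects),
#'   `truth` (the planted-feature ledger), `is_families` (list of
#'   [is_family()] objects, possibly empty).
#' @export
generate_pair <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  L <- spec$genome_length
  b1 <- as.integer(round(spec$skew_boundaries[1] * L))
  b2 <- as.integer(round(spec$skew_boundaries[2] * L))
  gc <- spec$background_gc

  # background with two skew arcs: [b1+1, b2] G-rich, the rest C-rich
  arc1 <- rand_seq(b2 - b1, gc, g_bias = spec$skew_bias)
  arc2a <- rand_seq(b1, gc, g_bias = -spec$skew_bias)
  arc2b <- rand_seq(L - b2, gc, g_bias = -spec$skew_bias)
  seq <- paste0(arc2a, arc1, arc2b)
  stopifnot(nchar(seq) == L)

  reg <- new_registry()
  feats <- list()
  genes_truth <- list()
  gc_guard <- gc - 2.5  # per-kb ceiling for planted low-GC content

  # dif at the terminus
  dif_start <- b2 + 1L
  seq <- write_at(seq, dif_start, spec$dif_motif)
  reg_claim(reg, dif_start, dif_start + nchar(spec$dif_motif) - 1L, "dif")
  feats[[length(feats) + 1L]] <- data.frame(
    feature_id = "SYNDIF1", kind = "misc", start = dif_start,
    end = dif_start + nchar(spec$dif_motif) - 1L, wraps = FALSE, strand = "+",
    product = "dif dimer-resolution site", anticodon = NA, translation = NA,
    stringsAsFactors = FALSE)

  # anchor gene pair flanking the origin (conserved intergenic region)
  anchL <- c(b1 - 1000L, b1 - 601L); anchR <- c(b1 + 601L, b1 + 1000L)
  reg_claim(reg, anchL[1], anchL[2], "origin anchor L")
  reg_claim(reg, anchR[1], anchR[2], "origin anchor R")
  feats[[length(feats) + 1L]] <- data.frame(
    feature_id = "SYNANCHL", kind = "CDS", start = anchL[1], end = anchL[2],
    wraps = FALSE, strand = "+", product = "conserved hypothetical protein",
    anticodon = NA, translation = NA, stringsAsFactors = FALSE)
  feats[[length(feats) + 1L]] <- data.frame(
    feature_id = "SYNANCHR", kind = "CDS", start = anchR[1], end = anchR[2],
    wraps = FALSE, strand = "+", product = "conserved hypothetical protein",
    anticodon = NA, translation = NA, stringsAsFactors = FALSE)

  # tRNA genes
  tp <- spec$trna_plan
  Lt <- spec$trna_length
  trna_seqs <- character(nrow(tp))
  trna_pos <- integer(nrow(tp))
  for (i in seq_len(nrow(tp))) {
    p <- as.integer(round(tp$pos_frac[i] * L))
    trna_pos[i] <- p
    ts <- rand_seq(Lt, 58)
    trna_seqs[i] <- ts
    top <- if (tp$strand[i] == "-") revcomp(ts) else ts
    seq <- write_at(seq, p, top)
    reg_claim(reg, p, p + Lt - 1L, paste0("tRNA ", tp$label[i]))
    feats[[length(feats) + 1L]] <- data.frame(
      feature_id = sprintf("SYNT%02d", i), kind = "tRNA", start = p,
      end = p + Lt - 1L, wraps = FALSE, strand = tp$strand[i],
      product = paste0("tRNA-", tp$label[i]),
      anticodon = sub("^.*-", "", tp$label[i]), translation = NA,
      stringsAsFactors = FALSE)
  }
  trna_ids <- sprintf("SYNT%02d", seq_len(nrow(tp)))
  anchor3_of <- function(i) if (tp$strand[i] == "-") trna_pos[i] else trna_pos[i] + Lt - 1L

  # typical islands: tile downstream of their anchor, each closed by a
  # duplication of the anchor's 3'-terminal `dup` bases
  islands_truth <- list()
  dup_intervals <- list()
  n_integrase <- 0L
  for (pl in spec$island_plans) {
    ai <- pl$anchor
    a3 <- anchor3_of(ai)
    strand <- tp$strand[ai]
    prev <- 0L
    for (k in seq_along(pl$islands)) {
      isl <- pl$islands[[k]]
      body_len <- isl$length - isl$dup
      body <- guarded_low_gc_seq(body_len, spec$island_gc, gc_guard)
      # force the base before the duplication to break suffix extension
      dup <- substr(trna_seqs[ai], Lt - isl$dup + 1L, Lt)
      prev_base <- substr(trna_seqs[ai], Lt - isl$dup, Lt - isl$dup)
      alt <- setdiff(.bases, prev_base)[1]
      substr(body, body_len, body_len) <- alt
      content <- paste0(body, dup)
      w <- write_oriented(seq, a3, strand, prev + 1L, content)
      seq <- w$seq
      reg_claim(reg, w$start, w$end, sprintf("island %s.%d", tp$label[ai], k))
      ivl <- oriented_interval(a3, strand, prev + 1L, prev + isl$length, L)
      dup_ivl <- oriented_interval(a3, strand, prev + isl$length - isl$dup + 1L,
                                   prev + isl$length, L)
      dup_intervals[[length(dup_intervals) + 1L]] <- c(dup_ivl$start, dup_ivl$end)
      integ_id <- NA_character_
      if (isTRUE(isl$integrase)) {
        n_integrase <- n_integrase + 1L
        integ_id <- sprintf("SYNINT%02d", n_integrase)
        iw <- write_oriented(seq, a3, strand, prev + 101L,
                             substr(content, 101L, 1000L))  # annotate, keep seq
        feats[[length(feats) + 1L]] <- data.frame(
          feature_id = integ_id, kind = "CDS", start = iw$start, end = iw$end,
          wraps = FALSE, strand = strand, product = "phage integrase",
          anticodon = NA, translation = NA, stringsAsFactors = FALSE)
      }
      islands_truth[[length(islands_truth) + 1L]] <- data.frame(
        anchor_id = trna_ids[ai], nesting_index = k,
        left_end = ivl$start, right_end = ivl$end, length = isl$length,
        dup_length = isl$dup, dup_start = dup_ivl$start, dup_end = dup_ivl$end,
        gc_target = spec$island_gc, integrase_locus = integ_id,
        stringsAsFactors = FALSE)
      prev <- prev + isl$length
    }
  }

  # IS families
  fams <- list()
  if (!is.null(spec$is_family_plans))
    for (fp in spec$is_family_plans)
      fams[[fp$name]] <- rand_seq(fp$length, fp$gc)

  mutate_to_identity <- function(s, identity) {
    n <- nchar(s)
    k <- as.integer(round((100 - identity) / 100 * n))
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    v <- strsplit(s, "")[[1]]
    v[pos] <- vapply(v[pos], function(b) setdiff(.bases, b)[sample.int(3, 1)], "")
    paste(v, collapse = "")
  }

  is_truth <- list()
  plant_is <- function(seq, family, start, identity, where) {
    ref <- fams[[family]]
    copy <- mutate_to_identity(ref, identity)
    reg_claim(reg, start, start + nchar(copy) - 1L, paste0("IS ", family, " ", where))
    is_truth[[length(is_truth) + 1L]] <<- data.frame(
      family = family, start = start, end = start + nchar(copy) - 1L,
      strand = "+", identity_target = identity, region = where,
      stringsAsFactors = FALSE)
    write_at(seq, start, copy)
  }

  add_gene <- function(seq, start, len, region, product = "hypothetical protein",
                       id = NULL) {
    id <- id %||% sprintf("SYNG%03d", length(genes_truth) + 1L)
    reg_claim(reg, start, start + len - 1L, paste0("gene ", id))
    feats[[length(feats) + 1L]] <<- data.frame(
      feature_id = id, kind = "CDS", start = start, end = start + len - 1L,
      wraps = FALSE, strand = if (stats::runif(1) < 0.5) "+" else "-",
      product = product, anticodon = NA, translation = NA,
      stringsAsFactors = FALSE)
    genes_truth[[length(genes_truth) + 1L]] <<- data.frame(
      id = id, start = start, end = start + len - 1L, region = region,
      stringsAsFactors = FALSE)
    seq
  }

  # symbiosis fragments
  symb <- NULL
  if (!is.null(spec$symbiosis_plan)) {
    sp <- spec$symbiosis_plan
    ai <- match(sp$anchor_label, tp$label)
    a3 <- anchor3_of(ai)
    strand <- tp$strand[ai]
    sizes <- sp$sizes
    # fragment A abuts the intact trnV 3' end
    contA <- guarded_low_gc_seq(sizes["A"], sp$gc, gc_guard)
    wA <- write_oriented(seq, a3, strand, 1L, contA)
    seq <- wA$seq
    fragA <- c(wA$start, wA$end)
    # partial trnV copy (minus strand) + fragment B, distal
    pB <- as.integer(round(0.30 * L))
    suffix <- substr(trna_seqs[ai], Lt - sp$partial_len + 1L, Lt)
    seq <- write_at(seq, pB, revcomp(suffix))
    # break suffix extension beyond partial_len on the copy's 5' side
    guard_base <- substr(trna_seqs[ai], Lt - sp$partial_len, Lt - sp$partial_len)
    seq <- write_at(seq, pB + sp$partial_len, setdiff(.bases, revcomp(guard_base))[1])
    reg_claim(reg, pB, pB + sp$partial_len, "partial trnV copy")
    partial <- data.frame(start = pB + sp$partial_len - 1L, end = pB,
                          strand = "-", length = sp$partial_len)
    contB <- guarded_low_gc_seq(sizes["B"], sp$gc, gc_guard)
    bStart <- pB + sp$partial_len
    # keep the extension-guard base: overwrite from bStart but re-apply guard
    seq <- write_at(seq, bStart, contB)
    seq <- write_at(seq, bStart, setdiff(.bases, revcomp(guard_base))[1])
    fragB <- c(bStart, bStart + sizes["B"] - 1L)
    # fragment C, a free-standing low-GC block clear of fragment A
    cStart <- max(as.integer(round(0.83 * L)),
                  fragA[2] + as.integer(round(0.05 * L)))
    if (cStart + sizes["C"] + 1000L > L)
      stop("infeasible packing: genome too short for the symbiosis plan")
    contC <- guarded_low_gc_seq(sizes["C"], sp$gc, gc_guard)
    seq <- write_at(seq, cStart, contC)
    fragC <- c(cStart, cStart + sizes["C"] - 1L)

    # IS copies inside A and C (plus backbone copies) when families exist
    if (length(fams)) {
      fnames <- names(fams)
      f1 <- fnames[1]; f2 <- fnames[length(fnames)]
      offs_A <- list(c(400L, f1, 100), c(9800L, f1, 95), c(19800L, f2, 100),
                     c(29800L, f1, 97), c(34800L, f2, 100))
      for (o in offs_A)
        seq <- plant_is(seq, o[[2]], fragA[1] + as.integer(o[[1]]),
                        as.numeric(o[[3]]), "A")
      offs_C <- list(c(600L, f1, 100), c(3000L, f2, 97), c(6500L, f1, 95))
      for (o in offs_C)
        seq <- plant_is(seq, o[[2]], fragC[1] + as.integer(o[[1]]),
                        as.numeric(o[[3]]), "C")
      seq <- plant_is(seq, f1, as.integer(round(0.24 * L)), 100, "backbone")
      seq <- plant_is(seq, f2, as.integer(round(0.90 * L)), 95, "backbone")
    }

    # genes inside fragments (become the near-identical tier in genome B)
    for (o in c(2000L, 3200L, 5000L, 6500L, 12000L, 14000L, 16000L,
                22000L, 25000L, 28000L))
      seq <- add_gene(seq, fragA[1] + o, 800L, "A")
    n_integrase <- n_integrase + 1L
    seq <- add_gene(seq, fragB[1] + 100L, 900L, "B", product = "integrase",
                    id = sprintf("SYNINT%02d", n_integrase))
    for (o in c(1200L, 1900L, 2600L, 3300L))
      seq <- add_gene(seq, fragB[1] + o, 500L, "B")
    for (o in c(2000L, 4400L, 8000L))
      seq <- add_gene(seq, fragC[1] + o, 700L, "C")
    seq <- add_gene(seq, fragC[1] + 8900L, 700L, "C")

    symb <- list(anchor = trna_ids[ai],
                 fragments = data.frame(
                   name = c("A", "B", "C"),
                   start = c(fragA[1], fragB[1], fragC[1]),
                   end = c(fragA[2], fragB[2], fragC[2]),
                   length = as.integer(sizes[c("A", "B", "C")]),
                   gc_target = sp$gc, stringsAsFactors = FALSE),
                 partial = partial)
  }

  # IS copies without a symbiosis plan: scatter them on the backbone so the
  # IS atlas remains testable in symbiosis-free worlds
  if (is.null(symb) && length(fams)) {
    fnames <- names(fams)
    f1 <- fnames[1]; f2 <- fnames[length(fnames)]
    bb <- list(c(0.20, f1, 100), c(0.35, f2, 95), c(0.45, f1, 97),
               c(0.65, f2, 100), c(0.85, f1, 95))
    for (o in bb)
      seq <- plant_is(seq, o[[2]], as.integer(round(as.numeric(o[[1]]) * L)),
                      as.numeric(o[[3]]), "backbone")
  }

  # backbone genes
  gp <- spec$gene_plan
  n_bb <- max(0L, gp$count - length(genes_truth))
  tries <- 0L
  while (n_bb > 0L && tries < 5000L) {
    tries <- tries + 1L
    len <- as.integer(sample(gp$min_len:gp$max_len, 1L))
    s <- as.integer(sample.int(L - len - 1L, 1L))
    if (!reg_free(reg, s - 50L, s + len + 49L)) next
    seq <- add_gene(seq, s, len, "backbone")
    n_bb <- n_bb - 1L
  }
  if (n_bb > 0L) stop("infeasible packing: could not place all backbone genes")

  # --- sweep genome A for accidental tRNA-suffix matches ---------------------
  protected <- rbind(
    do.call(rbind, lapply(seq_len(nrow(tp)), function(i)
      c(trna_pos[i], trna_pos[i] + Lt - 1L))),
    if (length(dup_intervals)) do.call(rbind, dup_intervals),
    c(dif_start, dif_start + nchar(spec$dif_motif) - 1L),
    if (!is.null(symb)) c(min(symb$partial$start, symb$partial$end),
                          max(symb$partial$start, symb$partial$end)),
    if (length(is_truth)) as.matrix(do.call(rbind, is_truth)[, c("start", "end")])
  )
  storage.mode(protected) <- "integer"
  allowed <- protected  # suffix occurrences inside planted motifs are expected
  seq <- sweep_suffix_matches(seq, trna_seqs, spec$min_dup, allowed, protected)

  features <- do.call(rbind, feats)
  genomeA <- annotated_genome("SYNA", seq, features)

  # --- derive genome B -------------------------------------------------------
  rate <- rep(spec$divergence, L)
  if (!is.null(symb))
    for (i in seq_len(nrow(symb$fragments)))
      rate[symb$fragments$start[i]:symb$fragments$end[i]] <-
        spec$symbiosis_plan$rate
  for (i in seq_len(nrow(protected)))
    rate[protected[i, 1]:protected[i, 2]] <- 0
  # start/stop codons do not drift between conspecific strains: keep the
  # terminal 6 bp of every annotated CDS intact (this also anchors local
  # alignments end-to-end, so per-gene identities are directly comparable
  # with the ledger's whole-gene substitution tally)
  cds_rows <- features[features$kind == "CDS", , drop = FALSE]
  for (i in seq_len(nrow(cds_rows))) {
    rate[cds_rows$start[i]:min(cds_rows$start[i] + 5L, L)] <- 0
    rate[max(cds_rows$end[i] - 5L, 1L):cds_rows$end[i]] <- 0
  }
  mut <- which(stats::runif(L) < rate)
  vB <- strsplit(seq, "")[[1]]
  if (length(mut)) {
    shift <- sample.int(3L, length(mut), replace = TRUE)
    cur <- match(vB[mut], .bases)
    vB[mut] <- .bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  seqB <- paste(vB, collapse = "")
  seqB <- revert_spurious(seq, seqB, trna_seqs, spec$min_dup,
                          c("GTTTAAAC", "ATTTAAAT", "TTAATTAA"))
  genomeB <- annotated_genome("SYNB", seqB, features)

  # realized per-gene identities (post-hoc tally of substituted sites)
  diffpos <- which(charToRaw(seq) != charToRaw(seqB))
  genes <- do.call(rbind, genes_truth)
  genes <- rbind(genes,
                 data.frame(id = c("SYNANCHL", "SYNANCHR"),
                            start = c(anchL[1], anchR[1]),
                            end = c(anchL[2], anchR[2]),
                            region = "backbone", stringsAsFactors = FALSE))
  genes$subs <- vapply(seq_len(nrow(genes)), function(i)
    sum(diffpos >= genes$start[i] & diffpos <= genes$end[i]), integer(1))
  genes$identity_realized <-
    round(100 * (1 - genes$subs / (genes$end - genes$start + 1L)), 2)

  truth <- list(seed = spec$seed, genome_length = L,
                background_gc = gc, divergence = spec$divergence,
                skew = list(origin = b1, terminus = b2),
                dif = list(start = dif_start,
                           end = dif_start + nchar(spec$dif_motif) - 1L,
                           strand = "+"),
                trnas = data.frame(id = trna_ids, label = tp$label,
                                   start = trna_pos, end = trna_pos + Lt - 1L,
                                   strand = tp$strand, seq = trna_seqs,
                                   stringsAsFactors = FALSE),
                islands = if (length(islands_truth)) do.call(rbind, islands_truth)
                          else NULL,
                is_copies = if (length(is_truth)) do.call(rbind, is_truth) else NULL,
                symbiosis = symb,
                genes = genes,
                origin_anchors = c("SYNANCHL", "SYNANCHR"))
  list(genomeA = genomeA, genomeB = genomeB, truth = truth,
       is_families = lapply(names(fams), function(nm)
         is_family(nm, fams[[nm]], source = "synthetic")))
}

# Mutate accidental occurrences of any tRNA min_dup-suffix (either strand)
# outside the allowed intervals; positions inside protected intervals are
# never touched.
sweep_suffix_matches <- function(seq, trna_seqs, min_dup, allowed, protected) {
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  in_tab <- function(tab, s, e) any(tab[, 1] <= e & tab[, 2] >= s)
  for (pass in 1:4) {
    dirty <- FALSE
    for (ts in trna_seqs) {
      s0 <- substr(ts, nchar(ts) - min_dup + 1L, nchar(ts))
      for (pat in unique(c(s0, revcomp(s0)))) {
        occ <- motif_starts_circular(seq, pat)
        for (p in occ) {
          e <- p + min_dup - 1L
          if (e > nchar(seq)) next  # wrapped occurrence: origin region is background
          if (in_tab(allowed, p, e)) next
          q <- setdiff(p:e, unlist(lapply(seq_len(nrow(protected)), function(i)
            if (protected[i, 1] <= e && protected[i, 2] >= p)
              max(p, protected[i, 1]):min(e, protected[i, 2]) else NULL)))
          if (!length(q)) next
          b <- substr(seq, q[1], q[1])
          substr(seq, q[1], q[1]) <- flip[[b]]
          dirty <- TRUE
        }
      }
    }
    if (!dirty) break
  }
  seq
}

# Revert partner-genome substitutions that created a restriction site or a
# tRNA-suffix match absent from the source genome.
revert_spurious <- function(seqA, seqB, trna_seqs, min_dup, enzyme_motifs) {
  pats <- enzyme_motifs
  for (ts in trna_seqs) {
    s0 <- substr(ts, nchar(ts) - min_dup + 1L, nchar(ts))
    pats <- c(pats, s0, revcomp(s0))
  }
  for (pat in unique(pats)) {
    occA <- motif_starts_circular(seqA, pat)
    occB <- motif_starts_circular(seqB, pat)
    for (p in setdiff(occB, occA)) {
      e <- min(p + nchar(pat) - 1L, nchar(seqB))
      substr(seqB, p, e) <- substr(seqA, p, e)
    }
  }
  seqB
}

# --- three-way proteome generator --------------------------------------------

#' Generate three synthetic proteomes with planted ortholog families
#'
#' Plants gene families according to a sharing plan: `core` families have
#' one member per genome; `pair_ab`/`pair_ac`/`pair_bc` families span two
#' genomes; `unique_a`/`unique_b`/`unique_c` are singletons.  Family members
#' are derived from a common ancestral protein by substitution to the
#' planted within-family identity; unrelated proteins are independent random
#' sequences.  The downstream orthology analyses consume proteomes, so the
#' generator emits protein sets rather than full chromosomes.
#'
#' @param plan list with counts `core`, `pair_ab`, `pair_ac`, `pair_bc`,
#'   `unique_a`, `unique_b`, `unique_c`, member identity
#'   `family_identity` (percent, default 70), protein length range
#'   `len_range` (default c(150, 400)).
#' @param seed RNG seed.
#' @return List with `sets` (list of three [protein_set()]: A, B, C) and
#'   `truth` (data.frame: `family`, `span`, `genome`, `id`).
#' @export
generate_triple <- function(plan = list(), seed = 1L) {
  defaults <- list(core = 20L, pair_ab = 6L, pair_ac = 3L, pair_bc = 3L,
                   unique_a = 5L, unique_b = 4L, unique_c = 4L,
                   family_identity = 70, len_range = c(150L, 400L))
  plan <- modifyList(defaults, plan)
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  rand_prot <- function(n) paste(sample(aa, n, replace = TRUE), collapse = "")
  mutate_prot <- function(s, identity) {
    n <- nchar(s)
    k <- as.integer(round((100 - identity) / 100 * n))
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    v <- strsplit(s, "")[[1]]
    v[pos] <- vapply(v[pos], function(b) sample(setdiff(aa, b), 1L), "")
    paste(v, collapse = "")
  }
  sets <- list(A = list(), B = list(), C = list())
  truth <- list()
  fam_i <- 0L
  add_family <- function(genomes) {
    fam_i <<- fam_i + 1L
    n <- sample(plan$len_range[1]:plan$len_range[2], 1L)
    anc <- rand_prot(n)
    for (g in genomes) {
      id <- sprintf("%s_%04d", g, length(sets[[g]]) + 1L)
      sets[[g]][[id]] <<- mutate_prot(anc, plan$family_identity)
      truth[[length(truth) + 1L]] <<- data.frame(
        family = fam_i, span = paste(genomes, collapse = ""),
        genome = g, id = id, stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(plan$core)) add_family(c("A", "B", "C"))
  for (i in seq_len(plan$pair_ab)) add_family(c("A", "B"))
  for (i in seq_len(plan$pair_ac)) add_family(c("A", "C"))
  for (i in seq_len(plan$pair_bc)) add_family(c("B", "C"))
  for (i in seq_len(plan$unique_a)) add_family("A")
  for (i in seq_len(plan$unique_b)) add_family("B")
  for (i in seq_len(plan$unique_c)) add_family("C")
  ps <- lapply(names(sets), function(g)
    protein_set(g, unlist(sets[[g]])))
  names(ps) <- names(sets)
  list(sets = ps, truth = do.call(rbind, truth))
}
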