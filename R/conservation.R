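#' Classify genes into three conservation tiers against a reference genome
#'
#' Each query gene's nucleotide sequence is searched against the full
#' reference genome sequence (both strands) and assigned one of three
#' tiers from its best alignment: `distinct_identical` (bit score >= 100
#' and identity strictly > 99%), `significant_similarity` (bit score >= 100,
#' identity <= 99%), or `no_similarity` (no alignment reaching bit 100).
#' The tier partition is exhaustive and mutually exclusive.
#'
#' @param gene_features feature table rows (CDS) of the query genome, or
#'   `NULL` for all CDS features of `query_genome`.
#' @param query_genome an [annotated_genome()] carrying the gene sequences.
#' @param reference_genome an [annotated_genome()] (or plain sequence
#'   string) to search against.
#' @param scheme a [scoring_scheme()] (nucleotide).
#' @param bit_min bit-score threshold separating "no similarity" (default
#'   100; "score 100 or more" is read as bit score).
#' @param identity_min identity threshold for the top tier (default 99;
#'   "over 99%" is strict).
#' @return data.frame: `gene_id`, `tier`, plus best-hit columns
#'   (`identity_pct`, `bit_score`, `evalue`, `s_start`, `s_end`, `strand`,
#'   `aligned_length`; NA for tier `no_similarity` with no hit at all).
#' @export
classify_genes <- function(gene_features = NULL, query_genome, reference_genome,
                           scheme = scoring_scheme("nucleotide"),
                           bit_min = 100, identity_min = 99) {
  if (is.null(gene_features))
    gene_features <- query_genome$features[query_genome$features$kind == "CDS", ,
                                           drop = FALSE]
  ref_seq <- if (inherits(reference_genome, "annotated_genome"))
    reference_genome$sequence else toupper(reference_genome)
  idx <- build_kmer_index(ref_seq, scheme$seed_k)
  rows <- vector("list", nrow(gene_features))
  for (i in seq_len(nrow(gene_features))) {
    g <- gene_features[i, ]
    gseq <- feature_seq(query_genome, g)
    if (nchar(gseq) == 0L) stop("zero-length gene ", g$feature_id)
    h <- align_local(gseq, ref_seq, scheme, subject_index = idx)
    if (nrow(h)) {
      best <- h[1, ]
      tier <- if (best$bit_score >= bit_min) {
        if (best$identity_pct > identity_min) "distinct_identical"
        else "significant_similarity"
      } else "no_similarity"
      rows[[i]] <- data.frame(gene_id = g$feature_id, tier = tier,
                              identity_pct = best$identity_pct,
                              bit_score = best$bit_score, evalue = best$evalue,
                              s_start = best$s_start, s_end = best$s_end,
                              strand = best$strand,
                              aligned_length = best$aligned_length,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(gene_id = g$feature_id, tier = "no_similarity",
                              identity_pct = NA_real_, bit_score = NA_real_,
                              evalue = NA_real_, s_start = NA_integer_,
                              s_end = NA_integer_, strand = NA_character_,
                              aligned_length = NA_integer_,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Identity histogram of conserved genes
#'
#' Bins genes with qualifying alignments (bit score >= 100) by percent
#' identity into `n_bins` equal-width bins over [lo, hi]; the top bin is
#' right-closed.  Identities outside the range are clamped to the edge
#' bins with a warning.  The `population` switch selects whether the top
#' tier is included (`"qualifying"`, all genes with bit >= 100) or only
#' the middle tier (`"significant_similarity"`).
#'
#' @param records a [classify_genes()] result.
#' @param n_bins number of bins (default 23).
#' @param lo,hi identity range (defaults 54, 100: 2-point bins).
#' @param population `"qualifying"` (tiers 1+2, default) or
#'   `"significant_similarity"`.
#' @param bit_min qualifying bit-score threshold (default 100).
#' @return An object of class `identity_histogram`: list with `breaks`
#'   (length n_bins+1), `counts`, `population_size`.
#' @export
identity_histogram <- function(records, n_bins = 23L, lo = 54, hi = 100,
                               population = c("qualifying", "significant_similarity"),
                               bit_min = 100) {
  population <- match.arg(population)
  sel <- !is.na(records$bit_score) & records$bit_score >= bit_min
  if (population == "significant_similarity")
    sel <- sel & records$tier == "significant_similarity"
  ids <- records$identity_pct[sel]
  if (any(ids < lo | ids > hi)) {
    warning("identities outside [", lo, ", ", hi, "] clamped to edge bins")
    ids <- pmin(pmax(ids, lo), hi)
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  # left-closed bins, top bin right-closed
  bin <- pmin(floor((ids - lo) / ((hi - lo) / n_bins)) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(breaks = breaks, counts = counts,
                 population_size = length(ids)),
            class = "identity_histogram")
}

#' @export
print.identity_histogram <- function(x, ...) {
  cat(sprintf("<identity_histogram> %d genes in %d bins over [%g, %g]\n",
              x$population_size, length(x$counts), min(x$breaks), max(x$breaks)))
  invisible(x)
}

#' Cluster top-tier genes into loci
#'
#' Sorts `distinct_identical` genes by position on the circle and merges
#' runs whose inter-gene gaps are at most `max_gap` into loci; loci with
#' fewer than `min_genes` members are dropped.  A locus may wrap the
#' origin (the first and last runs merge when their wrap-around gap
#' qualifies).
#'
#' @param records a [classify_genes()] result.
#' @param gene_features the feature table the records were computed from
#'   (for coordinates).
#' @param genome_length replicon length in bp.
#' @param max_gap maximum gap between consecutive member genes (default
#'   25000, chosen to tolerate strain-specific islets above 10 kb).
#' @param min_genes minimum genes per locus (default 3).
#' @return data.frame: `name`, `start`, `end`, `wraps`, `gene_count`,
#'   `members` (comma-joined gene ids).
#' @export
cluster_tier1_loci <- function(records, gene_features, genome_length,
                               max_gap = 25000L, min_genes = 3L) {
  t1 <- records$gene_id[records$tier == "distinct_identical"]
  empty <- data.frame(name = character(), start = integer(), end = integer(),
                      wraps = logical(), gene_count = integer(),
                      members = character(), stringsAsFactors = FALSE)
  if (!length(t1)) return(empty)
  f <- gene_features[gene_features$feature_id %in% t1, , drop = FALSE]
  f <- f[order(f$start), , drop = FALSE]
  n <- nrow(f)
  if (n == 1L) {
    runs <- list(1L)
  } else {
    gaps <- f$start[-1] - f$end[-n] - 1L
    newrun <- c(TRUE, gaps > max_gap)
    run_id <- cumsum(newrun)
    runs <- split(seq_len(n), run_id)
    # wrap-around merge: gap from last gene end through origin to first start
    if (length(runs) > 1L) {
      wrap_gap <- (genome_length - f$end[n]) + f$start[1] - 1L
      if (wrap_gap <= max_gap) {
        runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
        runs[[length(runs)]] <- NULL
      }
    }
  }
  rows <- lapply(runs, function(ii) {
    wraps <- any(diff(ii) < 0)  # merged wrap run: indices restart
    s <- f$start[ii[1]]
    e <- f$end[ii[length(ii)]]
    data.frame(start = s, end = e, wraps = wraps,
               gene_count = length(ii),
               members = paste(f$feature_id[ii], collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$gene_count >= min_genes, , drop = FALSE]
  if (!nrow(res)) return(empty)
  res <- res[order(-res$gene_count), , drop = FALSE]
  res <- cbind(name = sprintf("Locus%s", LETTERS[seq_len(nrow(res))]), res,
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Whole-genome hit table (dot-plot substrate)
#'
#' All local alignments between two genome sequences above an E-value
#' cutoff, computed by tiling the query genome into chunks and searching
#' each against the subject.  This is the tabular form of a whole-genome
#' dot comparison; plotting is left to the caller.
#'
#' @param genomeA,genomeB [annotated_genome()] objects.
#' @param evalue_max cutoff (default 1e-20).
#' @param chunk query tile size in bp (default 5000).
#' @param scheme a [scoring_scheme()].
#' @return data.frame of hits with query/subject coordinates.
#' @export
genome_hit_table <- function(genomeA, genomeB, evalue_max = 1e-20,
                             chunk = 5000L, scheme = scoring_scheme("nucleotide")) {
  idx <- build_kmer_index(genomeB$sequence, scheme$seed_k)
  starts <- seq(1L, genomeA$length, by = chunk)
  rows <- list()
  for (s in starts) {
    e <- min(s + chunk - 1L, genomeA$length)
    if (e - s + 1L < scheme$seed_k) next
    h <- align_local(substr(genomeA$sequence, s, e), genomeB$sequence,
                     scheme, subject_index = idx)
    h <- h[h$evalue <= evalue_max, , drop = FALSE]
    if (nrow(h)) {
      h$q_start <- h$q_start + s - 1L
      h$q_end <- h$q_end + s - 1L
      rows[[length(rows) + 1L]] <- h
    }
  }
  if (!length(rows)) return(empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
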