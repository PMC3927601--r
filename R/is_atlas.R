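#' Define an insertion-sequence family
#'
#' @param name family name (e.g. RSalpha, ISBj7).
#' @param reference_seq the family's reference element sequence (>= 100 bp).
#' @param source free-text provenance (genome/locus the reference came from).
#' @return An object of class `is_family`.
#' @export
is_family <- function(name, reference_seq, source = NA_character_) {
  reference_seq <- toupper(reference_seq)
  if (nchar(reference_seq) < 100L)
    stop("IS family ", name, " reference shorter than 100 bp; rejected")
  structure(list(name = name, reference_seq = reference_seq, source = source),
            class = "is_family")
}

#' Map insertion-sequence copies onto a genome
#'
#' Searches the genome (both strands) for alignments to each family
#' reference, keeps hits of at least `min_len` aligned bp with E-value at
#' most `evalue_max`, classifies overlapping assignments to the
#' best-scoring family, and merges same-family copies overlapping by more
#' than 50% into one copy.
#'
#' @param genome an [annotated_genome()].
#' @param families list of [is_family()] objects (unique names).
#' @param min_len minimum aligned length in bp (default 100).
#' @param evalue_max E-value cutoff (default 1e-60, appropriate for long
#'   near-identical repeats against a Mb-scale genome).
#' @param scheme a [scoring_scheme()].
#' @return data.frame of copies: `family`, `start`, `end`, `wraps`,
#'   `strand`, `identity_pct`, `evalue`, `aligned_length`, `bit_score`,
#'   sorted by coordinate.
#' @export
map_is_copies <- function(genome, families, min_len = 100L, evalue_max = 1e-60,
                          scheme = scoring_scheme("nucleotide")) {
  if (!length(families)) stop("at least one IS family required")
  nms <- vapply(families, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("IS family names must be unique")
  idx <- build_kmer_index(genome$sequence, scheme$seed_k)
  rows <- list()
  for (fam in families) {
    h <- align_local(fam$reference_seq, genome$sequence, scheme,
                     subject_index = idx)
    h <- h[h$aligned_length >= min_len & h$evalue <= evalue_max, , drop = FALSE]
    if (nrow(h)) {
      h$family <- fam$name
      rows[[length(rows) + 1L]] <- h
    }
  }
  if (!length(rows)) return(empty_is_copies())
  hits <- do.call(rbind, rows)
  # cross-family overlap: winner is the best bit score
  hits <- hits[order(-hits$bit_score, hits$s_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  if (nrow(hits) > 1) for (i in 2:nrow(hits)) {
    for (j in seq_len(i - 1)) {
      if (!keep[j]) next
      ov <- min(hits$s_end[i], hits$s_end[j]) - max(hits$s_start[i], hits$s_start[j]) + 1L
      len_i <- hits$s_end[i] - hits$s_start[i] + 1L
      len_j <- hits$s_end[j] - hits$s_start[j] + 1L
      if (ov > 0.5 * min(len_i, len_j)) { keep[i] <- FALSE; break }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  out <- data.frame(family = hits$family, start = hits$s_start,
                    end = hits$s_end, wraps = FALSE, strand = hits$strand,
                    identity_pct = hits$identity_pct, evalue = hits$evalue,
                    aligned_length = hits$aligned_length,
                    bit_score = hits$bit_score, stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_is_copies <- function() {
  data.frame(family = character(), start = integer(), end = integer(),
             wraps = logical(), strand = character(), identity_pct = numeric(),
             evalue = numeric(), aligned_length = integer(),
             bit_score = numeric(), stringsAsFactors = FALSE)
}

#' Count IS copies per named genome region
#'
#' A copy belongs to a region when its midpoint lies inside (deterministic
#' for boundary-straddling copies); copies in no region are tallied as
#' "backbone".  Overlapping regions assign the copy to the first region in
#' declared order, with a warning.
#'
#' @param copies a [map_is_copies()] result.
#' @param named_regions named list of [circular_interval()] objects
#'   (possibly wrapping).
#' @param genome_length replicon length in bp.
#' @return List with `counts` (family x region matrix including a
#'   `backbone` column and a `total` column) and `assignment` (per-copy
#'   region).
#' @export
count_by_region <- function(copies, named_regions, genome_length) {
  region_names <- names(named_regions)
  if (is.null(region_names) || any(region_names == ""))
    stop("named_regions must be a named list")
  # warn once about overlapping region definitions
  if (length(named_regions) > 1) {
    for (i in seq_along(named_regions)[-1]) for (j in seq_len(i - 1))
      if (intervals_overlap(named_regions[[i]], named_regions[[j]],
                            genome_length)) {
        warning("regions ", region_names[j], " and ", region_names[i],
                " overlap; copies assigned to the first in declared order")
        break
      }
  }
  mids <- if (nrow(copies)) {
    vapply(seq_len(nrow(copies)), function(i)
      interval_midpoint(circular_interval(copies$start[i], copies$end[i],
                                          isTRUE(copies$wraps[i])),
                        genome_length), integer(1))
  } else integer()
  assign_region <- function(p) {
    for (nm in region_names)
      if (interval_contains(named_regions[[nm]], p)) return(nm)
    "backbone"
  }
  assignment <- vapply(mids, assign_region, character(1))
  fams <- sort(unique(copies$family))
  cols <- c(region_names, "backbone")
  counts <- base::matrix(0L, length(fams), length(cols) + 1L,
                         dimnames = list(fams, c(cols, "total")))
  for (i in seq_along(assignment)) {
    counts[copies$family[i], assignment[i]] <-
      counts[copies$family[i], assignment[i]] + 1L
    counts[copies$family[i], "total"] <- counts[copies$family[i], "total"] + 1L
  }
  list(counts = counts, assignment = assignment)
}
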