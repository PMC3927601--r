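#' Construct an annotated circular genome
#'
#' The central container of the package: a single replicon sequence plus a
#' typed feature table.  Coordinates are 1-based and inclusive throughout;
#' features crossing the origin carry `wraps = TRUE` with `start > end`.
#'
#' @param id accession-like identifier.
#' @param sequence DNA string over A,C,G,T,N (case-insensitive).
#' @param features a data.frame with columns `feature_id`, `kind`
#'   (CDS/tRNA/rRNA/misc), `start`, `end`, `wraps`, `strand` (+/-), and
#'   optionally `product`, `anticodon`, `translation`.  May be `NULL`.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `annotated_genome` with elements `id`,
#'   `sequence`, `length`, `topology`, `features`.
#' @export
annotated_genome <- function(id, sequence, features = NULL,
                             topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  len <- nchar(sequence)
  features <- normalize_features(features, len)
  structure(list(id = as.character(id), sequence = sequence,
                 length = len, topology = topology, features = features),
            class = "annotated_genome")
}

empty_features <- function() {
  data.frame(feature_id = character(), kind = character(),
             start = integer(), end = integer(), wraps = logical(),
             strand = character(), product = character(),
             anticodon = character(), translation = character(),
             stringsAsFactors = FALSE)
}

normalize_features <- function(features, genome_length) {
  if (is.null(features) || nrow(features) == 0L) return(empty_features())
  f <- as.data.frame(features, stringsAsFactors = FALSE)
  for (col in c("product", "anticodon", "translation"))
    if (is.null(f[[col]])) f[[col]] <- NA_character_
  if (is.null(f$wraps)) f$wraps <- FALSE
  need <- c("feature_id", "kind", "start", "end", "wraps", "strand",
            "product", "anticodon", "translation")
  miss <- setdiff(c("feature_id", "kind", "start", "end", "strand"), names(f))
  if (length(miss)) stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  f <- f[, need]
  f$start <- as.integer(f$start); f$end <- as.integer(f$end)
  if (anyDuplicated(f$feature_id))
    stop("duplicate locus tags: ",
         paste(unique(f$feature_id[duplicated(f$feature_id)]), collapse = ", "))
  bad <- f$start < 1L | f$end < 1L | f$start > genome_length | f$end > genome_length
  if (any(bad))
    stop("features outside sequence [1, ", genome_length, "]: ",
         paste(f$feature_id[bad], collapse = ", "))
  bad2 <- !f$wraps & f$end < f$start
  if (any(bad2))
    stop("non-wrapping features with end < start: ",
         paste(f$feature_id[bad2], collapse = ", "))
  rownames(f) <- NULL
  f
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %s, %d features\n",
              x$id, format(x$length, big.mark = ","), x$topology,
              nrow(x$features)))
  if (nrow(x$features)) {
    tb <- table(x$features$kind)
    cat("  ", paste(sprintf("%s: %d", names(tb), tb), collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

feature_interval <- function(feat_row) {
  circular_interval(feat_row$start, feat_row$end, isTRUE(feat_row$wraps))
}

# Nucleotide sequence of a feature, on its coding strand.
feature_seq <- function(genome, feat_row) {
  s <- interval_subseq(genome$sequence, feature_interval(feat_row), genome$length)
  if (identical(feat_row$strand, "-")) revcomp(s) else s
}

#' Reverse complement of a DNA string
#'
#' @param x a character DNA string (IUPAC codes allowed).
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' GC content of a genome or region
#'
#' Percentage 100*(G+C)/(A+C+G+T) over the whole genome or a region; `N`
#' bases count towards length but are excluded from both numerator and
#' denominator.  Reported to two decimals.
#'
#' @param genome an [annotated_genome()] (or a plain DNA string).
#' @param interval optional [circular_interval()] restricting the region.
#' @return GC percentage, rounded to 2 decimals.
#' @export
gc_fraction <- function(genome, interval = NULL) {
  seq <- if (inherits(genome, "annotated_genome")) genome$sequence else toupper(genome)
  len <- nchar(seq)
  if (!is.null(interval)) {
    if (interval_length(interval, len) < 1L) stop("empty interval")
    if (max(interval$start, interval$end) > len)
      stop("interval outside genome [1, ", len, "]")
    seq <- interval_subseq(seq, interval, len)
  }
  if (nchar(seq) == 0L) stop("empty interval")
  counts <- base_counts(seq)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) return(NA_real_)
  round(100 * sum(counts[c("G", "C")]) / denom, 2)
}

base_counts <- function(seq) {
  v <- Biostrings::letterFrequency(Biostrings::DNAString(seq), c("A", "C", "G", "T", "N"))
  setNames(as.integer(v), c("A", "C", "G", "T", "N"))
}

#' Rotate a circular genome
#'
#' Moves position `new_start` to coordinate 1, remapping all feature
#' coordinates modulo the genome length.  Only meaningful for circular
#' topology.
#'
#' @param genome an [annotated_genome()].
#' @param new_start the 1-based position that becomes coordinate 1.
#' @return The rotated genome.
#' @export
rotate_genome <- function(genome, new_start) {
  stopifnot(inherits(genome, "annotated_genome"))
  if (genome$topology != "circular") stop("cannot rotate a linear genome")
  L <- genome$length
  new_start <- as.integer(wrap_pos(new_start, L))
  if (new_start == 1L) return(genome)
  seq2 <- paste0(substr(genome$sequence, new_start, L),
                 substr(genome$sequence, 1L, new_start - 1L))
  f <- genome$features
  if (nrow(f)) {
    shift <- function(p) as.integer(wrap_pos(p - new_start + 1L, L))
    f$start <- shift(f$start); f$end <- shift(f$end)
    f$wraps <- f$end < f$start
  }
  out <- genome
  out$sequence <- seq2
  out$features <- f
  out
}

#' Set the genome origin at a restriction recognition site
#'
#' Renumbers a circular genome so position 1 is the first base of the
#' `index`-th occurrence of `recognition_seq` on the top strand, mirroring
#' the convention of numbering a finished chromosome from a chosen
#' recognition site (e.g. PacI, TTAATTAA).
#'
#' @param genome an [annotated_genome()].
#' @param recognition_seq recognition motif (IUPAC allowed).
#' @param index which occurrence to use (1-based, in coordinate order).
#' @return The renumbered genome.
#' @export
set_origin_at_site <- function(genome, recognition_seq, index = 1L) {
  hits <- motif_starts_circular(genome$sequence, recognition_seq)
  if (length(hits) == 0L)
    stop("recognition sequence ", recognition_seq, " not found in ", genome$id)
  if (index > length(hits))
    stop("requested occurrence ", index, " but only ", length(hits), " present")
  rotate_genome(genome, hits[index])
}

# All start positions (1-based, on the top strand of the circle) of an IUPAC
# motif, including occurrences spanning the origin.  Overlapping occurrences
# all count.
motif_starts_circular <- function(seq, motif, circular = TRUE) {
  L <- nchar(seq)
  m <- nchar(motif)
  if (m > L) return(integer())
  subject <- if (circular) paste0(seq, substr(seq, 1L, m - 1L)) else seq
  hits <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                   Biostrings::DNAString(subject),
                                   fixed = FALSE)
  starts <- BiocGenerics::start(hits)
  sort(unique(as.integer(wrap_pos(starts, L))[starts <= L]))
}
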