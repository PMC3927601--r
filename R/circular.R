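#' Circular interval on a 1-based, inclusive coordinate system
#'
#' An interval on a circular (or linear) replicon.  `start` and `end` are
#' 1-based and inclusive; `wraps = TRUE` means the interval runs from
#' `start` through the origin to `end` (so `start > end` numerically).
#' Wrapped intervals render in the "start-0-end" convention used for
#' origin-spanning loci in genome tables.
#'
#' @param start,end 1-based inclusive bounds.
#' @param wraps logical; does the interval cross the origin?
#' @return An object of class `circular_interval`.
#' @export
circular_interval <- function(start, end, wraps = FALSE) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L, start >= 1, end >= 1)
  if (!wraps && end < start) stop("end < start for a non-wrapping interval")
  structure(list(start = as.integer(start), end = as.integer(end),
                 wraps = isTRUE(wraps)),
            class = "circular_interval")
}

#' Length of a circular interval
#'
#' @param ivl a [circular_interval()].
#' @param genome_length replicon length in bp; required when `ivl` wraps.
#' @return Length in bp.
#' @export
interval_length <- function(ivl, genome_length = NULL) {
  if (!ivl$wraps) return(ivl$end - ivl$start + 1L)
  if (is.null(genome_length)) stop("genome_length needed for a wrapped interval")
  as.integer(genome_length) - ivl$start + 1L + ivl$end
}

#' @export
format.circular_interval <- function(x, ...) {
  if (x$wraps) sprintf("%d-0-%d", x$start, x$end) else sprintf("%d-%d", x$start, x$end)
}

#' @export
print.circular_interval <- function(x, ...) {
  cat("<circular_interval> ", format(x), if (x$wraps) " (wraps origin)", "\n", sep = "")
  invisible(x)
}

# Reduce a (possibly out-of-range) 1-based position onto the circle.
wrap_pos <- function(pos, len) {
  ((as.numeric(pos) - 1) %% as.numeric(len)) + 1
}

# Midpoint of an interval on the circle (1-based, rounded down).
interval_midpoint <- function(ivl, genome_length) {
  l <- interval_length(ivl, genome_length)
  as.integer(wrap_pos(ivl$start + (l - 1) %/% 2, genome_length))
}

# Does 1-based position p fall inside the interval?
interval_contains <- function(ivl, p) {
  if (!ivl$wraps) p >= ivl$start & p <= ivl$end else p >= ivl$start | p <= ivl$end
}

# Extract the subsequence covered by an interval from a circular sequence
# given as a single string.
interval_subseq <- function(seq, ivl, genome_length = nchar(seq)) {
  if (!ivl$wraps) return(substr(seq, ivl$start, ivl$end))
  paste0(substr(seq, ivl$start, genome_length), substr(seq, 1L, ivl$end))
}
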