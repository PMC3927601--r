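#' Restriction enzyme definition
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (IUPAC allowed), length >= 4.
#' @param cut_offset cut position in bp from the recognition start on the
#'   top strand (0..recognition length).
#' @return An object of class `enzyme`.
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) stop("recognition length must be >= 4")
  if (cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset outside [0, recognition length]")
  structure(list(name = name, recognition = recognition,
                 cut_offset = as.integer(cut_offset)),
            class = "enzyme")
}

# Built-in enzymes used for chromosome fingerprinting of large bacterial
# genomes (8-bp blunt cutters) plus the PacI numbering anchor.  Recognition
# sequences and blunt cut offsets from the standard REBASE definitions.
.builtin_enzymes <- list(
  PmeI = list(recognition = "GTTTAAAC", cut_offset = 4L),
  SwaI = list(recognition = "ATTTAAAT", cut_offset = 4L),
  PacI = list(recognition = "TTAATTAA", cut_offset = 5L)
)

#' Look up a built-in enzyme by name
#'
#' @param name one of `"PmeI"`, `"SwaI"`, `"PacI"`, or an `enzyme` object
#'   (returned unchanged).
#' @return An [enzyme()].
#' @export
get_enzyme <- function(name) {
  if (inherits(name, "enzyme")) return(name)
  e <- .builtin_enzymes[[name]]
  if (is.null(e)) stop("unknown enzyme '", name, "'; supply an enzyme() object")
  enzyme(name, e$recognition, e$cut_offset)
}

#' Find restriction cut positions on a genome
#'
#' Scans the top strand of the (circular) sequence for all occurrences of
#' the recognition motif, including occurrences spanning the origin and
#' overlapping occurrences.  Only palindromic enzymes are supported: for a
#' palindrome the top-strand scan is exhaustive.
#'
#' @param genome an [annotated_genome()].
#' @param enz an [enzyme()] or built-in enzyme name.
#' @return Sorted integer vector of cut coordinates; each is the 1-based
#'   position of the first base of the downstream fragment
#'   (site start + cut offset, reduced onto the circle).
#' @export
find_sites <- function(genome, enz) {
  stopifnot(inherits(genome, "annotated_genome"), genome$length > 0L)
  enz <- get_enzyme(enz)
  if (!identical(enz$recognition, revcomp(enz$recognition)))
    stop("enzyme ", enz$name, " is not palindromic; bottom-strand scanning ",
         "is not supported")
  starts <- motif_starts_circular(genome$sequence, enz$recognition,
                                  circular = genome$topology == "circular")
  if (!length(starts)) return(integer())
  sort(unique(as.integer(wrap_pos(starts + enz$cut_offset, genome$length))))
}

#' In-silico restriction digest
#'
#' Pools cut positions across enzymes and returns the resulting fragment
#' table.  A circular genome with k cuts yields k fragments (one full-length
#' fragment when k = 0); a linear genome yields k + 1 fragments.
#'
#' @param genome an [annotated_genome()].
#' @param enzymes list/vector of [enzyme()] objects or built-in names.
#' @return An object of class `fragment_table`: a data.frame with columns
#'   `rank`, `start`, `end`, `wraps`, `length_bp`, `length_kb` (kb rounded
#'   half away from zero), sorted by descending length, with attributes
#'   `genome_id`, `enzymes`, `total_bp`, `topology`.
#' @export
digest <- function(genome, enzymes) {
  if (length(enzymes) < 1L) stop("at least one enzyme required")
  enzymes <- lapply(enzymes, get_enzyme)
  cuts <- sort(unique(unlist(lapply(enzymes, function(e) find_sites(genome, e)))))
  L <- genome$length
  if (genome$topology == "circular") {
    if (length(cuts) == 0L) {
      frags <- data.frame(start = 1L, end = L, wraps = FALSE, length_bp = L)
    } else {
      starts <- cuts
      ends <- c(cuts[-1] - 1L, cuts[1] - 1L)
      ends[ends == 0L] <- L
      wraps <- ends < starts
      len <- ifelse(wraps, L - starts + 1L + ends, ends - starts + 1L)
      frags <- data.frame(start = starts, end = ends, wraps = wraps, length_bp = len)
    }
  } else {
    bounds <- c(1L, cuts[cuts > 1L & cuts <= L], L + 1L)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1] - 1L
    frags <- data.frame(start = starts, end = ends, wraps = FALSE,
                        length_bp = ends - starts + 1L)
  }
  frags <- frags[order(-frags$length_bp, frags$start), , drop = FALSE]
  frags$rank <- seq_len(nrow(frags))
  frags$length_kb <- round_half_up(frags$length_bp / 1000)
  frags <- frags[, c("rank", "start", "end", "wraps", "length_bp", "length_kb")]
  rownames(frags) <- NULL
  structure(frags, class = c("fragment_table", "data.frame"),
            genome_id = genome$id,
            enzymes = vapply(enzymes, `[[`, "", "name"),
            total_bp = sum(frags$length_bp),
            topology = genome$topology)
}

# Round half away from zero to integer (table presentation convention).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.fragment_table <- function(x, ...) {
  cat(sprintf("In-silico digest of %s (%s) with %s: %d fragments, %s bp total\n",
              attr(x, "genome_id"), attr(x, "topology"),
              paste(attr(x, "enzymes"), collapse = " + "),
              nrow(x), format(attr(x, "total_bp"), big.mark = ",")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write a fragment table as TSV
#'
#' @param ft a [digest()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(ft, path) {
  write.table(as.data.frame(ft), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
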