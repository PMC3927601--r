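#' Read an annotated genome from file
#'
#' Reads a GenBank flat file, or a FASTA file paired with a GFF3 (or TSV)
#' feature table, into an [annotated_genome()].  Topology is taken from the
#' GenBank LOCUS line when present, defaulting to circular.
#'
#' @param path path to a GenBank or FASTA file.
#' @param format `"genbank"`, `"fasta"`, or `"auto"` (by extension/content).
#' @param features path to a GFF3 (`.gff3`/`.gff`) or TSV feature table,
#'   required with FASTA input if any features are wanted.
#' @param topology override for topology with FASTA input.
#' @return An [annotated_genome()].
#' @export
read_genome <- function(path, format = c("auto", "genbank", "fasta"),
                        features = NULL, topology = "circular") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|genbank)$", path, ignore.case = TRUE)) "genbank"
              else if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE)) "fasta"
              else if (startsWith(readLines(path, n = 1L), "LOCUS")) "genbank"
              else "fasta"
  }
  if (format == "genbank") return(read_genbank(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L) stop("expected exactly one sequence in ", path)
  id <- sub("\\s.*$", "", names(seqs)[1])
  feat <- if (!is.null(features)) read_feature_table(features) else NULL
  annotated_genome(id, as.character(seqs[[1]]), feat, topology = topology)
}

read_feature_table <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    md <- S4Vectors::mcols(gr)
    getcol <- function(nm) if (nm %in% names(md)) as.character(md[[nm]]) else NA_character_
    kind <- as.character(md$type)
    kind[!kind %in% c("CDS", "tRNA", "rRNA")] <- "misc"
    data.frame(feature_id = getcol("ID"), kind = kind,
               start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
               wraps = FALSE,
               strand = ifelse(as.character(BiocGenerics::strand(gr)) == "-", "-", "+"),
               product = getcol("product"), anticodon = getcol("anticodon"),
               translation = getcol("translation"), stringsAsFactors = FALSE)
  } else {
    read.table(path, header = TRUE, sep = "\t", quote = "",
               stringsAsFactors = FALSE, na.strings = c("NA", "."))
  }
}

# ---- GenBank flat file ------------------------------------------------------
# Minimal reader/writer for single-record bacterial flat files: LOCUS line
# (length + topology), FEATURES with simple, complement() and two-part
# join() locations (origin-wrapping), the qualifiers this package emits,
# and ORIGIN sequence blocks.  No pre-installed R package parses GenBank.

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("malformed GenBank record in ", path, ": no LOCUS line (line 1)")
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  topology <- if (any(tolower(locus) == "linear")) "linear" else "circular"
  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) stop("malformed GenBank record in ", path,
                            ": no ORIGIN section (after line ", length(lines), ")")
  seq_lines <- lines[(orig_i[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  features <- NULL
  if (length(feat_i)) {
    block <- lines[(feat_i[1] + 1L):(orig_i[1] - 1L)]
    features <- parse_genbank_features(block, path)
  }
  annotated_genome(id, sequence, features, topology = topology)
}

parse_genbank_features <- function(block, path = "<genbank>") {
  # A new feature starts at column 6; continuation/qualifier lines at col 22.
  starts <- grep("^ {5}\\S", block)
  if (!length(starts)) return(NULL)
  ends <- c(starts[-1] - 1L, length(block))
  rows <- lapply(seq_along(starts), function(i) {
    chunk <- block[starts[i]:ends[i]]
    head1 <- strsplit(trimws(chunk[1]), "\\s+")[[1]]
    kind <- head1[1]
    # location may continue over lines until the first qualifier
    qual_start <- grep("^\\s+/", chunk)[1]
    loc_lines <- if (is.na(qual_start)) chunk else chunk[seq_len(qual_start - 1L)]
    loc <- gsub("\\s", "", paste(c(sub("^\\s*\\S+\\s*", "", loc_lines[1]),
                                   trimws(loc_lines[-1])), collapse = ""))
    loc_parsed <- parse_genbank_location(loc, path)
    quals <- parse_genbank_qualifiers(if (is.na(qual_start)) character() else
                                      chunk[qual_start:length(chunk)])
    kind2 <- if (kind %in% c("CDS", "tRNA", "rRNA")) kind else "misc"
    data.frame(feature_id = quals[["locus_tag"]] %||% NA_character_,
               kind = kind2, start = loc_parsed$start, end = loc_parsed$end,
               wraps = loc_parsed$wraps, strand = loc_parsed$strand,
               product = quals[["product"]] %||% NA_character_,
               anticodon = quals[["anticodon"]] %||% NA_character_,
               translation = quals[["translation"]] %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$kind != "misc" | !is.na(out$feature_id), , drop = FALSE]
  out$feature_id[is.na(out$feature_id)] <-
    sprintf("FEAT%04d", which(is.na(out$feature_id)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_genbank_location <- function(loc, path = "<genbank>") {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  wraps <- FALSE
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    if (length(parts) != 2L)
      stop("unsupported join() location '", loc, "' in ", path)
    p1 <- parse_span(parts[1], path); p2 <- parse_span(parts[2], path)
    return(list(start = p1$start, end = p2$end, wraps = TRUE, strand = strand))
  }
  p <- parse_span(loc, path)
  list(start = p$start, end = p$end, wraps = wraps, strand = strand)
}

parse_span <- function(span, path) {
  span <- gsub("[<>]", "", span)
  m <- regmatches(span, regexec("^(\\d+)\\.\\.(\\d+)$", span))[[1]]
  if (length(m) != 3L) stop("cannot parse location span '", span, "' in ", path)
  list(start = as.integer(m[2]), end = as.integer(m[3]))
}

parse_genbank_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  txt <- trimws(lines)
  qi <- grep("^/", txt)
  ends <- c(qi[-1] - 1L, length(txt))
  out <- list()
  for (j in seq_along(qi)) {
    entry <- paste(txt[qi[j]:ends[j]], collapse = "")
    m <- regmatches(entry, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', entry))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

#' Write a genome to a GenBank flat file
#'
#' Emits a minimal single-record flat file (LOCUS, FEATURES, ORIGIN) that
#' [read_genome()] parses back to an identical in-memory object; writing the
#' re-read genome reproduces the file byte for byte.
#'
#' @param genome an [annotated_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   BCT",
                     genome$id, genome$length, genome$topology), con)
  writeLines(sprintf("DEFINITION  %s.", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- genome$features
  if (nrow(f)) for (i in seq_len(nrow(f))) {
    r <- f[i, ]
    loc <- if (r$wraps)
      sprintf("join(%d..%d,1..%d)", r$start, genome$length, r$end)
    else sprintf("%d..%d", r$start, r$end)
    if (r$strand == "-") loc <- sprintf("complement(%s)", loc)
    kind <- if (r$kind == "misc") "misc_feature" else r$kind
    writeLines(sprintf("     %-16s%s", kind, loc), con)
    q <- function(name, val) if (!is.na(val))
      writeLines(sprintf('                     /%s="%s"', name, val), con)
    q("locus_tag", r$feature_id)
    q("product", r$product)
    q("anticodon", r$anticodon)
    q("translation", r$translation)
  }
  writeLines("ORIGIN", con)
  s <- genome$sequence
  for (off in seq(1L, genome$length, by = 60L)) {
    chunk <- substr(s, off, min(off + 59L, genome$length))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(tolower(blocks), collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write genome sequence as FASTA
#'
#' @param genome an [annotated_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome$sequence)
  names(x) <- genome$id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Export the feature table as GFF3
#'
#' Origin-wrapping features are split into their two spans (GFF3 has no
#' wrapped-interval notation); both parts share the feature's ID.
#'
#' @param genome an [annotated_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genome, path) {
  f <- genome$features
  gr_rows <- function(r, s, e) {
    GenomicRanges::GRanges(genome$id, IRanges::IRanges(s, e),
                           strand = r$strand, type = r$kind,
                           ID = r$feature_id,
                           phase = if (r$kind == "CDS") 0L else NA_integer_,
                           product = r$product, anticodon = r$anticodon)
  }
  grl <- list()
  if (nrow(f)) for (i in seq_len(nrow(f))) {
    r <- f[i, ]
    if (r$wraps) {
      grl[[length(grl) + 1L]] <- gr_rows(r, r$start, genome$length)
      grl[[length(grl) + 1L]] <- gr_rows(r, 1L, r$end)
    } else grl[[length(grl) + 1L]] <- gr_rows(r, r$start, r$end)
  }
  gr <- if (length(grl)) do.call(c, grl) else GenomicRanges::GRanges()
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Convert intervals between GFF3-style and BED coordinates
#'
#' GFF3 intervals are 1-based inclusive; BED intervals are 0-based
#' half-open.  These helpers perform the conversion used whenever interval
#' output is emitted as BED.
#'
#' @param start,end 1-based inclusive bounds (for `to_bed`); 0-based
#'   half-open bounds (for `from_bed`).
#' @return A two-column data.frame with converted `start`, `end`.
#' @export
interval_to_bed <- function(start, end) data.frame(start = start - 1L, end = end)

#' @rdname interval_to_bed
#' @export
interval_from_bed <- function(start, end) data.frame(start = start + 1L, end = end)

#' Write named intervals as a BED file
#'
#' @param df data.frame with `start`, `end` (1-based inclusive), `name`,
#'   and optionally `strand`.
#' @param chrom chromosome/accession name.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, chrom, path) {
  bed <- data.frame(chrom = chrom,
                    start = as.integer(df$start) - 1L,
                    end = as.integer(df$end),
                    name = df$name,
                    score = 0L,
                    strand = if (!is.null(df$strand)) df$strand else "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
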