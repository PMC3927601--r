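#' Configuration for a full comparative run
#'
#' Collects every threshold the pipeline uses so they can be echoed into
#' the report for provenance.
#'
#' @param genome_a,genome_b paths or [annotated_genome()] objects (b may be
#'   NULL for a single-genome run).
#' @param out_dir output directory.
#' @param enzymes digestion enzymes (names or [enzyme()] objects).
#' @param window GC-skew window in bp.
#' @param dif_motif dif consensus 28-mer (user configuration).
#' @param dif_max_mismatches Hamming tolerance for the dif search.
#' @param min_dup minimum island duplication length.
#' @param evalue_rbh,evalue_dotplot,evalue_is E-value cutoffs for
#'   orthology (1e-4), whole-genome comparison (1e-20) and IS mapping
#'   (1e-60).
#' @param min_is_len minimum IS alignment length (100 bp).
#' @param identity_tier1 identity threshold for the top conservation tier.
#' @param bit_min qualifying bit score for conservation tiers.
#' @param gc_margin,gc_window low-GC detection parameters.
#' @param seed seed echoed into the report.
#' @return An object of class `run_config`.
#' @export
run_config <- function(genome_a, genome_b = NULL, out_dir = ".",
                       enzymes = c("PmeI", "SwaI"), window = 10000L,
                       dif_motif = "GGTGCGCATAATGTATATTATGTTAAAT",
                       dif_max_mismatches = 4L, min_dup = 14L,
                       evalue_rbh = 1e-4, evalue_dotplot = 1e-20,
                       evalue_is = 1e-60, min_is_len = 100L,
                       identity_tier1 = 99, bit_min = 100,
                       gc_margin = 2, gc_window = 5000L, seed = 1L) {
  structure(list(genome_a = genome_a, genome_b = genome_b, out_dir = out_dir,
                 enzymes = enzymes, window = as.integer(window),
                 dif_motif = dif_motif,
                 dif_max_mismatches = as.integer(dif_max_mismatches),
                 min_dup = as.integer(min_dup), evalue_rbh = evalue_rbh,
                 evalue_dotplot = evalue_dotplot, evalue_is = evalue_is,
                 min_is_len = as.integer(min_is_len),
                 identity_tier1 = identity_tier1, bit_min = bit_min,
                 gc_margin = gc_margin, gc_window = as.integer(gc_window),
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

load_genome_arg <- function(g) {
  if (inherits(g, "annotated_genome")) g else read_genome(g)
}

#' Run the full comparative analysis
#'
#' Orchestrates digestion, GC-skew/dif analysis, island detection, IS
#' mapping, conservation tiers, symbiosis-island assembly and (given a
#' second genome) the pairwise comparisons, writing per-module TSV
#' artifacts and a single JSON summary.  Reruns with identical inputs and
#' configuration produce byte-identical summaries.
#'
#' @param config a [run_config()].
#' @param is_families optional list of [is_family()] objects for IS
#'   mapping (skipped when NULL).
#' @param trnv_locus optional locus tag of the symbiosis anchor tRNA
#'   (symbiosis assembly skipped when NULL).
#' @return The report summary (list), invisibly; artifacts are written to
#'   `config$out_dir`.
#' @export
run_full_comparison <- function(config, is_families = NULL, trnv_locus = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  gA <- load_genome_arg(config$genome_a)
  gB <- if (!is.null(config$genome_b)) load_genome_arg(config$genome_b)
  summary <- list(config = config[setdiff(names(config),
                                          c("genome_a", "genome_b", "out_dir"))],
                  genome_a = list(id = gA$id, length = gA$length,
                                  gc_pct = gc_fraction(gA)))

  stage_log("digest", paste("digesting", gA$id))
  ft <- digest(gA, as.list(config$enzymes))
  write_fragment_table(ft, out("fragments_a.tsv"))
  summary$digest <- list(n_fragments = nrow(ft),
                         largest_kb = max(ft$length_kb),
                         smallest_kb = min(ft$length_kb),
                         total_bp = attr(ft, "total_bp"))

  stage_log("skew", "GC-skew profile and dif search")
  prof <- gc_skew_profile(gA, window = config$window)
  write.table(prof$values, out("skew_a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  shifts <- find_skew_shifts(prof)
  dif <- find_motif(gA, config$dif_motif, config$dif_max_mismatches)
  summary$replication <- list(origin = shifts$origin, terminus = shifts$terminus,
                              detected = shifts$detected,
                              dif_hits = nrow(dif),
                              dif_best = if (nrow(dif)) as.list(dif[1, ]) else NULL)
  if (nrow(dif))
    write_bed(data.frame(start = pmin(dif$start, dif$end),
                         end = pmax(dif$start, dif$end),
                         name = sprintf("dif_hit_%d", seq_len(nrow(dif))),
                         strand = dif$strand), gA$id, out("dif_a.bed"))

  stage_log("islands", "tRNA-anchored island scan")
  isl <- find_trna_anchored_islands(gA, min_dup = config$min_dup)
  write.table(isl, out("islands_a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cand <- find_candidate_low_gc_islands(gA, gc_margin = config$gc_margin,
                                        window = config$gc_window)
  write.table(cand, out("candidates_a.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  summary$islands <- list(n_typical = nrow(isl), n_candidates = nrow(cand),
                          dup_range = if (nrow(isl))
                            range(isl$duplication_length) else NULL)

  copies <- NULL
  if (!is.null(is_families)) {
    stage_log("ismap", sprintf("mapping %d IS families", length(is_families)))
    copies <- map_is_copies(gA, is_families, min_len = config$min_is_len,
                            evalue_max = config$evalue_is)
    write.table(copies, out("is_copies_a.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    summary$is_atlas <- list(n_copies = nrow(copies),
                             by_family = as.list(table(copies$family)))
  } else stage_log("ismap", "skipped: no IS families supplied")

  records <- NULL; loci <- NULL
  if (!is.null(gB)) {
    stage_log("conserve", paste("classifying", gA$id, "genes against", gB$id))
    cds <- gA$features[gA$features$kind == "CDS", , drop = FALSE]
    records <- classify_genes(cds, gA, gB, bit_min = config$bit_min,
                              identity_min = config$identity_tier1)
    write.table(records, out("conservation.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    hist <- identity_histogram(records, bit_min = config$bit_min)
    write.table(data.frame(bin_lo = head(hist$breaks, -1),
                           bin_hi = tail(hist$breaks, -1),
                           count = hist$counts),
                out("identity_histogram.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    loci <- cluster_tier1_loci(records, cds, gA$length)
    write.table(loci, out("tier1_loci.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    summary$conservation <- list(tiers = as.list(table(records$tier)),
                                 n_loci = nrow(loci),
                                 loci_genes = loci$gene_count)
  } else stage_log("conserve", "skipped: single-genome run")

  if (!is.null(trnv_locus) && !is.null(copies)) {
    stage_log("symbiosis", paste("assembling split island at", trnv_locus))
    symb <- assemble_symbiosis_islands(gA, isl, copies, loci, trnv_locus,
                                       gc_margin = config$gc_margin,
                                       window = config$gc_window)
    jsonlite::write_json(list(fragments = symb$fragments,
                              total_kb = symb$total_kb,
                              complete = symb$complete,
                              partial_trnv_hits = symb$partial_trnv_hits),
                         out("symbiosis.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    summary$symbiosis <- list(n_fragments_kept = sum(symb$fragments$kept),
                              total_kb = symb$total_kb,
                              complete = symb$complete)
  } else stage_log("symbiosis", "skipped: no anchor locus or no IS copies")

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  stage_log("report", paste("summary written to", out("summary.json")))
  invisible(summary)
}

# ---- command-line surface ---------------------------------------------------

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1L <= length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else { opts[[key]] <- TRUE; i <- i + 1L }
    } else i <- i + 1L
  }
  opts
}

#' Command-line entry point
#'
#' Subcommands: `convert`, `digest`, `skew`, `islands`, `ismap`,
#' `conserve`, `symbiosis`, `orthovenn`, `simulate`, `report`.  Invoked by
#' the `inst/cli/islandscout` Rscript wrapper; callable directly for
#' testing.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return Exit status (0 on success), invisibly.
#' @export
islandscout_cli <- function(args) {
  if (!length(args)) {
    message("usage: islandscout <convert|digest|skew|islands|ismap|conserve|",
            "symbiosis|orthovenn|simulate|report> [--flag value ...]")
    return(invisible(1L))
  }
  cmd <- args[1]
  o <- parse_cli_args(args[-1])
  status <- tryCatch({
    switch(cmd,
      convert = {
        g <- read_genome(o$`in`)
        if (!is.null(o$out)) write_fasta(g, o$out)
        if (!is.null(o$features)) write_gff3(g, o$features)
        if (!is.null(o$genbank)) write_genbank(g, o$genbank)
      },
      digest = {
        g <- read_genome(o$genome)
        enz <- strsplit(o$enzymes %||% "PmeI,SwaI", ",")[[1]]
        ft <- digest(g, as.list(enz))
        write_fragment_table(ft, o$out %||% "fragments.tsv")
      },
      skew = {
        g <- read_genome(o$genome)
        prof <- gc_skew_profile(g, window = as.integer(o$window %||% 10000))
        write.table(prof$values, o$out %||% "skew.tsv", sep = "\t",
                    quote = FALSE, row.names = FALSE)
        sh <- find_skew_shifts(prof)
        if (sh$detected)
          message(sprintf("origin ~%d bp, terminus ~%d bp", sh$origin, sh$terminus))
        if (!is.null(o$`dif-motif`)) {
          hits <- find_motif(g, o$`dif-motif`,
                             as.integer(o$`dif-mismatches` %||% 4))
          if (nrow(hits))
            write_bed(data.frame(start = pmin(hits$start, hits$end),
                                 end = pmax(hits$start, hits$end),
                                 name = sprintf("dif_%d", seq_len(nrow(hits))),
                                 strand = hits$strand),
                      g$id, o$`dif-out` %||% "dif.bed")
        }
      },
      islands = {
        g <- read_genome(o$genome)
        isl <- find_trna_anchored_islands(g,
                 min_dup = as.integer(o$`min-dup` %||% 14))
        write.table(isl, o$out %||% "islands.tsv", sep = "\t",
                    quote = FALSE, row.names = FALSE)
      },
      ismap = {
        g <- read_genome(o$genome)
        seqs <- Biostrings::readDNAStringSet(o$families)
        fams <- lapply(seq_along(seqs), function(i)
          is_family(names(seqs)[i], as.character(seqs[[i]])))
        copies <- map_is_copies(g, fams)
        write.table(copies, o$out %||% "is_copies.tsv", sep = "\t",
                    quote = FALSE, row.names = FALSE)
      },
      conserve = {
        gq <- read_genome(o$query); gr <- read_genome(o$ref)
        cds <- gq$features[gq$features$kind == "CDS", , drop = FALSE]
        rec <- classify_genes(cds, gq, gr)
        dir.create(o$out %||% ".", showWarnings = FALSE, recursive = TRUE)
        write.table(rec, file.path(o$out %||% ".", "conservation.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      },
      symbiosis = ,
      report = {
        cfg <- run_config(o$genome %||% o$query, o$ref,
                          out_dir = o$out %||% ".")
        fams <- if (!is.null(o$families)) {
          seqs <- Biostrings::readDNAStringSet(o$families)
          lapply(seq_along(seqs), function(i)
            is_family(names(seqs)[i], as.character(seqs[[i]])))
        }
        run_full_comparison(cfg, is_families = fams, trnv_locus = o$trnv)
      },
      orthovenn = {
        paths <- strsplit(o$sets, ",")[[1]]
        sets <- lapply(seq_along(paths), function(i) {
          ss <- Biostrings::readAAStringSet(paths[i])
          protein_set(LETTERS[i], setNames(as.character(ss),
                                           sub("\\s.*$", "", names(ss))))
        })
        vp <- venn_partition(sets[[1]], sets[[2]], sets[[3]])
        jsonlite::write_json(list(regions = as.list(vp$regions),
                                  total = vp$total, unit = vp$unit),
                             o$out %||% "venn.json", auto_unbox = TRUE,
                             pretty = TRUE)
      },
      simulate = {
        spec <- synth_spec(seed = as.integer(o$seed %||% 1))
        pair <- generate_pair(spec)
        dir.create(o$out %||% ".", showWarnings = FALSE, recursive = TRUE)
        od <- o$out %||% "."
        write_genbank(pair$genomeA, file.path(od, "genome_a.gb"))
        write_fasta(pair$genomeA, file.path(od, "genome_a.fa"))
        write_gff3(pair$genomeA, file.path(od, "genome_a.gff3"))
        write_genbank(pair$genomeB, file.path(od, "genome_b.gb"))
        jsonlite::write_json(pair$truth, file.path(od, "truth.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE,
                             force = TRUE)
      },
      stop("unknown subcommand: ", cmd)
    )
    0L
  }, error = function(e) {
    message("error [", cmd, "]: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
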