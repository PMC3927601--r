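#' Construct a protein set
#'
#' @param genome_id genome identifier.
#' @param proteins named character vector (names = locus tags, values =
#'   amino-acid sequences) or a list of `list(id=, seq=)`.
#' @return An object of class `protein_set`.
#' @export
protein_set <- function(genome_id, proteins) {
  if (is.list(proteins) && !is.null(proteins[[1]]$id))
    proteins <- setNames(vapply(proteins, `[[`, "", "seq"),
                         vapply(proteins, `[[`, "", "id"))
  if (is.null(names(proteins)) || any(names(proteins) == ""))
    stop("proteins must be named by locus tag")
  if (anyDuplicated(names(proteins)))
    stop("duplicate locus tags in protein set ", genome_id)
  proteins <- toupper(proteins)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", proteins)
  if (any(bad))
    stop("non amino-acid characters in: ",
         paste(head(names(proteins)[bad], 3), collapse = ", "))
  structure(list(genome_id = genome_id, proteins = proteins),
            class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("<protein_set> %s: %d proteins\n", x$genome_id, length(x$proteins)))
  invisible(x)
}

# Best hit of one protein against a protein set; returns NULL or a row with
# subject_id.  Ties break by database order (then coordinate).
.protein_best_hit <- function(seq, db, scheme, evalue_cutoff) {
  best_hit(seq, db, scheme, evalue_cutoff)
}

#' Reciprocal-best-hit ortholog pairs between two protein sets
#'
#' A pair (a, b) is reported iff b is a's best hit in set B and a is b's
#' best hit in set A, both with E-value at most `evalue_max`.  Best-hit
#' ties break by bit score, then E-value, then database order.
#'
#' @param setA,setB [protein_set()] objects.
#' @param evalue_max E-value cutoff (default 1e-4, the conventional
#'   proteome-comparison threshold).
#' @param scheme a protein [scoring_scheme()].
#' @return data.frame: `id_a`, `id_b`, `identity_pct`, `bit_score`,
#'   `evalue` (of the a->b alignment).
#' @export
reciprocal_best_hits <- function(setA, setB, evalue_max = 1e-4,
                                 scheme = scoring_scheme("protein")) {
  stopifnot(inherits(setA, "protein_set"), inherits(setB, "protein_set"))
  if (!length(setA$proteins) || !length(setB$proteins))
    stop("both protein sets must be non-empty")
  dbB <- prepare_blast_db(setB$proteins, scheme)
  dbA <- prepare_blast_db(setA$proteins, scheme)
  bestAB <- lapply(setA$proteins, .protein_best_hit, db = dbB,
                   scheme = scheme, evalue_cutoff = evalue_max)
  bestBA <- lapply(setB$proteins, .protein_best_hit, db = dbA,
                   scheme = scheme, evalue_cutoff = evalue_max)
  rows <- list()
  for (a in names(setA$proteins)) {
    hab <- bestAB[[a]]
    if (is.null(hab)) next
    b <- hab$subject_id
    hba <- bestBA[[b]]
    if (is.null(hba) || !identical(hba$subject_id, a)) next
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = a, id_b = b, identity_pct = hab$identity_pct,
      bit_score = hab$bit_score, evalue = hab$evalue,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(id_a = character(), id_b = character(),
                      identity_pct = numeric(), bit_score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Three-way Venn partition of gene families
#'
#' Computes the three pairwise reciprocal-best-hit graphs, links them into
#' connected components over the union of all proteins, and classifies each
#' component into one of the 7 Venn regions by the set of genomes it spans.
#' By default counts are per family (a component counts once, the
#' non-redundant accounting); `unit = "genes"` counts member genes instead.
#'
#' @param setA,setB,setC [protein_set()] objects.
#' @param evalue_max E-value cutoff (default 1e-4).
#' @param scheme a protein [scoring_scheme()].
#' @param unit `"families"` (default) or `"genes"`.
#' @return An object of class `venn_partition`: list with `regions` (named
#'   counts: A, B, C, AB, AC, BC, ABC), `total` (non-redundant union
#'   size), `components` (list of member vectors), `unit`.
#' @export
venn_partition <- function(setA, setB, setC, evalue_max = 1e-4,
                           scheme = scoring_scheme("protein"),
                           unit = c("families", "genes")) {
  unit <- match.arg(unit)
  sets <- list(A = setA, B = setB, C = setC)
  tag <- function(g, ids) paste0(g, "|", ids)
  nodes <- unlist(lapply(names(sets), function(g) tag(g, names(sets[[g]]$proteins))))
  edges <- character(0)
  for (pair in list(c("A", "B"), c("A", "C"), c("B", "C"))) {
    rbh <- reciprocal_best_hits(sets[[pair[1]]], sets[[pair[2]]],
                                evalue_max, scheme)
    if (nrow(rbh))
      edges <- c(edges, rbind(tag(pair[1], rbh$id_a), tag(pair[2], rbh$id_b)))
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (length(edges)) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)
  members <- split(nodes, comp$membership)
  region_of <- function(mem) {
    present <- sort(unique(sub("\\|.*$", "", mem)))
    paste(present, collapse = "")
  }
  regions <- setNames(numeric(7), c("A", "B", "C", "AB", "AC", "BC", "ABC"))
  for (mem in members) {
    r <- region_of(mem)
    w <- if (unit == "families") 1L else length(mem)
    regions[r] <- regions[r] + w
  }
  total <- if (unit == "families") length(members) else length(nodes)
  structure(list(regions = regions, total = total, components = members,
                 unit = unit),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("<venn_partition> %d %s in the non-redundant union\n",
              x$total, x$unit))
  print(x$regions)
  invisible(x)
}

#' Single-linkage protein clusters across genomes
#'
#' Links every ordered pair of proteins for which an alignment reaches
#' `min_identity` percent amino-acid identity and covers at least
#' `min_coverage` of the query length (either orientation passing
#' suffices), then takes the transitive closure.  Clusters containing
#' exactly one member per genome are flagged as single-copy acceptable.
#'
#' @param protein_sets list of at least two [protein_set()] objects.
#' @param min_identity percent identity threshold (default 60).
#' @param min_coverage query-length coverage fraction (default 0.7).
#' @param scheme a protein [scoring_scheme()].
#' @return An object of class `ortho_clusters`: list with `clusters`
#'   (list of data.frames `genome_id`, `id`), `single_copy` (logical
#'   vector), `n_genomes`.
#' @export
single_linkage_clusters <- function(protein_sets, min_identity = 60,
                                    min_coverage = 0.7,
                                    scheme = scoring_scheme("protein")) {
  if (length(protein_sets) < 2L) stop("need at least two protein sets")
  tab <- do.call(rbind, lapply(protein_sets, function(ps)
    data.frame(genome_id = ps$genome_id, id = names(ps$proteins),
               seq = unname(ps$proteins), stringsAsFactors = FALSE)))
  n <- nrow(tab)
  node <- paste0(tab$genome_id, "|", tab$id)
  edges <- character(0)
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    h <- align_local(tab$seq[i], tab$seq[j], scheme)
    if (!nrow(h)) next
    b <- h[1, ]
    qcov_i <- b$aligned_length / nchar(tab$seq[i])
    qcov_j <- b$aligned_length / nchar(tab$seq[j])
    if (b$identity_pct >= min_identity &&
        (qcov_i >= min_coverage || qcov_j >= min_coverage))
      edges <- c(edges, node[i], node[j])
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(node)
  if (length(edges)) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)
  members <- split(seq_len(n), comp$membership)
  genome_ids <- vapply(protein_sets, `[[`, "", "genome_id")
  clusters <- lapply(members, function(ii)
    data.frame(genome_id = tab$genome_id[ii], id = tab$id[ii],
               stringsAsFactors = FALSE))
  single_copy <- vapply(clusters, function(cl) {
    length(unique(cl$genome_id)) == length(genome_ids) &&
      nrow(cl) == length(genome_ids)
  }, logical(1))
  structure(list(clusters = unname(clusters),
                 single_copy = unname(single_copy),
                 n_genomes = length(genome_ids)),
            class = "ortho_clusters")
}

#' @export
print.ortho_clusters <- function(x, ...) {
  cat(sprintf("<ortho_clusters> %d clusters over %d genomes; %d single-copy acceptable\n",
              length(x$clusters), x$n_genomes, sum(x$single_copy)))
  invisible(x)
}
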