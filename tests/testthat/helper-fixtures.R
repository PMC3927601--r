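# Shared fixtures: built once per session and cached, because the default
# synthetic world (500 kb) and its gene classification are used by several
# test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture_pair <- function() {
  if (is.null(.fixture_cache$pair))
    .fixture_cache$pair <- generate_pair(synth_spec(seed = 7))
  .fixture_cache$pair
}

fixture_records <- function() {
  if (is.null(.fixture_cache$records)) {
    pair <- fixture_pair()
    cds <- pair$genomeA$features[pair$genomeA$features$kind == "CDS", ]
    .fixture_cache$records <- classify_genes(cds, pair$genomeA, pair$genomeB)
  }
  .fixture_cache$records
}

fixture_islands <- function() {
  if (is.null(.fixture_cache$islands))
    .fixture_cache$islands <- find_trna_anchored_islands(fixture_pair()$genomeA)
  .fixture_cache$islands
}

fixture_is_copies <- function() {
  if (is.null(.fixture_cache$copies)) {
    pair <- fixture_pair()
    .fixture_cache$copies <- map_is_copies(pair$genomeA, pair$is_families)
  }
  .fixture_cache$copies
}

# A compact world (150 kb, no symbiosis) for orchestration tests.
small_world_spec <- function(seed = 3L) {
  synth_spec(
    seed = seed, genome_length = 150000L,
    # asymmetric arcs: at this scale the default near-balanced arcs leave
    # the cumulative-skew extremes within noise of each other
    skew_boundaries = c(0.07, 0.80),
    trna_plan = data.frame(
      label = c("trnS-GGA", "trnK-CTT", "trnL-CAA", "trnQ-TTG", "trnM-CAT"),
      strand = c("+", "+", "-", "+", "+"),
      pos_frac = c(0.10, 0.28, 0.52, 0.70, 0.90), stringsAsFactors = FALSE),
    island_plans = list(
      list(anchor = 1L, islands = list(list(length = 8000L, dup = 47L,
                                            integrase = TRUE))),
      list(anchor = 3L, islands = list(list(length = 5000L, dup = 14L,
                                            integrase = FALSE)))),
    symbiosis_plan = FALSE,
    gene_plan = list(count = 12L, min_len = 300L, max_len = 1500L))
}

random_dna <- function(n, gc = 0.5) {
  g <- gc
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)), collapse = "")
}

# Substitute an exact number of positions (never to the same base).
mutate_exact <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(v, collapse = "")
}

write_at_test <- function(s, pos, content) {
  substr(s, pos, pos + nchar(content) - 1) <- content
  s
}

mutate_exact_prot <- function(s, k) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  v <- strsplit(s, "")[[1]]
  pos <- sample(length(v), k)
  v[pos] <- vapply(v[pos], function(b) sample(setdiff(aa, b), 1), "")
  paste(v, collapse = "")
}

# Independent union-find oracle over an explicit edge list.
uf_components <- function(nodes, edges_from, edges_to) {
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_along(edges_from)) {
    a <- find(match(edges_from[e], nodes))
    b <- find(match(edges_to[e], nodes))
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  unname(split(nodes, roots))
}

# Canonical form of a partition (set of sets) for comparison.
canon_partition <- function(groups) {
  sort(vapply(groups, function(g) paste(sort(g), collapse = "+"), ""))
}

# Naive exhaustive motif scan on the doubled sequence (digest/motif oracle).
naive_motif_starts <- function(seq, motif) {
  L <- nchar(seq)
  m <- nchar(motif)
  ch <- strsplit(paste0(seq, substr(seq, 1, m - 1)), "")[[1]]
  pat <- strsplit(motif, "")[[1]]
  ok <- rep(TRUE, L)
  for (j in seq_len(m)) ok <- ok & ch[seq_len(L) + j - 1] == pat[j]
  which(ok)
}
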