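test_that("tier rules: verbatim, diverged and absent genes", {
  set.seed(71)
  ref <- random_dna(50000, gc = 0.6)
  gene1 <- substr(ref, 10001, 11200)            # verbatim, 1200 bp
  gene2 <- mutate_exact(substr(ref, 20001, 21000), 80)  # planted 92.0%
  gene3 <- random_dna(900, gc = 0.6)            # absent
  q <- paste0(random_dna(500, .6), gene1, random_dna(300, .6), gene2,
              random_dna(300, .6), gene3, random_dna(500, .6))
  f <- data.frame(feature_id = c("g1", "g2", "g3"), kind = "CDS",
                  start = c(501, 501 + 1200 + 300,
                            501 + 1200 + 300 + 1000 + 300),
                  end = c(500 + 1200, 500 + 1200 + 300 + 1000,
                          500 + 1200 + 300 + 1000 + 300 + 900),
                  strand = "+")
  qg <- annotated_genome("q", q, f)
  rec <- classify_genes(f, qg, ref)
  expect_equal(rec$tier[rec$gene_id == "g1"], "distinct_identical")
  expect_equal(rec$tier[rec$gene_id == "g2"], "significant_similarity")
  expect_true(abs(rec$identity_pct[rec$gene_id == "g2"] - 92.0) <= 0.5)
  expect_equal(rec$tier[rec$gene_id == "g3"], "no_similarity")
  # partition is exhaustive and mutually exclusive
  expect_true(all(rec$tier %in% c("distinct_identical", "significant_similarity",
                                  "no_similarity")))
  expect_equal(nrow(rec), 3L)
})

test_that("tier counts are monotone in the identity cutoff", {
  rec <- fixture_records()
  pair <- fixture_pair()
  cds <- pair$genomeA$features[pair$genomeA$features$kind == "CDS", ]
  n99 <- sum(rec$tier == "distinct_identical")
  rec95 <- classify_genes(cds, pair$genomeA, pair$genomeB, identity_min = 95)
  expect_gte(sum(rec95$tier == "distinct_identical"), n99)
})

test_that("classifier identity matches the generator's realized identities", {
  rec <- fixture_records()
  truth <- fixture_pair()$truth$genes
  m <- merge(rec, truth, by.x = "gene_id", by.y = "id")
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(abs(m$identity_pct - m$identity_realized) <= 0.5))
  # near-identical symbiosis genes land in the top tier
  expect_true(all(m$tier[m$identity_realized > 99.2] == "distinct_identical"))
  expect_true(all(m$tier[m$identity_realized < 95] == "significant_similarity"))
})

test_that("identity histogram matches a brute-force binning oracle", {
  rec <- data.frame(gene_id = sprintf("g%d", 1:10), tier = "distinct_identical",
                    identity_pct = rep(100, 10), bit_score = 500,
                    stringsAsFactors = FALSE)
  h <- identity_histogram(rec)
  expect_equal(h$counts[23], 10L)
  expect_equal(sum(h$counts), h$population_size)
  set.seed(72)
  ids <- round(runif(500, 54, 100), 2)
  rec2 <- data.frame(gene_id = sprintf("g%d", 1:500),
                     tier = "significant_similarity",
                     identity_pct = ids, bit_score = 500,
                     stringsAsFactors = FALSE)
  h2 <- identity_histogram(rec2)
  oracle <- table(cut(ids, breaks = seq(54, 100, by = 2),
                      right = FALSE, include.lowest = FALSE))
  # right-open bins except the top one; move exact-100 mass into bin 23
  oracle[23] <- oracle[23] + sum(ids == 100)
  expect_equal(h2$counts, as.integer(oracle))
  expect_equal(sum(h2$counts), 500L)
  # out-of-range identities clamp with a warning
  rec3 <- rbind(rec2, data.frame(gene_id = "low", tier = "significant_similarity",
                                 identity_pct = 40, bit_score = 500))
  expect_warning(h3 <- identity_histogram(rec3), "clamped")
  expect_equal(h3$counts[1], h2$counts[1] + 1L)
})

test_that("tier-1 locus clustering merges runs and respects gaps and wrap", {
  mk <- function(starts, len = 500) {
    n <- length(starts)
    list(features = data.frame(feature_id = sprintf("t%02d", seq_len(n)),
                               kind = "CDS", start = starts,
                               end = starts + len - 1, strand = "+",
                               stringsAsFactors = FALSE),
         records = data.frame(gene_id = sprintf("t%02d", seq_len(n)),
                              tier = "distinct_identical",
                              stringsAsFactors = FALSE))
  }
  # 20 genes within 100 kb, gaps < 25 kb -> one locus
  x <- mk(seq(10000, 105000, by = 5000))
  loci <- cluster_tier1_loci(x$records, x$features, 500000)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$gene_count, 20L)
  # two clusters separated by more than max_gap
  y <- mk(c(seq(10000, 20000, by = 5000), seq(200000, 210000, by = 5000)))
  loci2 <- cluster_tier1_loci(y$records, y$features, 500000)
  expect_equal(nrow(loci2), 2L)
  # singletons below min_genes are dropped
  z <- mk(c(10000, 200000, 400000))
  expect_equal(nrow(cluster_tier1_loci(z$records, z$features, 500000)), 0L)
  # a locus wrapping the origin is stitched across the seam
  w <- mk(c(495000, 499000, 2000, 6000), len = 800)
  lw <- cluster_tier1_loci(w$records, w$features, 500000)
  expect_equal(nrow(lw), 1L)
  expect_true(lw$wraps)
  expect_equal(lw$gene_count, 4L)
  expect_equal(lw$start, 495000)
  expect_equal(lw$end, 6799)
})

test_that("fixture loci recover the planted symbiosis gene clusters", {
  pair <- fixture_pair()
  rec <- fixture_records()
  cds <- pair$genomeA$features[pair$genomeA$features$kind == "CDS", ]
  loci <- cluster_tier1_loci(rec, cds, pair$genomeA$length)
  truth <- pair$truth
  frag_of <- function(nm) truth$symbiosis$fragments[
    truth$symbiosis$fragments$name == nm, ]
  expect_gte(nrow(loci), 3L)
  # each planted fragment is covered by exactly one locus
  for (nm in c("A", "B", "C")) {
    fr <- frag_of(nm)
    hit <- loci$start <= fr$end & loci$end >= fr$start
    expect_equal(sum(hit), 1L, label = paste("fragment", nm))
  }
})
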