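# Hand-built miniature genome: one tRNA with a planted 3'-suffix duplication
# closing a low-GC island a known distance downstream.
build_island_genome <- function(island_len = 3000, dup = 47, strand = "+",
                                trna_len = 76, L = 30000, trna_at = 10000,
                                island_gc = 50, bg_gc = 65) {
  trna <- random_dna(trna_len, gc = 0.55)
  body <- random_dna(island_len - dup, gc = island_gc / 100)
  # force a mismatch right before the duplication so its length is exact
  pre <- substr(trna, trna_len - dup, trna_len - dup)
  substr(body, nchar(body), nchar(body)) <- setdiff(c("A", "C", "G", "T"), pre)[1]
  content <- paste0(body, substr(trna, trna_len - dup + 1, trna_len))
  s <- random_dna(L, gc = bg_gc / 100)
  if (strand == "+") {
    s <- write_at_test(s, trna_at, trna)
    s <- write_at_test(s, trna_at + trna_len, content)
    tf <- c(trna_at, trna_at + trna_len - 1)
  } else {
    s <- write_at_test(s, trna_at, revcomp(trna))
    s <- write_at_test(s, trna_at - island_len, revcomp(content))
    tf <- c(trna_at, trna_at + trna_len - 1)
  }
  f <- data.frame(feature_id = "tX", kind = "tRNA", start = tf[1], end = tf[2],
                  strand = strand, product = "tRNA-Xxx", anticodon = "NNN")
  g <- annotated_genome("mini", s, f)
  # scrub chance copies of the scan suffix outside the plant
  list(genome = g, trna = trna)
}

test_that("a planted suffix duplication delimits one island exactly", {
  set.seed(61)
  for (strand in c("+", "-")) {
    bi <- build_island_genome(island_len = 3000, dup = 47, strand = strand)
    isl <- find_trna_anchored_islands(bi$genome)
    expect_equal(nrow(isl), 1L, info = strand)
    expect_equal(isl$duplication_length, 47L)
    expect_equal(isl$length, 3000L)
    expect_equal(isl$nesting_index, 1L)
    if (strand == "+") {
      expect_equal(isl$left_end, 10000L + 76L)
      expect_equal(isl$right_end, 10000L + 76L + 2999L)
    } else {
      expect_equal(isl$right_end, 10000L - 1L)
      expect_equal(isl$left_end, 10000L - 3000L)
    }
  }
})

test_that("a 13-bp duplication is below the 14-bp floor and not reported", {
  set.seed(62)
  bi <- build_island_genome(island_len = 2000, dup = 13)
  isl <- find_trna_anchored_islands(bi$genome, min_dup = 14)
  expect_equal(nrow(isl), 0L)
  # the same plant clears a 13-bp floor
  isl13 <- find_trna_anchored_islands(bi$genome, min_dup = 13)
  expect_equal(nrow(isl13), 1L)
})

test_that("islands above the GC filter are dropped unless the filter is off", {
  set.seed(63)
  bi <- build_island_genome(island_len = 3000, dup = 40, island_gc = 72,
                            bg_gc = 65)
  expect_equal(nrow(find_trna_anchored_islands(bi$genome)), 0L)
  expect_equal(nrow(find_trna_anchored_islands(bi$genome, gc_filter = FALSE)), 1L)
})

test_that("stacked islands tile the anchor with correct nesting on the fixture", {
  isl <- fixture_islands()
  tr <- fixture_pair()$truth$islands
  expect_equal(nrow(isl), nrow(tr))
  key <- function(d) d[order(d$left_end), ]
  isl <- key(isl); tr <- key(tr)
  expect_equal(isl$left_end, tr$left_end)
  expect_equal(isl$right_end, tr$right_end)
  expect_equal(isl$duplication_length, tr$dup_length)
  expect_equal(isl$nesting_index, tr$nesting_index)
  expect_equal(isl$integrase_locus, tr$integrase_locus)
  # stacked islands are contiguous: next left end = previous duplication end + 1
  for (a in unique(isl$anchor_id)) {
    sub <- isl[isl$anchor_id == a, ]
    sub <- sub[order(sub$nesting_index), ]
    if (nrow(sub) > 1)
      expect_equal(sub$left_end[-1], head(sub$right_end, -1) + 1L)
  }
  # every reported island sits below the genome's mean GC (filter invariant)
  expect_true(all(isl$gc_pct < gc_fraction(fixture_pair()$genomeA)))
})

test_that("low-GC candidates require depressed GC, length, and no duplication", {
  set.seed(64)
  L <- 60000
  s <- random_dna(L, gc = 0.65)
  trna <- random_dna(76, gc = 0.55)
  s <- write_at_test(s, 20000, trna)
  s <- write_at_test(s, 20076, random_dna(30000, gc = 0.50))
  f <- data.frame(feature_id = "tC", kind = "tRNA", start = 20000, end = 20075,
                  strand = "+", product = "tRNA-Can", anticodon = "NNN")
  g <- annotated_genome("cand", s, f)
  cand <- find_candidate_low_gc_islands(g, gc_margin = 2, min_len = 10000,
                                        window = 5000)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$start, 20076L)
  expect_true(abs(cand$length - 30000) <= 5000)
  expect_lt(cand$gc_pct, gc_fraction(g) - 2)
  # planting a terminal duplication flips it to a typical island
  dup <- substr(trna, 77 - 47, 76)
  s2 <- write_at_test(s, 20076 + 30000 - 47, dup)
  g2 <- annotated_genome("cand2", s2, f)
  expect_equal(nrow(find_candidate_low_gc_islands(g2, gc_margin = 2,
                                                  min_len = 10000,
                                                  window = 5000)), 0L)
  expect_equal(nrow(find_trna_anchored_islands(g2)), 1L)
  # a uniform-GC genome yields nothing
  su <- write_at_test(random_dna(L, gc = 0.65), 20000, trna)
  gu <- annotated_genome("uni", su, f)
  expect_equal(nrow(find_candidate_low_gc_islands(gu)), 0L)
})

test_that("partial tRNA copies: exact scan, strand conventions, self-exclusion", {
  set.seed(65)
  L <- 50000
  trna <- random_dna(76, gc = 0.55)
  s <- random_dna(L, gc = 0.63)
  s <- write_at_test(s, 30000, trna)  # the intact gene
  suffix45 <- substr(trna, 76 - 44, 76)
  s <- write_at_test(s, 8000, revcomp(suffix45))       # minus-strand relic
  # guard both flanks so the match length is exactly 45
  pre <- substr(trna, 76 - 45, 76 - 45)
  s <- write_at_test(s, 8045, setdiff(c("A", "C", "G", "T"), revcomp(pre))[1])
  g <- annotated_genome("par", s)
  hits <- find_partial_trna_copies(g, trna, min_len = 45)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  expect_gt(hits$start, hits$end)  # descending-coordinate convention
  expect_equal(hits$end, 8000L)
  expect_equal(hits$length, 45L)
  # nothing planted -> the intact gene is excluded -> empty
  s0 <- write_at_test(random_dna(L, gc = 0.63), 30000, trna)
  expect_equal(nrow(find_partial_trna_copies(annotated_genome("p0", s0), trna)),
               0L)
  expect_error(find_partial_trna_copies(g, substr(trna, 1, 40), min_len = 45),
               "longer than min_len")
})

test_that("split symbiosis island is reassembled from joint evidence", {
  pair <- fixture_pair()
  gA <- pair$genomeA
  truth <- pair$truth
  isl <- fixture_islands()
  copies <- fixture_is_copies()
  cds <- gA$features[gA$features$kind == "CDS", ]
  rec <- fixture_records()
  loci <- cluster_tier1_loci(rec, cds, gA$length)
  symb <- assemble_symbiosis_islands(gA, isl, copies, loci,
                                     truth$symbiosis$anchor)
  expect_s3_class(symb, "symbiosis_island_set")
  expect_true(symb$complete)
  expect_equal(sort(symb$fragments$name[symb$fragments$kept]), c("A", "B", "C"))
  tf <- truth$symbiosis$fragments
  for (nm in c("A", "B", "C")) {
    got <- symb$fragments[symb$fragments$name == nm, ]
    want <- tf[tf$name == nm, ]
    expect_lte(abs(got$start - want$start), 5000, label = paste("frag", nm, "start"))
    expect_lte(abs(got$end - want$end), 5000, label = paste("frag", nm, "end"))
    expect_gte(got$evidence_n, 2)
  }
  # the partial trnV relic is found where it was planted
  expect_equal(symb$partial_trnv_hits$start[1], truth$symbiosis$partial$start)
  expect_equal(symb$partial_trnv_hits$strand[1], "-")
  expect_true(abs(symb$total_kb - sum(tf$length) / 1000) <= 11)
  expect_error(assemble_symbiosis_islands(gA, isl, copies, loci, "NOPE"),
               "not found")
})

test_that("degenerate evidence yields a partial result, not an error", {
  pair <- fixture_pair()
  gA <- pair$genomeA
  isl <- fixture_islands()
  no_copies <- map_is_copies(gA, list(is_family("ISNone", random_dna(1200))))
  symb <- assemble_symbiosis_islands(gA, isl, no_copies, NULL,
                                     pair$truth$symbiosis$anchor)
  expect_false(symb$complete)
  expect_true(nrow(symb$fragments) >= 1)  # evidence report retained
})
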