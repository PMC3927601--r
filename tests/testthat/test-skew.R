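test_that("per-window skew equals direct counting and handles edge cases", {
  g <- annotated_genome("gg", strrep("G", 500))
  p <- gc_skew_profile(g, window = 100, step = 100)
  expect_true(all(p$values$skew == 1))
  g2 <- annotated_genome("gc", strrep("GC", 250))
  p2 <- gc_skew_profile(g2, window = 100, step = 100)
  expect_true(all(p2$values$skew == 0))
  set.seed(13)
  s <- random_dna(20000, gc = 0.6)
  g3 <- annotated_genome("r", s)
  p3 <- gc_skew_profile(g3, window = 1000, step = 500)
  v <- strsplit(s, "")[[1]]
  vv <- c(v, v)  # circular wrap
  for (i in c(1, 7, 20, nrow(p3$values))) {
    st <- 1 + (i - 1) * 500
    win <- vv[st:(st + 999)]
    gcount <- sum(win == "G"); ccount <- sum(win == "C")
    expect_equal(p3$values$skew[i], (gcount - ccount) / (gcount + ccount))
  }
  # cumulative track ends at the genome's total G - C
  expect_equal(tail(p3$cumulative$cum_gc, 1), sum(v == "G") - sum(v == "C"))
  expect_error(gc_skew_profile(g, window = 10000), "window larger")
})

test_that("skew shifts localise planted arc boundaries; flat profiles refuse", {
  pair <- fixture_pair()
  prof <- gc_skew_profile(pair$genomeA)
  sh <- find_skew_shifts(prof)
  expect_true(sh$detected)
  L <- pair$truth$genome_length
  circ_dist <- function(a, b) min((a - b) %% L, (b - a) %% L)
  expect_lte(circ_dist(sh$origin, pair$truth$skew$origin), prof$window)
  expect_lte(circ_dist(sh$terminus, pair$truth$skew$terminus), prof$window)
  # origin and terminus approximately antipodal on a two-arc genome
  expect_lt(abs(circ_dist(sh$origin, sh$terminus) - L / 2), 2 * prof$window)
  # a structureless profile yields an explicit no-shift result
  flat <- annotated_genome("flat", strrep("GC", 5000))
  shf <- find_skew_shifts(gc_skew_profile(flat, window = 500, step = 500))
  expect_false(shf$detected)
  expect_true(is.na(shf$origin))
})

test_that("find_motif equals the exhaustive scan and reports strands", {
  set.seed(23)
  s <- random_dna(30000, gc = 0.55)
  motif <- "GGTGCGCATAATGTATATTATGTTAAAT"
  s <- write_at_test(s, 5000, motif)
  s <- write_at_test(s, 12000, revcomp(motif))
  g <- annotated_genome("m", s)
  hits <- find_motif(g, motif, max_mismatches = 2)
  plus <- hits[hits$strand == "+" & hits$mismatches == 0, ]
  minus <- hits[hits$strand == "-" & hits$mismatches == 0, ]
  expect_true(5000 %in% plus$start)
  expect_true(12000 %in% minus$start)
  # oracle: exhaustive Hamming scan on both strands of the doubled sequence
  ham_scan <- function(seq, pat, kmax) {
    L <- nchar(seq); m <- nchar(pat)
    ch <- strsplit(paste0(seq, substr(seq, 1, m - 1)), "")[[1]]
    pv <- strsplit(pat, "")[[1]]
    mm <- rep(0L, L)
    for (j in seq_len(m)) mm <- mm + (ch[seq_len(L) + j - 1] != pv[j])
    which(mm <= kmax)
  }
  oracle <- sort(unique(c(ham_scan(s, motif, 2), ham_scan(s, revcomp(motif), 2))))
  expect_setequal(hits$start, oracle)
  # ranked by distance then coordinate
  expect_true(all(diff(hits$mismatches) >= 0))
  expect_error(find_motif(g, "ACGTQQ"), "non-IUPAC")
})

test_that("origin intergenic alignment reports identity of the conserved spacer", {
  set.seed(31)
  mk <- function(inter) {
    s <- random_dna(5000, gc = 0.6)
    s <- write_at_test(s, 1001, strrep("A", 400))  # anchor gene L placeholder
    s <- write_at_test(s, 1401, inter)
    s <- write_at_test(s, 1401 + nchar(inter), strrep("T", 400))
    f <- data.frame(feature_id = c("gL", "gR"), kind = "CDS",
                    start = c(1001, 1401 + nchar(inter)),
                    end = c(1400, 1800 + nchar(inter)), strand = "+")
    annotated_genome("og", s, f)
  }
  inter <- random_dna(391, gc = 0.6)
  gA <- mk(inter)
  res0 <- locate_origin_intergenic(gA, gA, list(A = c("gL", "gR"), B = c("gL", "gR")))
  expect_equal(res0$identity_pct, 100)
  expect_equal(res0$aligned_length, 391L)
  # partner spacer mutated at exactly 18% of positions -> ~82% identity
  gB <- mk(mutate_exact(inter, round(0.18 * 391)))
  res <- locate_origin_intergenic(gA, gB, list(A = c("gL", "gR"), B = c("gL", "gR")))
  expect_true(abs(res$identity_pct - 82) <= 2)
  # unrelated spacers: nothing significant
  gC <- mk(random_dna(391, gc = 0.6))
  res2 <- locate_origin_intergenic(gA, gC, list(A = c("gL", "gR"), B = c("gL", "gR")))
  expect_true(is.null(res2$alignment) || res2$alignment$evalue > 1e-6)
  expect_error(locate_origin_intergenic(gA, gB, list(A = c("gL", "nope"),
                                                     B = c("gL", "gR"))),
               "nope")
})
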