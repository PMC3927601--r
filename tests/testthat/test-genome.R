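test_that("circular intervals: length, wrapping and rendering", {
  ivl <- circular_interval(10, 20)
  expect_equal(interval_length(ivl), 11L)
  w <- circular_interval(95, 5, wraps = TRUE)
  expect_equal(interval_length(w, genome_length = 100), 11L)
  expect_equal(format(w), "95-0-5")
  expect_error(circular_interval(20, 10), "end < start")
  # wrapped + complementary interval lengths tile the circle
  comp <- circular_interval(6, 94)
  expect_equal(interval_length(w, 100) + interval_length(comp, 100), 100L)
})

test_that("gc_fraction matches a brute-force per-base tally", {
  expect_equal(gc_fraction("GGCC"), 100)
  expect_equal(gc_fraction("ATAT"), 0)
  set.seed(11)
  s <- random_dna(10000, gc = 0.62)
  v <- strsplit(s, "")[[1]]
  expect_equal(gc_fraction(s), round(100 * mean(v %in% c("G", "C")), 2))
  # N counts to length but not to GC
  expect_equal(gc_fraction("GGNN"), 100)
  g <- annotated_genome("x", s)
  expect_equal(gc_fraction(g, circular_interval(11, 250)),
               round(100 * mean(v[11:250] %in% c("G", "C")), 2))
  # wrapped interval
  expect_equal(gc_fraction(g, circular_interval(9990, 10, wraps = TRUE)),
               round(100 * mean(v[c(9990:10000, 1:10)] %in% c("G", "C")), 2))
  expect_error(gc_fraction(g, circular_interval(20000, 20010)), "outside")
})

test_that("feature validation catches bad tables", {
  s <- random_dna(1000)
  f <- data.frame(feature_id = c("a", "a"), kind = "CDS", start = 1,
                  end = 10, strand = "+")
  expect_error(annotated_genome("x", s, f), "duplicate locus tags")
  f2 <- data.frame(feature_id = "b", kind = "CDS", start = 1, end = 2000,
                   strand = "+")
  expect_error(annotated_genome("x", s, f2), "outside sequence")
  expect_error(annotated_genome("x", "ACGTQ"), "outside")
})

test_that("rotation is invertible and preserves genome properties", {
  set.seed(5)
  s <- random_dna(5000, gc = 0.6)
  f <- data.frame(feature_id = c("g1", "g2"), kind = "CDS",
                  start = c(100, 4800), end = c(400, 4950),
                  strand = c("+", "-"))
  g <- annotated_genome("rot", s, f)
  k <- 1234L
  g2 <- rotate_genome(g, k)
  expect_equal(g2$length, g$length)
  expect_equal(gc_fraction(g2), gc_fraction(g))
  # feature lengths preserved
  len <- function(gn) ifelse(gn$features$wraps,
                             gn$length - gn$features$start + 1 + gn$features$end,
                             gn$features$end - gn$features$start + 1)
  expect_equal(sort(len(g2)), sort(len(g)))
  # digestion fragment multiset invariant under rotation
  expect_equal(sort(digest(g2, list("PmeI", "SwaI"))$length_bp),
               sort(digest(g, list("PmeI", "SwaI"))$length_bp))
  # inverse rotation recovers the original coordinates
  g3 <- rotate_genome(g2, g$length - k + 2L)
  expect_equal(g3$sequence, g$sequence)
  expect_equal(g3$features$start, g$features$start)
})

test_that("set_origin_at_site renumbers at the chosen occurrence", {
  set.seed(9)
  body <- gsub("TTAATTAA", "TTAATTGA", random_dna(4000))  # scrub chance sites
  s <- paste0(substr(body, 1, 1000), "TTAATTAA",
              substr(body, 1001, 3000), "TTAATTAA",
              substr(body, 3001, 4000))
  g <- annotated_genome("pac", s)
  r1 <- set_origin_at_site(g, "TTAATTAA")
  expect_equal(substr(r1$sequence, 1, 8), "TTAATTAA")
  r2 <- set_origin_at_site(g, "TTAATTAA", index = 2)
  expect_equal(substr(r2$sequence, 1, 8), "TTAATTAA")
  expect_false(identical(r1$sequence, r2$sequence))
  expect_equal(gc_fraction(r2), gc_fraction(g))
  expect_error(set_origin_at_site(g, "GCGCGCGC"), "not found")
  expect_error(set_origin_at_site(g, "TTAATTAA", index = 5), "only 2")
})
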