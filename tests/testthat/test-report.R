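test_that("full comparison report reproduces the truth ledger counts", {
  spec <- small_world_spec(seed = 31)
  pair <- generate_pair(spec)
  out <- file.path(tempdir(), "run1")
  cfg <- run_config(pair$genomeA, pair$genomeB, out_dir = out, seed = 31)
  suppressMessages(
    rep1 <- run_full_comparison(cfg, is_families = pair$is_families))
  truth <- pair$truth
  expect_equal(rep1$islands$n_typical, nrow(truth$islands))
  expect_equal(rep1$is_atlas$n_copies, nrow(truth$is_copies))
  expect_equal(rep1$digest$total_bp, truth$genome_length)
  expect_true(rep1$replication$detected)
  expect_lte(min(abs(rep1$replication$origin - truth$skew$origin),
                 truth$genome_length -
                   abs(rep1$replication$origin - truth$skew$origin)),
             cfg$window)
  expect_equal(rep1$replication$dif_best$start, truth$dif$start)
  # tier counts re-derivable from realized identities (bit floor is cleared
  # by every planted gene, so tiers depend on identity alone)
  want_top <- sum(truth$genes$identity_realized > 99)
  got_top <- rep1$conservation$tiers$distinct_identical
  expect_equal(if (is.null(got_top)) 0L else got_top, want_top)
  # artifacts exist
  for (f in c("fragments_a.tsv", "skew_a.tsv", "islands_a.tsv",
              "is_copies_a.tsv", "conservation.tsv", "summary.json"))
    expect_true(file.exists(file.path(out, f)), label = f)
})

test_that("reruns are byte-identical and single-genome runs degrade politely", {
  spec <- small_world_spec(seed = 31)
  pair <- generate_pair(spec)
  out2 <- file.path(tempdir(), "run2")
  cfg2 <- run_config(pair$genomeA, pair$genomeB, out_dir = out2, seed = 31)
  suppressMessages(run_full_comparison(cfg2, is_families = pair$is_families))
  out1 <- file.path(tempdir(), "run1")
  if (file.exists(file.path(out1, "summary.json")))
    expect_identical(readLines(file.path(out1, "summary.json")),
                     readLines(file.path(out2, "summary.json")))
  # degraded mode: no partner genome -> conservation stage skipped, named
  out3 <- file.path(tempdir(), "run3")
  cfg3 <- run_config(pair$genomeA, out_dir = out3)
  msgs <- capture.output(
    rep3 <- run_full_comparison(cfg3), type = "message")
  expect_true(any(grepl("conserve.*skipped", msgs)))
  expect_null(rep3$conservation)
  expect_false(file.exists(file.path(out3, "conservation.tsv")))
})

test_that("CLI subcommands run end to end through the dispatcher", {
  spec <- small_world_spec(seed = 33)
  pair <- generate_pair(spec)
  gb <- tempfile(fileext = ".gb")
  write_genbank(pair$genomeA, gb)
  # convert
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  st <- islandscout_cli(c("convert", "--in", gb, "--out", fa,
                          "--features", gff))
  expect_equal(st, 0L)
  expect_true(file.exists(fa) && file.exists(gff))
  # digest
  tsv <- tempfile(fileext = ".tsv")
  st2 <- islandscout_cli(c("digest", "--genome", gb, "--enzymes", "PmeI,SwaI",
                           "--out", tsv))
  expect_equal(st2, 0L)
  tab <- read.table(tsv, header = TRUE, sep = "\t")
  expect_equal(sum(tab$length_bp), pair$genomeA$length)
  # islands
  itsv <- tempfile(fileext = ".tsv")
  st3 <- islandscout_cli(c("islands", "--genome", gb, "--out", itsv))
  expect_equal(st3, 0L)
  itab <- read.table(itsv, header = TRUE, sep = "\t")
  expect_equal(nrow(itab), nrow(pair$truth$islands))
  # an unknown subcommand fails with non-zero status
  expect_equal(suppressMessages(islandscout_cli("frobnicate")), 1L)
})
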