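nt_oracle_matrix <- local({
  m <- matrix(-3, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  diag(m) <- 2
  m
})

# Independent exhaustive DP oracle (Biostrings implementation).
oracle_score <- function(a, b, scheme = scoring_scheme("nucleotide")) {
  mat <- if (scheme$mode == "nucleotide") nt_oracle_matrix else "BLOSUM62"
  max(0, Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE))
}

test_that("identical sequences give one full-cover, 100%-identity alignment", {
  set.seed(51)
  s <- random_dna(1000, gc = 0.5)
  h <- align_local(s, s)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity_pct, 100)
  expect_equal(c(h$q_start, h$q_end), c(1L, 1000L))
  expect_equal(c(h$s_start, h$s_end), c(1L, 1000L))
  expect_equal(h$raw_score, 2000L)
  expect_lt(h$evalue, 1e-100)
  expect_error(align_local("", s), "non-empty")
  expect_error(align_local("MKVL", s, scoring_scheme("nucleotide")), "not a DNA")
})

test_that("internal engine equals the exhaustive DP oracle on short pairs", {
  set.seed(52)
  for (i in 1:80) {
    a <- random_dna(sample(5:30, 1))
    b <- random_dna(sample(5:30, 1))
    h <- align_local(a, b, both_strands = FALSE)
    mine <- if (nrow(h)) h$raw_score[1] else 0
    expect_equal(mine, oracle_score(a, b), info = paste(a, b))
  }
})

test_that("ungapped optimal score is symmetric under query/subject swap", {
  set.seed(53)
  sch <- scoring_scheme("nucleotide", gap_open = 1000L)  # gaps priced out
  for (i in 1:20) {
    a <- random_dna(sample(10:25, 1)); b <- random_dna(sample(10:25, 1))
    ha <- align_local(a, b, sch, both_strands = FALSE)
    hb <- align_local(b, a, sch, both_strands = FALSE)
    sa <- if (nrow(ha)) ha$raw_score[1] else 0
    sb <- if (nrow(hb)) hb$raw_score[1] else 0
    expect_equal(sa, sb)
  }
})

test_that("extra substitutions never increase the optimal score", {
  set.seed(54)
  for (i in 1:15) {
    a <- random_dna(25)
    bv <- strsplit(a, "")[[1]]
    prev <- align_local(a, a, both_strands = FALSE)$raw_score[1]
    # substitute fresh positions only, never back towards the original base
    for (p in sample(25, 5)) {
      bv[p] <- setdiff(c("A", "C", "G", "T"), substr(a, p, p))[sample.int(3, 1)]
      h <- align_local(a, paste(bv, collapse = ""), both_strands = FALSE)
      cur <- if (nrow(h)) h$raw_score[1] else 0
      expect_lte(cur, prev)
      prev <- cur
    }
  }
})

test_that("unrelated long sequences produce no significant alignment", {
  set.seed(55)
  a <- random_dna(10000); b <- random_dna(10000)
  h <- align_local(a, b)
  expect_true(nrow(h) == 0 || min(h$evalue) > 1e-20)
})

test_that("best_hit ranking and cutoffs behave per the tie rules", {
  set.seed(56)
  db <- lapply(1:5, function(i) list(id = paste0("s", i), seq = random_dna(300)))
  q <- db[[3]]$seq
  b <- best_hit(q, db)
  expect_equal(b$subject_id, "s3")
  # exact tie: duplicate the target later in the database; earlier wins
  db2 <- c(db, list(list(id = "dup", seq = db[[3]]$seq)))
  b2 <- best_hit(q, db2)
  expect_equal(b2$subject_id, "s3")
  # absent query -> none under a strict cutoff
  expect_null(best_hit(random_dna(300), db, evalue_cutoff = 1e-10))
})

test_that("E-value decreases as bit score increases for a fixed search space", {
  sch <- scoring_scheme("nucleotide")
  bits <- seq(20, 200, by = 20)
  ev <- vapply(bits, function(b) islandscout:::evalue_of(b, 1000, 1e6), 1)
  expect_true(all(diff(ev) < 0))
})

test_that("internal engine agrees with installed BLAST+ on planted identities", {
  # parity harness; blastn ships in this toolchain
  set.seed(57)
  qf <- tempfile(fileext = ".fa"); sf <- tempfile(fileext = ".fa")
  ref <- random_dna(800, gc = 0.6)
  muts <- c(0, 40, 100)  # 100 / 95 / 87.5 percent planted identity
  qs <- vapply(muts, function(k) if (k == 0) ref else mutate_exact(ref, k), "")
  writeLines(c(rbind(paste0(">q", seq_along(qs)), qs)), qf)
  writeLines(c(">ref", ref), sf)
  ext <- tryCatch(external_blast_adapter(qf, sf, "nucleotide",
                                         extra_args = c("-dust", "no")),
                  error = function(e) e)
  if (inherits(ext, "error")) {
    expect_match(conditionMessage(ext), "optional dependency")
  } else {
    for (i in seq_along(qs)) {
      mine <- align_local(qs[i], ref)[1, ]
      theirs <- ext[ext$query_id == paste0("q", i), ][1, ]
      expect_lt(abs(mine$identity_pct - theirs$identity_pct), 1.0)
    }
  }
})
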