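rand_prot <- function(n) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

test_that("identical protein sets map one-to-one; orphans stay unpaired", {
  set.seed(81)
  prots <- setNames(vapply(1:10, function(i) rand_prot(120), ""),
                    sprintf("p%02d", 1:10))
  A <- protein_set("A", prots)
  B <- protein_set("B", prots)
  rbh <- reciprocal_best_hits(A, B)
  expect_equal(nrow(rbh), 10L)
  expect_equal(rbh$id_a, rbh$id_b)
  expect_true(all(rbh$identity_pct == 100))
  # a protein present only in A stays unpaired
  A2 <- protein_set("A", c(prots, orphan = rand_prot(150)))
  rbh2 <- reciprocal_best_hits(A2, B)
  expect_false("orphan" %in% rbh2$id_a)
  expect_equal(nrow(rbh2), 10L)
})

test_that("RBH is symmetric in its arguments", {
  tri <- generate_triple(plan = list(core = 6L, pair_ab = 2L, pair_ac = 0L,
                                     pair_bc = 0L, unique_a = 2L, unique_b = 2L,
                                     unique_c = 0L), seed = 82)
  ab <- reciprocal_best_hits(tri$sets$A, tri$sets$B)
  ba <- reciprocal_best_hits(tri$sets$B, tri$sets$A)
  expect_setequal(paste(ab$id_a, ab$id_b), paste(ba$id_b, ba$id_a))
})

test_that("venn partition handles the degenerate trivial cases", {
  set.seed(83)
  prots <- setNames(vapply(1:5, function(i) rand_prot(100), ""),
                    sprintf("q%d", 1:5))
  vp <- venn_partition(protein_set("A", prots), protein_set("B", prots),
                       protein_set("C", prots))
  expect_equal(unname(vp$regions["ABC"]), 5)
  expect_equal(sum(vp$regions), vp$total)
  expect_equal(unname(vp$regions[c("A", "B", "C", "AB", "AC", "BC")]),
               rep(0, 6))
  # mutually unrelated sets: only singleton regions
  mk <- function(g, n, len) protein_set(g, setNames(
    vapply(seq_len(n), function(i) rand_prot(len), ""),
    sprintf("%s%d", g, seq_len(n))))
  vp2 <- venn_partition(mk("A", 3, 90), mk("B", 4, 110), mk("C", 5, 130))
  expect_equal(unname(vp2$regions[c("A", "B", "C")]), c(3, 4, 5))
  expect_equal(unname(vp2$regions["ABC"]), 0)
  expect_equal(vp2$total, 12)
})

test_that("planted triple recovers its Venn structure and RBH pairs exactly", {
  tri <- generate_triple(seed = 84)
  tt <- tri$truth
  vp <- venn_partition(tri$sets$A, tri$sets$B, tri$sets$C)
  expected <- table(tt$span[!duplicated(tt$family)])
  for (r in names(expected))
    expect_equal(unname(vp$regions[r]), unname(as.numeric(expected[r])),
                 label = paste("region", r))
  # planted A-B pairs recovered exactly
  rbh <- reciprocal_best_hits(tri$sets$A, tri$sets$B)
  fam_ab <- tt[tt$genome %in% c("A", "B") & grepl("A", tt$span) &
               grepl("B", tt$span), ]
  want <- vapply(split(fam_ab, fam_ab$family), function(d)
    paste(d$id[d$genome == "A"], d$id[d$genome == "B"]), "")
  expect_setequal(paste(rbh$id_a, rbh$id_b), unname(want))
})

test_that("single-linkage closure: chains merge, and the igraph route equals union-find", {
  set.seed(85)
  # explicit chain: a ~ b, b ~ c, a !~ c
  base <- rand_prot(200)
  b <- mutate_exact_prot(base, 60)    # 70% to base
  c_ <- mutate_exact_prot(b, 60)      # 70% to b, ~52% to base
  sets <- list(protein_set("G1", c(pa = base)),
               protein_set("G2", c(pb = b)),
               protein_set("G3", c(pc = c_)))
  cl <- single_linkage_clusters(sets)
  expect_equal(length(cl$clusters), 1L)
  expect_equal(nrow(cl$clusters[[1]]), 3L)
  expect_true(cl$single_copy[1])
  # seeded families across 3 genomes: compare with an independent
  # pairwiseAlignment + union-find oracle
  tri <- generate_triple(plan = list(core = 5L, pair_ab = 3L, pair_ac = 2L,
                                     pair_bc = 2L, unique_a = 3L, unique_b = 2L,
                                     unique_c = 2L, family_identity = 85),
                         seed = 86)
  cl2 <- single_linkage_clusters(tri$sets)
  tab <- do.call(rbind, lapply(tri$sets, function(ps)
    data.frame(g = ps$genome_id, id = names(ps$proteins),
               seq = unname(ps$proteins))))
  node <- paste0(tab$g, "|", tab$id)
  ef <- character(); et <- character()
  for (i in seq_len(nrow(tab) - 1)) for (j in (i + 1):nrow(tab)) {
    pa <- Biostrings::pairwiseAlignment(tab$seq[i], tab$seq[j], type = "local",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 11, gapExtension = 1)
    alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
    ident <- Biostrings::pid(pa, type = "PID1")
    cov <- alen / pmin(nchar(tab$seq[i]), nchar(tab$seq[j]))
    if (ident >= 60 && cov >= 0.7) { ef <- c(ef, node[i]); et <- c(et, node[j]) }
  }
  oracle <- uf_components(node, ef, et)
  mine <- lapply(cl2$clusters, function(d) paste0(d$genome_id, "|", d$id))
  expect_equal(canon_partition(mine), canon_partition(oracle))
  # tightening the identity threshold only refines the partition
  cl3 <- single_linkage_clusters(tri$sets, min_identity = 90)
  expect_gte(length(cl3$clusters), length(cl2$clusters))
  # every tighter cluster sits inside exactly one looser cluster
  loose <- lapply(cl2$clusters, function(d) paste0(d$genome_id, "|", d$id))
  for (tight in lapply(cl3$clusters, function(d) paste0(d$genome_id, "|", d$id))) {
    inside <- vapply(loose, function(lv) all(tight %in% lv), logical(1))
    expect_equal(sum(inside), 1L)
  }
})
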