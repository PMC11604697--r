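test_that("rank-sum test: exact enumeration regime and tie handling", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)   # 2 * 1/6 over C(4,2) labellings
  expect_equal(r$method, "exact")

  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.9)                         # identical multisets
  expect_equal(same$method, "normal_approx")     # ties force the approximation

  set.seed(21)
  shifted <- rank_sum_test(rnorm(40, 2), rnorm(40, 0))
  expect_lt(shifted$p, 0.05)

  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum exact and normal approximation agree closely at n1 = n2 = 10", {
  set.seed(22)
  for (i in 1:20) {
    x <- rnorm(10); y <- rnorm(10)
    p_apx <- rank_sum_test(x, y)$p               # n = 20: approximation path
    p_ex <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE)$p.value)
    expect_lte(abs(p_apx - p_ex), 0.02)
  }
})

test_that("expression comparison reports direction and handles missing genes", {
  expr <- data.frame(gene_id = sprintf("g%d", 1:6),
                     tpm = c(7, 7, 7, 0, 0, 0))
  res <- expression_contact_comparison(expr, c("g1", "g2", "g3"))
  expect_equal(res$direction, "connected_higher")
  expect_lt(res$p_two_sided, 0.05)
  expect_lt(res$p_greater, res$p_two_sided)

  expect_warning(
    res2 <- expression_contact_comparison(expr, c("g1", "g2", "g3", "gZ")),
    "absent"
  )
  expect_equal(res2$n_connected, 3L)
  expect_error(expression_contact_comparison(expr, character(0)), "empty")
})

test_that("chromatin-state enrichment matches the closed form and conserves mass", {
  genome_size <- 100000
  seg <- granges_from_bed("chr1", c(0, 5000), c(5000, 100000),
                          name = c("Enh", "Quies"))
  seg$state <- seg$name
  # query wholly inside a state covering 5% of the genome: fold 20
  q <- granges_from_bed("chr1", 1000, 2000)
  e <- chromhmm_enrichment(q, seg, genome_size)
  expect_equal(e$fold[e$state == "Enh"], 20)
  expect_equal(e$log2_fold[e$state == "Enh"], log2(1 / 0.05), tolerance = 1e-9)
  expect_equal(e$log2_fold[e$state == "Quies"], -Inf)

  # half in the 5% state: fold 10
  q2 <- granges_from_bed("chr1", 4500, 5500)
  e2 <- chromhmm_enrichment(q2, seg, genome_size)
  expect_equal(e2$fold[e2$state == "Enh"], 10)
  expect_equal(e2$log2_fold[e2$state == "Enh"], log2(10), tolerance = 1e-9)

  # query proportional to state coverage: log2 fold 0 everywhere
  q3 <- granges_from_bed("chr1", c(0, 5000), c(100, 6900))
  e3 <- chromhmm_enrichment(q3, seg, genome_size)
  expect_equal(e3$log2_fold, c(0, 0), tolerance = 1e-9)

  # conservation: folds weighted by state fraction of the covered genome sum to 1
  covered <- sum(e2$state_bp)
  w <- e2$state_bp / covered
  folds_cov <- chromhmm_enrichment(q2, seg, covered)$fold
  expect_equal(sum(w * folds_cov), 1, tolerance = 1e-9)

  expect_error(chromhmm_enrichment(GenomicRanges::GRanges(), seg, genome_size), "empty")
})

test_that("gene-set overlap test equals the exact hypergeometric tail", {
  universe <- sprintf("u%02d", 1:20)
  hits <- universe[1:5]
  reference <- universe[c(1, 2, 3, 10)]    # overlap 3
  r <- geneset_overlap_test(hits, reference, universe)
  expect_equal(r$overlap, 3L)
  # manual combinatorics: P[X >= 3] with X ~ Hypergeom(N=20, K=4, n=5)
  p_manual <- (choose(4, 3) * choose(16, 2) + choose(4, 4) * choose(16, 1)) / choose(20, 5)
  expect_equal(r$p, p_manual, tolerance = 1e-12)
  expect_equal(sum(r$table), 20)

  expect_equal(geneset_overlap_test(universe, reference, universe)$p, 1)
  expect_gt(geneset_overlap_test(universe[19:20], universe[1:2], universe)$p, 0.8)
  expect_error(geneset_overlap_test(c("zz"), reference, universe), "subsets")
})

test_that("delta-delta-Ct normalisation maps the reference to 1", {
  ct <- data.frame(sample = c("ref", "kd"), ct_target = c(19, 20),
                   ct_control = c(18, 18))
  r <- qpcr_ddct(ct, "ref")
  expect_equal(r$rel_expr[r$sample == "ref"], 1)
  expect_equal(r$rel_expr[r$sample == "kd"], 0.5)   # ddCt = 1 -> 2^-1

  eq <- data.frame(sample = c("a", "b", "c"), ct_target = c(20, 21, 22),
                   ct_control = c(15, 16, 17))      # equal dCt everywhere
  expect_equal(qpcr_ddct(eq, "a")$rel_expr, c(1, 1, 1))
  ct$ct_control[2] <- NA
  expect_error(qpcr_ddct(ct, "ref"), "control")
})

test_that("paired t test matches the closed form and flags degeneracy", {
  x <- c(10, 12, 11, 13); y <- c(12, 14, 12, 15)   # diffs 2,2,1,2
  r <- paired_t_test(x, y)
  d <- y - x
  expect_equal(r$t, mean(d) / (sd(d) / 2), tolerance = 1e-12)  # 7
  expect_equal(r$p, 2 * pt(-abs(r$t), 3), tolerance = 1e-12)
  expect_equal(r$percent_change, 100 * (mean(y) - mean(x)) / mean(x))
  expect_false(r$degenerate)

  same <- paired_t_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  const <- paired_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))   # all diffs 1
  expect_true(const$degenerate)
  expect_equal(const$p, 0)
  expect_error(paired_t_test(1:3, 1:4), "paired")
})
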