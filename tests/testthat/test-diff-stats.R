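test_that("SAM d at s0 = 0 equals the pooled-variance t statistic", {
  set.seed(2)
  X <- matrix(rnorm(20 * 24), 20, 24)
  rownames(X) <- sprintf("G%02d", 1:20)
  lab <- rep(c(0L, 1L), each = 12)
  d <- sam_statistic(X, lab, s0 = 0)$d
  oracle <- apply(X, 1, function(r)
    t.test(r[lab == 1], r[lab == 0], var.equal = TRUE)$statistic)
  expect_equal(unname(d), unname(oracle), tolerance = 1e-10)
  # constant gene across both classes -> d = 0
  X[1, ] <- 5
  expect_identical(sam_statistic(X, lab, s0 = 0)$d[[1]], 0)
  # scale equivariance: doubling a gene leaves d unchanged at s0 = 0
  X2 <- X; X2[2, ] <- 2 * X2[2, ]
  expect_equal(sam_statistic(X2, lab, s0 = 0)$d[2],
               sam_statistic(X, lab, s0 = 0)$d[2], tolerance = 1e-12)
  expect_error(sam_statistic(X, rep(1L, 24)), "both classes")
})

test_that("sam_fdr recovers planted genes and is seed-reproducible", {
  prep <- small_prepared()
  truth <- small_cohort()$truth
  res <- sam_fdr(prep$layers$ge, prep$labels, n_permutations = 150, seed = 4)
  expect_true(all(res$q_value >= 0 & res$q_value <= 1))
  # q monotone non-increasing in |d|
  ord <- order(abs(res$d), decreasing = TRUE)
  expect_true(all(diff(res$q_value[ord]) >= -1e-12))
  expect_gte(mean(truth$planted_ge %in% res$symbol[res$selected]), 0.9)
  res2 <- sam_fdr(prep$layers$ge, prep$labels, n_permutations = 150, seed = 4)
  expect_identical(res$q_value, res2$q_value)
  # q-values invariant to gene order
  v <- prep$layers$ge$values
  sh <- sample(nrow(v))
  res3 <- sam_fdr(v[sh, ], prep$labels, n_permutations = 150, seed = 4)
  expect_equal(res3$q_value[match(res$symbol, res3$symbol)], res$q_value)
})

test_that("sam_fdr warns when fewer distinct permutations exist than requested", {
  set.seed(8)
  X <- matrix(rnorm(5 * 8), 5, 8)
  lab <- rep(c(0L, 1L), each = 4)
  expect_warning(sam_fdr(X, lab, n_permutations = 100, seed = 1),
                 "distinct permutations")
  expect_error(sam_fdr(X, lab, n_permutations = 50), ">= 100")
})

test_that("fold change and volcano table match hand arithmetic and the Welch oracle", {
  X <- rbind(A = c(8, 8, 8, 2, 2, 2), B = c(3, 3, 3, 3, 3, 3),
             C = c(1, 1, 1, 0, 0, 0))
  colnames(X) <- sprintf("s%d", 1:6)
  lab <- c(1L, 1L, 1L, 0L, 0L, 0L)
  fc <- fold_change(X, lab)
  expect_equal(unname(fc["A"]), 4)          # means 8 vs 2 -> FC 4
  expect_equal(unname(fc["B"]), 1)
  expect_true(is.na(fc["C"]))               # zero denominator -> NA, not Inf
  set.seed(3)
  X2 <- matrix(rnorm(20 * 30, 5), 20, 30)
  lab2 <- rep(c(1L, 0L), 15)
  vt <- volcano_table(X2, lab2, X_test = X2)
  oracle <- apply(X2, 1, function(r) t.test(r[lab2 == 1], r[lab2 == 0])$p.value)
  expect_equal(vt$p_value, unname(oracle), tolerance = 1e-10)
  expect_equal(vt$log2_fc[1], log2(mean(X2[1, lab2 == 1]) / mean(X2[1, lab2 == 0])))
})

test_that("Bonferroni cutoffs reproduce the genome-wide constants", {
  b <- bonferroni_cutoff(21342)
  expect_equal(round(b$neg_log10, 2), 5.63)
  expect_equal(signif(b$per_test_p, 3), 2.34e-6)
  expect_equal(b$per_test_p * b$n_tests, 0.05)   # exact by construction
  b2 <- bonferroni_cutoff(23494)
  expect_equal(round(b2$neg_log10, 2), 5.67)
  expect_equal(round(-log10(2.10e-6), 2), 5.68)  # the rounded printed chain
  expect_equal(bonferroni_cutoff(1)$per_test_p, 0.05)
  expect_error(bonferroni_cutoff(0), "n_tests")
})

test_that("correlation filter selects by |r| with sign symmetry", {
  prep <- small_prepared()
  truth <- small_cohort()$truth
  sel <- correlation_filter(prep$layers$me, prep$layers$ge)
  expect_gte(mean(truth$planted_me %in% sel), 0.95)
  r <- attr(sel, "r")
  # perfect anticorrelation construct
  ge <- omics_matrix(matrix(1:10, 1, 10, dimnames = list("A", paste0("s", 1:10))) * 1.0, "GE")
  lay <- omics_matrix(matrix(seq(1, 0.1, length.out = 10), 1, 10,
                             dimnames = list("A", paste0("s", 1:10))), "ME")
  sel2 <- correlation_filter(lay, ge)
  expect_identical(as.character(sel2), "A")
  expect_equal(unname(attr(sel2, "r")["A"]), -1)
  # negating a layer row flips r but not membership
  neg <- omics_matrix(1 - lay$values, "ME")
  sel3 <- correlation_filter(neg, ge)
  expect_identical(as.character(sel3), "A")
  expect_equal(unname(attr(sel3, "r")["A"]), 1)
})

test_that("an independent ME gene is essentially never selected at n = 141", {
  # null correlation distribution: |r| > 0.5 at n = 141 has p ~ 3e-10
  co <- generate_cohort(null_cohort_config(31))
  prep <- tobsig:::prepare_cohort(co)
  sel <- correlation_filter(prep$layers$me, prep$layers$ge)
  expect_lte(length(sel) / 2000, 0.001)
})
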