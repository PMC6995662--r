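test_that("full-rank PLS equals ordinary least squares on autoscaled data", {
  set.seed(42)
  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- rep(c(0L, 1L), 15)
  fit <- fit_pls(X, y, 5)
  Xs <- scale(X)
  ols <- drop(solve(crossprod(Xs), crossprod(Xs, y - mean(y))))
  expect_equal(unname(fit$b), unname(ols), tolerance = 1e-8)
})

test_that("NIPALS scores are orthogonal and weights unit-norm", {
  set.seed(1)
  X <- matrix(rnorm(40 * 12), 40, 12)
  y <- rep(c(0L, 1L), 20)
  fit <- fit_pls(X, y, 5)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_equal(unname(colSums(fit$W^2)), rep(1, fit$n_components),
               tolerance = 1e-10)
  # one-component direction is proportional to the autoscaled class-mean difference
  Xs <- scale(X)
  dmean <- colMeans(Xs[y == 1, ]) - colMeans(Xs[y == 0, ])
  w1 <- fit$W[, 1]
  expect_lt(max(abs(w1 / sqrt(sum(w1^2)) - dmean / sqrt(sum(dmean^2)))), 1e-8)
})

test_that("separable one-gene data gives a correctly signed, perfect classifier", {
  X <- matrix(c(rep(0, 10), rep(3, 10)), ncol = 1,
              dimnames = list(NULL, "g1"))
  y <- rep(c(0L, 1L), each = 10)
  fit <- fit_pls(X + rnorm(20, 0, 0.01), y, 1)
  expect_gt(fit$b[1], 0)
  pr <- predict_pls(fit, X)
  expect_identical(pr$class, y)
  expect_true(all((pr$score >= 0.5) == (y == 1L)))
})

test_that("prediction honours the centering identity and gene order invariance", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- rep(c(0L, 1L), 20)
  fit <- fit_pls(X, y, 3)
  # a sample at the training mean scores the training label mean
  at_mean <- matrix(fit$x_mean, 1, dimnames = list(NULL, fit$genes))
  expect_equal(predict_pls(fit, at_mean)$score, fit$y_mean, tolerance = 1e-10)
  # permuting gene columns (with names) leaves predictions unchanged
  Xn <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(NULL, paste0("g", 1:6)))
  perm <- sample(6)
  expect_equal(predict_pls(fit, Xn[, perm])$score, predict_pls(fit, Xn)$score)
  expect_error(predict_pls(fit, Xn[, 1:3]), "lacks model genes")
  # coefficient vector reproduces training predictions
  Xs <- sweep(sweep(X, 2, fit$x_mean), 2, fit$x_scale, "/")
  expect_equal(drop(Xs %*% fit$b) + fit$y_mean, predict_pls(fit, X)$score,
               tolerance = 1e-12)
})

test_that("duplicating a gene splits its coefficient but keeps predictions", {
  # at full rank the PLS fit equals the projection onto the column space,
  # which a duplicated column does not enlarge
  set.seed(9)
  X <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- rep(c(0L, 1L), 20)
  Xd <- cbind(X, g1b = X[, "g1"])
  f1 <- fit_pls(X, y, 4)
  f2 <- suppressWarnings(fit_pls(Xd, y, 4))
  expect_equal(predict_pls(f2, Xd)$score, predict_pls(f1, X)$score,
               tolerance = 1e-8)
  expect_equal(unname(f2$b["g1"] + f2$b["g1b"]), unname(f1$b["g1"]),
               tolerance = 1e-8)
})

test_that("contribution ranking is scale-invariant and flags noise genes last", {
  set.seed(12)
  n <- 60
  y <- rep(c(0L, 1L), n / 2)
  signal <- matrix(y + rnorm(n, 0, 0.3), ncol = 1)
  last <- 0
  for (s in 1:100) {
    set.seed(s)
    X <- cbind(sig = signal[, 1], noise = rnorm(n))
    fit <- fit_pls(X, y, 2)
    rk <- contributions(fit)
    if (rk$symbol[2] == "noise") last <- last + 1
  }
  expect_gte(last, 95)
  # rescaling a raw gene's unit does not change its rank (autoscaling)
  set.seed(5)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("g", 1:5)))
  X[, 1] <- X[, 1] + y
  r1 <- contributions(fit_pls(X, y, 2))
  X2 <- X; X2[, 3] <- X2[, 3] * 1000
  r2 <- contributions(fit_pls(X2, y, 2))
  expect_identical(r1$symbol, r2$symbol)
})

test_that("component selection returns 1 for rank-one signal and respects max_A", {
  set.seed(21)
  n <- 60
  y <- rep(c(0L, 1L), n / 2)
  f <- y + rnorm(n, 0, 0.2)
  X <- outer(f, runif(8, 0.5, 2)) + matrix(rnorm(n * 8, 0, 0.05), n, 8)
  colnames(X) <- paste0("g", 1:8)
  sel <- select_n_components(X, y, max_A = 5, seed = 2)
  expect_identical(sel$a, 1L)
  expect_identical(select_n_components(X, y, max_A = 1, seed = 2)$a, 1L)
  # deterministic under the seeded fold assignment
  expect_identical(sel, select_n_components(X, y, max_A = 5, seed = 2))
})

test_that("degenerate inputs are handled: zero-variance genes and excess A", {
  set.seed(30)
  X <- matrix(rnorm(20 * 3), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- 7
  y <- rep(c(0L, 1L), 10)
  expect_warning(fit <- fit_pls(X, y, 2), "zero-variance")
  expect_identical(fit$genes, c("a", "c"))
  expect_warning(fit_pls(X[, c(1, 3)], y, 10), "truncated")
})

test_that("model JSON serialization round-trips predictions", {
  set.seed(2)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- rep(c(0L, 1L), 15)
  fit <- fit_pls(X, y, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(fit, path)
  back <- read_pls_model(path)
  expect_equal(predict_pls(back, X)$score, predict_pls(fit, X)$score,
               tolerance = 1e-12)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(7)
  X <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("g", 1:10)))
  y <- rep(c(0L, 1L), 15)
  fit <- fit_pls(X, y, 3)
  Xs <- scale(X)
  mo <- mixOmics::pls(Xs, y - mean(y), ncomp = 3, scale = FALSE,
                      mode = "regression")
  Xn <- matrix(rnorm(8 * 10), 8, 10, dimnames = list(NULL, colnames(X)))
  Xn_s <- scale(Xn, center = attr(Xs, "scaled:center"),
                scale = attr(Xs, "scaled:scale"))
  pr <- predict(mo, Xn_s)
  expect_equal(unname(drop(pr$predict[, 1, 3])) + mean(y),
               predict_pls(fit, Xn)$score, tolerance = 1e-8)
})
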