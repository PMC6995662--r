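#' Kernel specifications
#'
#' @param kind `"linear"`, `"rbf"` or `"polynomial"`.
#' @param gamma RBF width parameter, `exp(-gamma * |a - b|^2)`; required
#'   for `"rbf"`.
#' @param degree,coef0 polynomial kernel `(a.b + coef0)^degree`.
#' @return list of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("linear", "rbf", "polynomial"),
                        gamma = NULL, degree = 3L, coef0 = 1) {
  kind <- match.arg(kind)
  if (kind == "rbf" && (is.null(gamma) || gamma <= 0))
    stop("rbf kernel needs gamma > 0")
  if (kind == "polynomial" && (degree < 1 || degree != round(degree)))
    stop("polynomial kernel needs integer degree >= 1")
  structure(list(kind = kind, gamma = gamma, degree = degree, coef0 = coef0),
            class = "kernel_spec")
}

#' Gram matrix between two sample sets
#'
#' `K[i, j] = k(A[i, ], B[j, ])`; symmetric positive semidefinite when
#' `A = B`.
#'
#' @param A,B samples x genes matrices with matching gene dimension.
#' @param k a [kernel_spec()].
#' @return `nrow(A)` x `nrow(B)` kernel matrix.
#' @export
gram_matrix <- function(A, B, k) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B))
    stop("gene dimensions differ: ", ncol(A), " vs ", ncol(B))
  switch(k$kind,
         linear = tcrossprod(A, B),
         polynomial = (tcrossprod(A, B) + k$coef0)^k$degree,
         rbf = {
           d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
           exp(-k$gamma * pmax(d2, 0))
         })
}

# feature-space double centering of a training Gram matrix:
# Kc = (I - J/n) K (I - J/n)
center_gram <- function(K) {
  n <- nrow(K)
  rm_ <- colMeans(K)              # column means = row means of symmetric K
  gm <- mean(K)
  sweep(sweep(K, 2, rm_), 1, rm_) + gm
}

# centering of a test-vs-train Gram block against the training geometry:
# Kt_c = (Kt - 1_m rowmean(K)^T)(I - J/n)  expanded without forming J
center_gram_test <- function(Kt, K_train) {
  n <- ncol(Kt)
  mu <- colMeans(K_train)
  gm <- mean(K_train)
  Ktc <- sweep(Kt, 2, mu)
  sweep(Ktc, 1, rowMeans(Kt) - gm)
}

#' Fit a kernel PLS discriminant model
#'
#' PLS carried out in the kernel-induced feature space: the Gram matrix of
#' the autoscaled inputs is double-centered and latent variables are
#' extracted by iterative deflation; predictions use the dual coefficients
#' against the stored training inputs. With a linear kernel the model is
#' algebraically equivalent to [fit_pls()].
#'
#' @param X samples x genes matrix.
#' @param y binary 0/1 labels.
#' @param k a [kernel_spec()]; default linear.
#' @param n_components number of latent variables.
#' @return Object of class `kpls_model` with the kernel spec, autoscaling
#'   vectors, stored (scaled) training inputs, score/loading matrices and
#'   the training-label mean.
#' @export
fit_kpls <- function(X, y, k = kernel_spec("linear"), n_components = 2) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 4) stop("need at least 4 samples")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (anyNA(X)) stop("missing values present; impute before fit_kpls")
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%d", seq_len(ncol(X)))
  x_mean <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  keep <- x_scale > 0
  if (!all(keep)) {
    warning("dropping zero-variance genes: ",
            paste(utils::head(colnames(X)[!keep], 5), collapse = ", "))
    X <- X[, keep, drop = FALSE]
    x_mean <- x_mean[keep]; x_scale <- x_scale[keep]
  }
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  y_mean <- mean(y)
  yc <- matrix(y - y_mean, ncol = 1)

  K <- gram_matrix(Xs, Xs, k)
  Kc <- center_gram(K)
  A <- min(as.integer(n_components), n - 1L)
  Tm <- matrix(0, n, A); U <- matrix(0, n, A)
  Kd <- Kc; Yd <- yc
  a <- 0L
  for (i in seq_len(A)) {
    u <- Yd[, 1, drop = FALSE]
    t <- Kd %*% u
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) { warning("n_components truncated to rank ", a); break }
    t <- t / nt
    c_ <- crossprod(Yd, t)
    u <- Yd %*% c_
    u <- u / sqrt(sum(u^2))
    Tm[, i] <- t; U[, i] <- u
    H <- diag(n) - tcrossprod(t)
    Kd <- H %*% Kd %*% H
    Yd <- Yd - tcrossprod(t) %*% Yd
    a <- i
  }
  if (a == 0L) stop("no KPLS component could be extracted")
  Tm <- Tm[, seq_len(a), drop = FALSE]; U <- U[, seq_len(a), drop = FALSE]
  # dual regression: fitted = Kc U (T' Kc U)^-1 T' y
  M <- solve(crossprod(Tm, Kc %*% U), crossprod(Tm, yc))
  dual <- U %*% M                       # n x 1
  structure(list(kernel = k, n_components = a, Xs_train = Xs,
                 K_train = K, dual = dual, scores = Tm,
                 x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 genes = colnames(Xs),
                 class_encoding = c(never = 0, smoker = 1)),
            class = "kpls_model")
}

#' Predict from a kernel PLS model
#'
#' @param model a `kpls_model`.
#' @param X_new samples x genes matrix carrying the model's genes.
#' @return list with `score` and `class` (threshold 0.5).
#' @export
predict_kpls <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new)) && ncol(X_new) == length(model$genes))
    colnames(X_new) <- model$genes
  missing <- setdiff(model$genes, colnames(X_new))
  if (length(missing))
    stop("X_new lacks model genes: ", paste(utils::head(missing, 5), collapse = ", "))
  Xs <- sweep(sweep(X_new[, model$genes, drop = FALSE], 2, model$x_mean),
              2, model$x_scale, "/")
  Kt <- gram_matrix(Xs, model$Xs_train, model$kernel)
  Ktc <- center_gram_test(Kt, model$K_train)
  score <- drop(Ktc %*% model$dual) + model$y_mean
  list(score = score, class = as.integer(score >= 0.5))
}

#' Tune the kernel and component count by cross-validation
#'
#' Evaluates every kernel in the grid under seeded stratified k-fold CV and
#' returns the spec and component count with the highest accuracy; ties are
#' resolved toward the simplest kernel (linear first, then RBF by ascending
#' gamma, then polynomial by degree) and the fewest components.
#'
#' @param X samples x genes matrix.
#' @param y binary labels.
#' @param grid list of [kernel_spec()]s; `NULL` gives the default linear +
#'   RBF grid with `gamma = 2^(-3..3) / p`.
#' @param max_A largest component count tried.
#' @param k folds.
#' @param seed fold seed.
#' @return list with `kernel`, `n_components`, `accuracy`, and the full
#'   `table` of per-candidate CV accuracies.
#' @export
tune_kernel <- function(X, y, grid = NULL, max_A = 5, k = 5, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(grid)) {
    p <- ncol(X)
    grid <- c(list(kernel_spec("linear")),
              lapply(2^(-3:3) / p, function(g) kernel_spec("rbf", gamma = g)))
  }
  if (!length(grid)) stop("empty kernel grid")
  y <- as.integer(y)
  folds <- stratified_kfold(y, k = k, seed = seed)
  simplicity <- vapply(grid, function(ks)
    switch(ks$kind, linear = 0, rbf = 1 + ks$gamma * 1e-9, polynomial = 2 + ks$degree),
    numeric(1))
  rows <- list()
  for (gi in seq_along(grid)) {
    ks <- grid[[gi]]
    A_cap <- max(1L, min(max_A, nrow(X) - ceiling(nrow(X) / k) - 1L))
    correct <- numeric(A_cap); total <- 0
    ok_A <- A_cap
    for (f in seq_len(k)) {
      tr <- folds != f
      for (a in seq_len(A_cap)) {
        fit <- suppressWarnings(fit_kpls(X[tr, , drop = FALSE], y[tr], ks, a))
        if (fit$n_components < a) { ok_A <- min(ok_A, fit$n_components); next }
        pr <- predict_kpls(fit, X[!tr, , drop = FALSE])
        correct[a] <- correct[a] + sum(pr$class == y[!tr])
      }
      total <- total + sum(!tr)
    }
    for (a in seq_len(ok_A))
      rows[[length(rows) + 1L]] <- data.frame(
        grid_index = gi, n_components = a, accuracy = correct[a] / total,
        simplicity = simplicity[gi])
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$accuracy, tab$simplicity, tab$n_components), ]
  best <- tab[1L, ]
  list(kernel = grid[[best$grid_index]], n_components = best$n_components,
       accuracy = best$accuracy, table = tab)
}
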