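#' Fit a linear PLS discriminant model (NIPALS)
#'
#' Univariate-response partial least squares fitted by NIPALS deflation on
#' the autoscaled predictor matrix (each gene centered and scaled to unit
#' variance) and the centered 0/1 class label. Autoscaling makes the
#' per-gene regression coefficients comparable across genes, which is what
#' the contribution ranking of the backward-elimination stage relies on.
#' The fit is deterministic: no random initialisation is involved.
#'
#' @param X samples x genes numeric matrix (column names = gene symbols).
#' @param y binary 0/1 labels, one per row of `X` (1 = smoker).
#' @param n_components number of latent variables A; truncated with a
#'   warning if it exceeds `min(p, n - 1)` or the effective rank.
#' @return An object of class `pls_model`: weights `W` (p x A), loadings
#'   `P` (p x A), y-loadings `q` (length A), scores `scores` (n x A),
#'   per-gene coefficients `b` (for the full A; coefficients for any
#'   smaller number of components via [pls_coefficients()]), scaling
#'   vectors `x_mean`, `x_scale`, `y_mean`, the retained `genes`, and any
#'   `dropped` zero-variance genes.
#' @export
fit_pls <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 4) stop("need at least 4 samples")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (anyNA(X)) stop("missing values present; impute before fit_pls")
  if (is.null(colnames(X))) colnames(X) <- sprintf("g%d", seq_len(p))

  x_mean <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[x_scale == 0]
  if (length(dropped)) {
    warning("dropping zero-variance genes: ",
            paste(utils::head(dropped, 5), collapse = ", "))
    keep <- x_scale > 0
    X <- X[, keep, drop = FALSE]
    x_mean <- x_mean[keep]; x_scale <- x_scale[keep]
    p <- ncol(X)
    if (!p) stop("all genes have zero variance")
  }
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  y_mean <- mean(y)
  yc <- y - y_mean

  A_max <- min(p, n - 1)
  A <- as.integer(n_components)
  if (A > A_max) {
    warning("n_components truncated from ", A, " to ", A_max)
    A <- A_max
  }
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- numeric(A)
  Tm <- matrix(0, n, A)
  Xd <- Xs; yd <- yc
  a <- 0L
  for (k in seq_len(A)) {
    w <- crossprod(Xd, yd)           # p x 1; univariate y: one NIPALS pass
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {                # residual rank exhausted
      warning("n_components truncated to effective rank ", a)
      break
    }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-24) { warning("n_components truncated to effective rank ", a); break }
    pvec <- crossprod(Xd, t) / tt
    qk <- sum(yd * t) / tt
    W[, k] <- w; P[, k] <- pvec; Q[k] <- qk; Tm[, k] <- t
    Xd <- Xd - tcrossprod(t, pvec)
    yd <- yd - qk * t
    a <- k
  }
  if (a == 0L) stop("no PLS component could be extracted")
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[seq_len(a)]; Tm <- Tm[, seq_len(a), drop = FALSE]
  b <- stats::setNames(pls_b(W, P, Q, a), colnames(X))
  structure(list(n_components = a, W = W, P = P, q = Q, scores = Tm,
                 b = b, x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 genes = colnames(X), dropped = dropped,
                 class_encoding = c(never = 0, smoker = 1)),
            class = "pls_model")
}

# regression coefficients on the autoscaled space for the first a components
pls_b <- function(W, P, Q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), Q[seq_len(a)]))
}

#' Coefficients of a fitted PLS model at a given number of components
#'
#' @param model a `pls_model`.
#' @param a number of components (defaults to the fitted maximum).
#' @return Named per-gene coefficient vector on the autoscaled scale.
#' @export
pls_coefficients <- function(model, a = model$n_components) {
  if (a < 1 || a > model$n_components) stop("a out of range")
  stats::setNames(pls_b(model$W, model$P, model$q, a), model$genes)
}

#' Predict from a linear PLS model
#'
#' Continuous score = autoscaled X times the coefficient vector plus the
#' training label mean; class 1 (smoker) when the score is >= 0.5 under the
#' 0/1 encoding.
#'
#' @param model a `pls_model`.
#' @param X_new samples x genes matrix carrying at least the model's genes
#'   (matched by column name; extra columns ignored).
#' @param a number of components to use (default: all fitted).
#' @return list with `score` and `class` vectors.
#' @export
predict_pls <- function(model, X_new, a = model$n_components) {
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new)) && ncol(X_new) == length(model$genes))
    colnames(X_new) <- model$genes
  missing <- setdiff(model$genes, colnames(X_new))
  if (length(missing))
    stop("X_new lacks model genes: ", paste(utils::head(missing, 5), collapse = ", "))
  Xs <- sweep(sweep(X_new[, model$genes, drop = FALSE], 2, model$x_mean),
              2, model$x_scale, "/")
  b <- pls_b(model$W, model$P, model$q, a)
  score <- drop(Xs %*% b) + model$y_mean
  list(score = score, class = as.integer(score >= 0.5))
}

#' Gene contributions of a PLS model
#'
#' The contribution of a gene is the absolute value of its regression
#' coefficient on the autoscaled predictors; the larger, the more the gene
#' matters to the tobacco-exposure classification. Ties are broken by
#' ascending gene symbol so rankings are reproducible.
#'
#' @param model a `pls_model`.
#' @param a number of components (default: all fitted).
#' @return data.frame with `symbol`, `coefficient`, `contribution` (=
#'   `abs(coefficient)`), sorted by descending contribution, with `rank`.
#' @export
contributions <- function(model, a = model$n_components) {
  b <- pls_coefficients(model, a)
  ord <- order(-abs(b), names(b))
  data.frame(symbol = names(b)[ord], coefficient = unname(b[ord]),
             contribution = unname(abs(b[ord])),
             rank = seq_along(b), stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the number of PLS components by cross-validated accuracy
#'
#' Evaluates A = 1..max_A under seeded stratified k-fold cross-validation
#' and returns the smallest A attaining the maximal accuracy.
#'
#' @param X samples x genes matrix.
#' @param y binary labels.
#' @param max_A largest number of components to consider.
#' @param k folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with `a` (chosen component count), `accuracy` (the vector
#'   of CV accuracies for A = 1..max_A evaluated).
#' @export
select_n_components <- function(X, y, max_A = 10, k = 5, seed = 1L) {
  acc <- cv_accuracy_per_A(X, y, max_A, k, seed)$accuracy
  list(a = which.max(acc), accuracy = acc)
}

# One CV pass returning accuracy (and confusion counts) for every A in
# 1..max_A; reused by select_n_components and the elimination loop.
cv_accuracy_per_A <- function(X, y, max_A, k = 5, seed = 1L) {
  X <- as.matrix(X); y <- as.integer(y)
  folds <- stratified_kfold(y, k = k, seed = seed)
  A_cap <- max(1L, min(max_A, ncol(X), nrow(X) - ceiling(nrow(X) / k) - 1L))
  tp <- fp <- tn <- fn <- matrix(0L, A_cap, k)
  a_eff <- A_cap
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- suppressWarnings(fit_pls(X[tr, , drop = FALSE], y[tr], A_cap))
    a_eff <- min(a_eff, fit$n_components)
    for (a in seq_len(fit$n_components)) {
      pr <- predict_pls(fit, X[!tr, , drop = FALSE], a = a)
      yv <- y[!tr]
      tp[a, f] <- sum(pr$class == 1L & yv == 1L)
      fp[a, f] <- sum(pr$class == 1L & yv == 0L)
      tn[a, f] <- sum(pr$class == 0L & yv == 0L)
      fn[a, f] <- sum(pr$class == 0L & yv == 1L)
    }
  }
  idx <- seq_len(a_eff)
  TP <- rowSums(tp)[idx]; FP <- rowSums(fp)[idx]
  TN <- rowSums(tn)[idx]; FN <- rowSums(fn)[idx]
  list(accuracy = (TP + TN) / (TP + TN + FP + FN),
       sensitivity = TP / (TP + FN), specificity = TN / (TN + FP))
}

#' Serialize / restore a PLS model as JSON
#'
#' @param model a `pls_model`.
#' @param path output JSON path.
#' @export
write_pls_model <- function(model, path) {
  obj <- lapply(unclass(model), function(x) if (is.matrix(x)) unname(x) else x)
  obj$kind <- "pls"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("W", "P", "scores")) obj[[f]] <- as.matrix(obj[[f]])
  obj$kind <- NULL
  names(obj$b) <- obj$genes
  structure(obj, class = "pls_model")
}
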