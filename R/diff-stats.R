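#' SAM-style moderated t statistic
#'
#' Per-gene relative difference d = (mean1 - mean0) / (s + s0), where s is
#' the pooled standard-error term of the two-sample t statistic and s0 is a
#' small "fudge factor" stabilising low-variance genes. At `s0 = 0` the
#' statistic is exactly the pooled-variance two-sample t.
#'
#' @param X an [omics_matrix()] with no missing values (impute upstream), or
#'   a plain genes x samples matrix.
#' @param labels binary 0/1 vector over the columns of `X` (1 = smoker).
#' @param s0 non-negative fudge factor; `NULL` selects it automatically via
#'   [estimate_s0()].
#' @return list with per-gene numeric vectors `d`, `numerator` (mean
#'   difference, class 1 minus class 0), `s` (gene-specific scatter), and
#'   the scalar `s0` used.
#' @export
sam_statistic <- function(X, labels, s0 = 0) {
  v <- if (inherits(X, "omics_matrix")) X$values else X
  labels <- as.integer(labels)
  if (length(labels) != ncol(v)) stop("labels must match the sample columns")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (anyNA(v)) stop("missing values present; impute before sam_statistic")
  parts <- sam_parts(v, labels)
  if (is.null(s0)) s0 <- estimate_s0(parts$r, parts$s)
  d <- parts$r / (parts$s + s0)
  d[parts$r == 0 & parts$s + s0 == 0] <- 0   # constant gene: define 0/0 as 0
  if (any(!is.finite(d)))
    stop("non-finite d statistic; use s0 > 0 for zero-variance genes")
  list(d = d, numerator = parts$r, s = parts$s, s0 = s0)
}

# numerator r and scatter s for every gene, vectorised over genes
sam_parts <- function(v, labels) {
  i1 <- labels == 1L; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- rowMeans(v[, i1, drop = FALSE]); m0 <- rowMeans(v[, i0, drop = FALSE])
  ss1 <- rowSums((v[, i1, drop = FALSE] - m1)^2)
  ss0 <- rowSums((v[, i0, drop = FALSE] - m0)^2)
  pooled <- (ss1 + ss0) / (n1 + n0 - 2)
  s <- sqrt((1 / n1 + 1 / n0) * pooled)
  list(r = m1 - m0, s = s)
}

#' Choose the SAM fudge factor s0
#'
#' Tusher-style automatic selection: candidate s0 values are percentiles of
#' the gene scatters s_i; the chosen percentile minimises the coefficient of
#' variation of the d statistic's spread across windows of s, making d's
#' variability roughly independent of the gene's variance.
#'
#' @param r per-gene mean differences.
#' @param s per-gene scatters.
#' @return The selected s0 (a scalar).
#' @export
estimate_s0 <- function(r, s) {
  alphas <- seq(0, 1, by = 0.05)
  cand <- stats::quantile(s, alphas, names = FALSE)
  qs <- stats::quantile(s, seq(0, 1, length.out = 101), names = FALSE)
  bins <- cut(s, unique(qs), include.lowest = TRUE)
  cvs <- vapply(cand, function(s0) {
    d <- r / (s + s0)
    v <- tapply(d, bins, function(x) stats::mad(x))
    v <- v[is.finite(v) & v > 0]
    if (length(v) < 2) return(Inf)
    stats::sd(v) / mean(v)
  }, numeric(1))
  cand[which.min(cvs)]
}

#' Permutation-FDR SAM analysis
#'
#' Computes the d statistic for every gene and estimates q-values from a
#' permutation null: labels are permuted (stratified proportionally across
#' the true classes, keeping class sizes) and, for each observed |d|, the
#' expected number of null genes at least as extreme is compared with the
#' observed count. q-values are monotone non-increasing in |d| and capped
#' at 1; the null proportion pi0 is fixed at 1 (conservative).
#'
#' @inheritParams sam_statistic
#' @param n_permutations number of label permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @param s0 fudge factor; `NULL` (default) auto-selects via [estimate_s0()].
#' @param fdr_cutoff threshold used for the `selected` flag (the study-wide
#'   default is q <= 0.1).
#' @return A data.frame (one row per gene, original order) with columns
#'   `symbol`, `d`, `numerator`, `s`, `fold_change`, `q_value`, `rank`
#'   (1 = largest |d|), `selected`; attribute `s0` records the fudge factor.
#' @export
sam_fdr <- function(X, labels, n_permutations = 1000, seed = 1L, s0 = NULL,
                    fdr_cutoff = 0.1) {
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  v <- if (inherits(X, "omics_matrix")) X$values else X
  syms <- rownames(v)
  if (is.null(syms)) syms <- sprintf("g%d", seq_len(nrow(v)))
  labels <- as.integer(labels)
  obs <- sam_statistic(v, labels, s0 = s0)
  s0 <- obs$s0
  n <- length(labels)
  n1 <- sum(labels == 1L)
  max_distinct <- choose(n, n1)
  B <- n_permutations
  if (max_distinct < B) {
    warning("only ", max_distinct, " distinct permutations exist; using all")
    B <- max_distinct
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  idx1 <- which(labels == 1L); idx0 <- which(labels == 0L)
  # proportional stratified ("balanced") permutations: the pseudo-smoker
  # group draws from each true class in proportion to its size
  k1 <- round(n1 * length(idx1) / n)
  perm_d <- matrix(0, nrow(v), B)
  for (b in seq_len(B)) {
    pick <- c(sample(idx1, k1), sample(idx0, n1 - k1))
    pl <- integer(n); pl[pick] <- 1L
    parts <- sam_parts(v, pl)
    perm_d[, b] <- parts$r / (parts$s + s0)
  }

  ad <- abs(obs$d)
  ord <- order(ad, decreasing = TRUE)
  # expected false positives at each observed |d| threshold
  null_sorted <- sort(abs(as.vector(perm_d)))
  exceed <- length(null_sorted) -
    findInterval(ad[ord] - 1e-12, null_sorted)  # #null >= threshold
  V <- exceed / B
  R <- seq_along(ord)
  q <- pmin(1, V / R)
  q <- cummax(q)          # monotone non-increasing in |d|
  q_out <- numeric(length(ad)); q_out[ord] <- q
  rank_out <- integer(length(ad)); rank_out[ord] <- R

  res <- data.frame(symbol = syms, d = obs$d, numerator = obs$numerator,
                    s = obs$s, fold_change = fold_change(2^v, labels),
                    q_value = q_out, rank = rank_out,
                    selected = q_out <= fdr_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "s0") <- s0
  attr(res, "n_permutations") <- B
  res
}

#' Per-gene fold change between classes
#'
#' Ratio of class means on the linear scale, smoker class over never
#' smokers. A zero denominator mean yields `NA` rather than an infinity.
#'
#' @param X_linear genes x samples matrix (or `omics_matrix`) on the linear
#'   scale (undo any log transform first).
#' @param labels binary 0/1 vector (1 = smoker).
#' @return Named numeric vector of fold changes.
#' @export
fold_change <- function(X_linear, labels) {
  v <- if (inherits(X_linear, "omics_matrix")) X_linear$values else X_linear
  labels <- as.integer(labels)
  m1 <- rowMeans(v[, labels == 1L, drop = FALSE], na.rm = TRUE)
  m0 <- rowMeans(v[, labels == 0L, drop = FALSE], na.rm = TRUE)
  fc <- m1 / m0
  fc[m0 == 0] <- NA_real_
  fc
}

#' Volcano table: log2 fold change and Welch-test p per gene
#'
#' The x axis of the genome-wide volcano view: log2 of the smoker/never
#' fold change on the linear scale; the y axis: -log10 of the two-sided
#' Welch (unequal-variance) t-test p-value computed on `X_test` (typically
#' the log-scale matrix).
#'
#' @param X_linear linear-scale matrix for the fold change.
#' @param labels binary 0/1 vector (1 = smoker).
#' @param X_test matrix on which the t-test runs; defaults to
#'   `log2(X_linear + 1)`.
#' @return data.frame with `symbol`, `log2_fc`, `p_value`, `neg_log10_p`.
#' @export
volcano_table <- function(X_linear, labels, X_test = NULL) {
  v <- if (inherits(X_linear, "omics_matrix")) X_linear$values else X_linear
  if (is.null(X_test)) X_test <- log2(v + 1)
  tv <- if (inherits(X_test, "omics_matrix")) X_test$values else X_test
  p <- welch_p(tv, as.integer(labels))
  fc <- fold_change(v, labels)
  syms <- rownames(v); if (is.null(syms)) syms <- sprintf("g%d", seq_len(nrow(v)))
  data.frame(symbol = syms, log2_fc = unname(log2(fc)), p_value = unname(p),
             neg_log10_p = unname(-log10(p)), stringsAsFactors = FALSE,
             row.names = NULL)
}

# vectorised two-sided Welch t-test p-values, rowwise, NA-tolerant
welch_p <- function(v, labels) {
  i1 <- labels == 1L; i0 <- !i1
  x1 <- v[, i1, drop = FALSE]; x0 <- v[, i0, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n0 <- rowSums(!is.na(x0))
  m1 <- rowMeans(x1, na.rm = TRUE); m0 <- rowMeans(x0, na.rm = TRUE)
  v1 <- apply(x1, 1, stats::var, na.rm = TRUE)
  v0 <- apply(x0, 1, stats::var, na.rm = TRUE)
  se2 <- v1 / n1 + v0 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  p[se2 == 0 & (m1 == m0)] <- 1
  p
}

#' Bonferroni family-wise cutoff
#'
#' For `n_tests` simultaneous comparisons at family-wise level `alpha`, the
#' per-test p cutoff is `alpha / n_tests`. For the 21,342 genes of the
#' expression volcano this gives 2.34e-6, i.e. -log10 = 5.63.
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error level.
#' @return list `n_tests`, `alpha`, `per_test_p`, `neg_log10`.
#' @export
bonferroni_cutoff <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || n_tests < 1) stop("n_tests must be >= 1")
  per <- alpha / n_tests
  list(n_tests = n_tests, alpha = alpha, per_test_p = per,
       neg_log10 = -log10(per))
}

#' Expression-correlation candidate filter for ME / CNV layers
#'
#' Genes whose methylation or copy number varies with their own expression
#' are unlikely to be pure noise: the filter keeps genes with
#' `|Pearson r| > threshold` between the layer's values and the expression
#' values across shared samples (pairwise-complete observations).
#'
#' @param layer `omics_matrix` (ME or CNV, any scale).
#' @param ge expression `omics_matrix` (log scale recommended).
#' @param threshold absolute-correlation threshold (study default 0.5).
#' @return Character vector of selected gene symbols. Genes with fewer than
#'   3 complete pairs are skipped with a warning. The full per-gene r is
#'   attached as attribute `r`.
#' @export
correlation_filter <- function(layer, ge, threshold = 0.5) {
  common_s <- intersect(sample_ids(layer), sample_ids(ge))
  common_g <- intersect(gene_symbols(layer), gene_symbols(ge))
  if (length(common_s) < 3 || !length(common_g))
    stop("correlation_filter needs >= 3 shared samples and >= 1 shared gene")
  lv <- layer$values[common_g, common_s, drop = FALSE]
  gv <- ge$values[common_g, common_s, drop = FALSE]
  r <- vapply(seq_along(common_g), function(i) {
    ok <- !is.na(lv[i, ]) & !is.na(gv[i, ])
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(stats::cor(lv[i, ok], gv[i, ok]))
  }, numeric(1))
  names(r) <- common_g
  if (anyNA(r))
    warning(sum(is.na(r)), " gene(s) skipped: fewer than 3 complete pairs")
  sel <- common_g[!is.na(r) & abs(r) > threshold]
  attr(sel, "r") <- r
  sel
}
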