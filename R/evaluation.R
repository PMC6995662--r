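#' Confusion-matrix classification metrics
#'
#' Sensitivity is the recall of the positive (smoker) class, specificity
#' the recall of the never-smoker class, accuracy the overall correct
#' fraction — the three quantities used to report every classifier in this
#' package.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive_class the label counted as positive (default `1`, the
#'   smoker encoding).
#' @return list of class `classification_metrics`: `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `specificity`, `accuracy`, `positive_class`.
#' @export
confusion <- function(y_true, y_pred, positive_class = 1L) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  pos <- y_true == positive_class
  hit <- y_pred == positive_class
  TP <- sum(pos & hit); FN <- sum(pos & !hit)
  TN <- sum(!pos & !hit); FP <- sum(!pos & hit)
  m <- structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                      sensitivity = TP / (TP + FN),
                      specificity = TN / (TN + FP),
                      accuracy = (TP + TN) / length(y_true),
                      positive_class = positive_class),
                 class = "classification_metrics")
  m
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("SN %.1f%%  SP %.1f%%  ACC %.1f%%  (TP %d FP %d TN %d FN %d)\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
              x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Seeded stratified k-fold assignment
#'
#' Shuffles each class independently and deals its members round-robin
#' across folds, so fold sizes differ by at most one overall and per-class
#' proportions are preserved within one sample.
#'
#' @param labels class labels.
#' @param k number of folds (default 5).
#' @param seed RNG seed; the same seed gives the same folds.
#' @return Integer vector of fold ids in 1..k, aligned with `labels`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = 1L) {
  tab <- table(labels)
  if (any(tab < k))
    stop("every class needs at least k = ", k, " members (smallest has ",
         min(tab), ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fold <- integer(length(labels))
  load <- integer(k)                 # running fold sizes across classes
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    # deal round-robin starting from the lightest folds so overall fold
    # sizes stay within one of each other
    cycle <- rep_len(order(load), length(idx))
    fold[idx] <- cycle
    load <- load + tabulate(cycle, k)
  }
  fold
}

#' ROC curve points and AUC
#'
#' Standard threshold sweep over the continuous scores, grouping tied
#' scores, from (0, 0) to (1, 1); AUC by the trapezoid rule (equal to the
#' normalised Mann-Whitney U statistic when scores are tie-free).
#'
#' @param scores numeric scores (higher = more smoker-like).
#' @param y_true binary 0/1 labels.
#' @return list with `points` (data.frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_points <- function(scores, y_true) {
  y_true <- as.integer(y_true)
  if (length(unique(y_true)) < 2) stop("y_true must contain both classes")
  if (length(scores) != length(y_true)) stop("length mismatch")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y_true[ord]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1L); fp <- cumsum(y == 0L)
  last <- !duplicated(grp, fromLast = TRUE)
  pts <- data.frame(fpr = c(0, fp[last] / n0), tpr = c(0, tp[last] / n1),
                    threshold = c(Inf, s[last]))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}
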