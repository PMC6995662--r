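#' Stage 1 — statistical candidate genes for one layer
#'
#' Expression candidates are the genes the SAM permutation analysis calls
#' significant at q <= `fdr_cutoff`; methylation and copy-number candidates
#' are the genes whose values track their own expression with
#' `|r| > cor_threshold` (see [correlation_filter()]).
#'
#' @param layer_matrix preprocessed, imputed [omics_matrix()] of the layer
#'   under selection (log2 GE, beta ME, or log2(CNV/2)).
#' @param ge_matrix preprocessed log-scale expression matrix (used by the
#'   ME/CNV correlation rule; ignored for GE).
#' @param labels binary 0/1 labels over the layer's samples (1 = smoker).
#' @param layer `"GE"`, `"ME"` or `"CNV"`.
#' @param fdr_cutoff SAM q-value threshold (study default 0.1).
#' @param cor_threshold absolute-correlation threshold (study default 0.5).
#' @param n_permutations,seed passed to [sam_fdr()].
#' @return Character vector of candidate symbols; attribute `detail` holds
#'   the per-gene statistics table.
#' @export
statistical_candidates <- function(layer_matrix, ge_matrix, labels,
                                   layer = c("GE", "ME", "CNV"),
                                   fdr_cutoff = 0.1, cor_threshold = 0.5,
                                   n_permutations = 1000, seed = 1L) {
  layer <- match.arg(layer)
  if (layer == "GE") {
    res <- sam_fdr(layer_matrix, labels, n_permutations = n_permutations,
                   seed = seed, fdr_cutoff = fdr_cutoff)
    sel <- res$symbol[res$selected]
    detail <- res
  } else {
    sel <- correlation_filter(layer_matrix, ge_matrix, threshold = cor_threshold)
    detail <- data.frame(symbol = names(attr(sel, "r")), r = attr(sel, "r"),
                         row.names = NULL, stringsAsFactors = FALSE)
    attributes(sel) <- NULL
  }
  if (!length(sel))
    stop("no candidate genes for layer ", layer,
         "; consider relaxing the FDR/correlation threshold")
  out <- sel
  attr(out, "detail") <- detail
  out
}

#' Stage 2 — merge curated (experimentally supported) genes
#'
#' Unions the statistically selected candidates with a curated list of
#' genes with experimental evidence, restricted to genes actually present
#' in the data, so that known biology is not overwhelmed by the genome-wide
#' search. Curated genes absent from the data are skipped with a warning.
#'
#' @param candidates character vector from [statistical_candidates()].
#' @param curated character vector of curated symbols (may be empty).
#' @param universe symbols present in the (preprocessed) data.
#' @return Character vector; attribute `injected` lists the curated genes
#'   added beyond the candidates.
#' @export
merge_experimental <- function(candidates, curated, universe) {
  curated <- unique(curated)
  absent <- setdiff(curated, universe)
  if (length(absent))
    warning("curated genes absent from the data, skipped: ",
            paste(utils::head(absent, 10), collapse = ", "))
  usable <- intersect(curated, universe)
  out <- union(candidates, usable)
  attr(out, "injected") <- setdiff(usable, candidates)
  out
}

#' Stage 3 — iterative contribution-based backward elimination
#'
#' Repeatedly fits a linear PLS classifier on the remaining genes, ranks
#' them by contribution (|autoscaled coefficient|, recomputed on the full
#' training set each iteration), removes the single least-important gene,
#' and records seeded stratified 5-fold cross-validated accuracy. The loop
#' stops when the running best accuracy has not improved for `patience`
#' consecutive removals, or when two genes remain; the returned signature
#' is the gene set at the best-accuracy iteration (ties resolved toward
#' fewer genes).
#'
#' @param X samples x candidate-genes matrix (imputed; columns named).
#' @param y binary 0/1 labels (1 = smoker).
#' @param max_A largest PLS component count considered per refit.
#' @param k cross-validation folds.
#' @param seed fold-assignment seed (fixed for the whole run).
#' @param patience removals tolerated without a new accuracy best.
#' @return list with `trace` (data.frame: `iteration`, `remaining_count`,
#'   `cv_accuracy`, `cv_sensitivity`, `cv_specificity`, `n_components`,
#'   `removed_gene` — the gene removed *after* the row's model was scored)
#'   and `signature` (character vector at the best iteration), plus
#'   `best_iteration`, `best_accuracy`.
#' @export
iterative_elimination <- function(X, y, max_A = 10, k = 5, seed = 1L,
                                  patience = 10) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 candidate genes")
  y <- as.integer(y)
  genes <- colnames(X)
  sets <- list()
  rows <- list()
  best_acc <- -Inf; best_iter <- NA_integer_; since_best <- 0L
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cv <- cv_accuracy_per_A(X[, genes, drop = FALSE], y, max_A, k, seed)
    a_best <- which.max(cv$accuracy)           # ties -> smallest A
    acc <- cv$accuracy[a_best]
    fit <- suppressWarnings(fit_pls(X[, genes, drop = FALSE], y, a_best))
    rk <- contributions(fit)
    removed <- if (length(genes) > 2L) rk$symbol[nrow(rk)] else NA_character_
    sets[[iter]] <- genes
    rows[[iter]] <- data.frame(
      iteration = iter, remaining_count = length(genes),
      cv_accuracy = acc, cv_sensitivity = cv$sensitivity[a_best],
      cv_specificity = cv$specificity[a_best],
      n_components = a_best, removed_gene = removed,
      stringsAsFactors = FALSE)
    if (acc > best_acc + 1e-12) {
      best_acc <- acc; best_iter <- iter; since_best <- 0L
    } else {
      # ties toward fewer genes: a later iteration matching the best wins
      if (acc >= best_acc - 1e-12) best_iter <- iter
      since_best <- since_best + 1L
    }
    if (length(genes) <= 2L || since_best >= patience) break
    genes <- setdiff(genes, removed)
  }
  trace <- do.call(rbind, rows)
  list(trace = trace, signature = sets[[best_iter]],
       best_iteration = best_iter, best_accuracy = best_acc)
}

#' Run the full three-stage identification for one layer
#'
#' Chains statistical candidate selection, curated-gene merging and
#' iterative contribution elimination, then fits the final linear PLS and a
#' tuned kernel PLS on the signature genes. Metrics are reported for
#' training cross-validation, training resubstitution, and (when a
#' validation cohort is supplied) held-out prediction.
#'
#' @param layer_matrix,ge_matrix,labels,layer as in
#'   [statistical_candidates()]; matrices must be imputed.
#' @param curated curated gene symbols (default none).
#' @param validation_matrix optional held-out [omics_matrix()] of the same
#'   layer (imputed, same preprocessing).
#' @param validation_labels binary labels for the validation samples.
#' @param fdr_cutoff,cor_threshold,n_permutations stage-1 parameters.
#' @param max_A,k,patience stage-3 parameters.
#' @param kernel_grid passed to [tune_kernel()] (`NULL` = default grid).
#' @param seed master seed for permutations and fold assignment.
#' @return list of class `signature_set`: `layer`, `genes` (ranked by final
#'   contribution), `candidates`, `injected`, `trace`, `pls_model`,
#'   `kpls_model`, `kernel`, and `metrics` (named list of
#'   `classification_metrics`: `cv`, `resubstitution_pls`,
#'   `resubstitution_kpls`, optionally `validation_pls`,
#'   `validation_kpls`).
#' @export
run_layer <- function(layer_matrix, ge_matrix, labels,
                      layer = c("GE", "ME", "CNV"), curated = character(0),
                      validation_matrix = NULL, validation_labels = NULL,
                      fdr_cutoff = 0.1, cor_threshold = 0.5,
                      n_permutations = 1000, max_A = 10, k = 5,
                      patience = 10, kernel_grid = NULL, seed = 1L) {
  layer <- match.arg(layer)
  cand <- statistical_candidates(layer_matrix, ge_matrix, labels, layer,
                                 fdr_cutoff = fdr_cutoff,
                                 cor_threshold = cor_threshold,
                                 n_permutations = n_permutations, seed = seed)
  detail <- attr(cand, "detail")
  merged <- merge_experimental(cand, curated, gene_symbols(layer_matrix))
  injected <- attr(merged, "injected")

  Xt <- t(layer_matrix$values[merged, , drop = FALSE])
  if (anyNA(Xt)) stop("layer matrix must be imputed before run_layer")
  elim <- iterative_elimination(Xt, labels, max_A = max_A, k = k,
                                seed = seed, patience = patience)
  sig <- elim$signature

  Xsig <- Xt[, sig, drop = FALSE]
  cvA <- cv_accuracy_per_A(Xsig, labels, max_A, k, seed)
  a_best <- which.max(cvA$accuracy)
  final_pls <- suppressWarnings(fit_pls(Xsig, labels, a_best))
  tuned <- tune_kernel(Xsig, labels, grid = kernel_grid, max_A = max_A,
                       k = k, seed = seed)
  final_kpls <- fit_kpls(Xsig, labels, tuned$kernel, tuned$n_components)

  metrics <- list(
    cv = structure(list(TP = NA, FP = NA, TN = NA, FN = NA,
                        sensitivity = cvA$sensitivity[a_best],
                        specificity = cvA$specificity[a_best],
                        accuracy = cvA$accuracy[a_best], positive_class = 1L),
                   class = "classification_metrics"),
    resubstitution_pls = confusion(labels, predict_pls(final_pls, Xsig)$class),
    resubstitution_kpls = confusion(labels, predict_kpls(final_kpls, Xsig)$class))

  if (!is.null(validation_matrix)) {
    if (is.null(validation_labels)) stop("validation_labels required")
    missing <- setdiff(sig, gene_symbols(validation_matrix))
    if (length(missing))
      stop("validation cohort lacks signature genes: ",
           paste(utils::head(missing, 5), collapse = ", "))
    Xv <- t(validation_matrix$values[sig, , drop = FALSE])
    if (anyNA(Xv)) stop("validation matrix must be imputed")
    metrics$validation_pls <-
      confusion(validation_labels, predict_pls(final_pls, Xv)$class)
    metrics$validation_kpls <-
      confusion(validation_labels, predict_kpls(final_kpls, Xv)$class)
  }

  ranked <- contributions(final_pls)
  structure(list(layer = layer, genes = ranked$symbol,
                 ranking = ranked, candidates = as.character(cand),
                 candidate_detail = detail, injected = injected,
                 trace = elim$trace, best_iteration = elim$best_iteration,
                 n_components = a_best, kernel = tuned$kernel,
                 pls_model = final_pls, kpls_model = final_kpls,
                 metrics = metrics, seed = seed),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set [%s]: %d genes (from %d candidates, %d injected)\n",
              x$layer, length(x$genes), length(x$candidates),
              length(x$injected)))
  cat("  CV: "); print(x$metrics$cv)
  if (!is.null(x$metrics$validation_kpls)) {
    cat("  validation (KPLS): "); print(x$metrics$validation_kpls)
  }
  invisible(x)
}

#' Write a signature set's tables to a directory
#'
#' Emits the ranked signature TSV (`rank`, `symbol`, `contribution`), the
#' elimination trace TSV and a metrics JSON.
#'
#' @param sig a `signature_set`.
#' @param dir output directory.
#' @export
write_signature_set <- function(sig, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(rank = sig$ranking$rank, symbol = sig$ranking$symbol,
               contribution = sig$ranking$contribution),
    file.path(dir, sprintf("signature_%s.tsv", tolower(sig$layer))),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sig$trace,
                     file.path(dir, sprintf("trace_%s.tsv", tolower(sig$layer))),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  flat <- lapply(sig$metrics, function(m)
    list(sensitivity = m$sensitivity, specificity = m$specificity,
         accuracy = m$accuracy))
  jsonlite::write_json(
    list(layer = sig$layer, n_signature = length(sig$genes),
         n_candidates = length(sig$candidates),
         injected = sig$injected, kernel = unclass(sig$kernel),
         n_components = sig$n_components, seed = sig$seed, metrics = flat),
    file.path(dir, sprintf("metrics_%s.json", tolower(sig$layer))),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
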