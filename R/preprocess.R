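#' Filter genes by symbol validity and observedness
#'
#' Keeps genes that carry a recognised symbol and have at least one observed
#' value; genes missing in every sample are removed, genes missing in only
#' part of the samples are retained.
#'
#' @param m an [omics_matrix()].
#' @param valid_symbols character vector of accepted symbols, or `NULL` to
#'   skip the symbol check.
#' @return The filtered `omics_matrix` (possibly with zero genes).
#' @export
filter_genes <- function(m, valid_symbols = NULL) {
  keep <- rowSums(!m$missing_mask) >= 1L
  if (!is.null(valid_symbols)) keep <- keep & gene_symbols(m) %in% valid_symbols
  subset_omics(m, genes = which(keep))
}

#' Restrict two cohorts to their common genes
#'
#' Both matrices are reduced to the intersection of their gene symbols, in a
#' shared deterministic order, keeping their own sample columns.
#'
#' @param train,validation `omics_matrix` objects of the same layer.
#' @return list with elements `train` and `validation`.
#' @export
intersect_common_genes <- function(train, validation) {
  if (train$layer != validation$layer)
    stop("layers differ: ", train$layer, " vs ", validation$layer)
  common <- intersect(gene_symbols(train), gene_symbols(validation))
  if (!length(common))
    stop("no genes are common to the training and validation cohorts")
  common <- sort(common)
  list(train = subset_omics(train, genes = common),
       validation = subset_omics(validation, genes = common))
}

#' Expression and copy-number transforms
#'
#' `transform_ge()` applies `log2(x + 1)` (tolerates the zeros that occur in
#' level-3 RNA-seq quantifications); `transform_cnv()` applies `log2(x / 2)`
#' so the diploid baseline maps to 0 and a single male chrY copy to -1.
#' Masks are preserved.
#'
#' @param m an [omics_matrix()] (`GE` raw linear scale; `CNV` raw copies).
#' @return The transformed `omics_matrix`.
#' @export
transform_ge <- function(m) {
  if (m$layer != "GE") stop("transform_ge expects a GE layer")
  v <- m$values
  ok <- v[!m$missing_mask]
  if (length(ok) && min(ok) < 0) stop("GE values must be >= 0")
  v <- log2(v + 1)
  structure(list(layer = "GE", values = v, missing_mask = m$missing_mask),
            class = "omics_matrix")
}

#' @rdname transform_ge
#' @export
transform_cnv <- function(m) {
  if (m$layer != "CNV") stop("transform_cnv expects a CNV layer")
  v <- m$values
  bad <- rowSums(v <= 0 & !m$missing_mask, na.rm = TRUE) > 0
  if (any(bad))
    stop("nonpositive copy numbers for genes: ",
         paste(utils::head(gene_symbols(m)[bad], 5), collapse = ", "))
  structure(list(layer = "CNV", values = log2(v / 2),
                 missing_mask = m$missing_mask),
            class = "omics_matrix")
}

#' @rdname transform_ge
#' @export
inverse_transform_cnv <- function(m) {
  structure(list(layer = "CNV", values = 2 * 2^m$values,
                 missing_mask = m$missing_mask),
            class = "omics_matrix")
}

#' Aggregate probe-level methylation to promoter-level gene values
#'
#' A gene's methylation value is the mean beta over probes whose position
#' falls inside the gene's promoter interval (1-based inclusive); missing
#' probe values are excluded from the mean and genes with no promoter probe
#' are dropped.
#'
#' @param probe_values probes x samples numeric matrix (beta scale),
#'   rownames = probe ids.
#' @param probe_positions data.frame with `probe_id`, `chromosome`,
#'   `position`.
#' @param ann gene annotation (see [load_annotation()]).
#' @return An `ME` [omics_matrix()] with one row per gene retained.
#' @export
aggregate_promoter_me <- function(probe_values, probe_positions, ann) {
  stopifnot(is.matrix(probe_values))
  pos <- probe_positions[match(rownames(probe_values), probe_positions$probe_id), ]
  if (anyNA(pos$probe_id)) stop("probes without positions: ",
                                paste(utils::head(setdiff(rownames(probe_values),
                                                          probe_positions$probe_id), 5),
                                      collapse = ", "))
  rows <- vector("list", nrow(ann))
  kept <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    hit <- which(pos$chromosome == ann$chromosome[i] &
                   pos$position >= ann$promoter_start[i] &
                   pos$position <= ann$promoter_end[i])
    if (!length(hit)) next
    kept[i] <- TRUE
    block <- probe_values[hit, , drop = FALSE]
    mu <- colMeans(block, na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_
    rows[[i]] <- mu
  }
  if (!any(kept)) stop("no gene has a probe in its promoter interval")
  v <- do.call(rbind, rows[kept])
  omics_matrix(v, "ME", gene_symbols = ann$symbol[kept],
               sample_ids = colnames(probe_values))
}

#' Drop samples lacking required clinical covariates
#'
#' Removes samples for which any of age, gender, stage or vital status is
#' missing, consistently from the sample table and every supplied matrix;
#' surviving samples keep their original order.
#'
#' @param st sample-table data.frame ([load_sample_table()]).
#' @param ... `omics_matrix` objects whose columns are subset in step.
#' @return list with `samples` (the filtered table) and `matrices` (list of
#'   filtered matrices, in input order).
#' @export
filter_samples <- function(st, ...) {
  need <- c("age", "gender", "stage", "vital_status")
  ok <- stats::complete.cases(st[need])
  keep_ids <- st$sample_id[ok]
  mats <- lapply(list(...), function(m) {
    idx <- which(sample_ids(m) %in% keep_ids)
    subset_omics(m, samples = idx)
  })
  list(samples = st[ok, , drop = FALSE], matrices = mats)
}

#' Binary smoking labels for classification
#'
#' Encodes the smoker class as 1 and never smokers as 0, dropping samples in
#' other categories. By default the contrast is current-vs-never; cohorts
#' that only report "ever" can use `positive = "ever"`.
#'
#' @param st sample table.
#' @param positive smoking category treated as the smoker (positive) class.
#' @return named integer vector (names = sample ids) with values 0/1.
#' @export
smoking_labels <- function(st, positive = c("current", "ever")) {
  positive <- match.arg(positive)
  keep <- st$smoking %in% c("never", positive)
  y <- as.integer(st$smoking[keep] == positive)
  names(y) <- st$sample_id[keep]
  y
}
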