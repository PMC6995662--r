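#' Construct an omics matrix
#'
#' The basic container for one omics layer: a genes x samples numeric matrix
#' with an explicit missing-value mask. Methylation is carried as beta values
#' in \[0, 1\]; copy number on the raw scale (diploid baseline 2) until
#' [transform_cnv()] is applied.
#'
#' @param values numeric matrix, genes in rows, samples in columns. `NA`
#'   entries are recorded in the mask.
#' @param layer one of `"GE"`, `"ME"`, `"CNV"`.
#' @param gene_symbols character vector of unique row names; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of column names; defaults to
#'   `colnames(values)`.
#' @return An object of class `omics_matrix`: a list with elements `layer`,
#'   `values` (with dimnames set), and `missing_mask`.
#' @export
omics_matrix <- function(values, layer = c("GE", "ME", "CNV"),
                         gene_symbols = rownames(values),
                         sample_ids = colnames(values)) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(gene_symbols) || length(gene_symbols) != nrow(values))
    stop("gene_symbols must match the number of rows (", nrow(values), ")")
  if (is.null(sample_ids) || length(sample_ids) != ncol(values))
    stop("sample_ids must match the number of columns (", ncol(values), ")")
  if (anyDuplicated(gene_symbols))
    stop("duplicate gene symbols: ",
         paste(unique(gene_symbols[duplicated(gene_symbols)]), collapse = ", "))
  dimnames(values) <- list(gene_symbols, sample_ids)
  out <- structure(
    list(layer = layer, values = values, missing_mask = is.na(values)),
    class = "omics_matrix"
  )
  validate_omics_matrix(out)
  out
}

# ME betas must stay in [0, 1]. CNV may be raw (>= 0) or log2(CNV/2)
# scale, so its range is policed at the transform boundary instead.
validate_omics_matrix <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  ok <- v[!m$missing_mask]
  if (m$layer == "ME" && length(ok) && (min(ok) < 0 || max(ok) > 1))
    stop("ME beta values must lie in [0, 1]")
  invisible(m)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d genes x %d samples, %.1f%% missing\n",
              x$layer, nrow(x$values), ncol(x$values),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

gene_symbols <- function(m) rownames(m$values)
sample_ids <- function(m) colnames(m$values)

# Row/column subsetting that keeps values and mask in register.
subset_omics <- function(m, genes = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  out <- structure(list(layer = m$layer, values = v, missing_mask = is.na(v)),
                   class = "omics_matrix")
  out
}

#' Impute missing values by per-gene means
#'
#' Replaces masked entries of a layer with the gene's mean over non-missing
#' samples. When `reference` is supplied (the training cohort), its gene
#' means are used instead, so validation imputation never looks at
#' validation labels or values beyond the gene mean learned on training.
#'
#' @param m an [omics_matrix()].
#' @param reference optional `omics_matrix` whose per-gene means are used.
#' @return An `omics_matrix` with no missing values (genes missing
#'   everywhere in both `m` and `reference` raise an error; drop them with
#'   [filter_genes()] first).
#' @export
impute_gene_means <- function(m, reference = NULL) {
  v <- m$values
  src <- if (is.null(reference)) v else {
    if (!identical(rownames(reference$values), rownames(v)))
      stop("reference gene symbols must match")
    reference$values
  }
  mu <- rowMeans(src, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu)))
    stop("genes with no observed values cannot be imputed: ",
         paste(utils::head(rownames(v)[is.nan(mu) | is.na(mu)], 5), collapse = ", "))
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- mu[idx[, 1L]]
  structure(list(layer = m$layer, values = v,
                 missing_mask = matrix(FALSE, nrow(v), ncol(v),
                                       dimnames = dimnames(v))),
            class = "omics_matrix")
}
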