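#' Read an omics layer from a TSV file
#'
#' Expects genes as rows with the symbol in the first column and one column
#' per sample; the header row carries sample ids. Empty cells and the tokens
#' `NA`, `NaN`, `null` are treated as missing and recorded in the mask.
#' Gzipped files are accepted.
#'
#' @param path file path (plain or `.gz`).
#' @param layer `"GE"`, `"ME"` or `"CNV"`.
#' @return An [omics_matrix()].
#' @export
load_omics <- function(path, layer = c("GE", "ME", "CNV")) {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      na.strings = c("", "NA", "NaN", "null"),
                      colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  if (ncol(df) < 2L)
    stop("malformed header in ", path,
         ": need a symbol column plus at least one sample column")
  syms <- df[[1L]]
  if (anyNA(syms) || any(syms == ""))
    stop("missing gene symbol at row ",
         which(is.na(syms) | syms == "")[1L], " of ", path)
  if (anyDuplicated(syms))
    stop("duplicate gene symbols in ", path, ": ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "))
  body <- df[-1L]
  num <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell in ", path, " at gene '", syms[bad[1L, 1L]],
         "', sample '", colnames(num)[bad[1L, 2L]], "'")
  omics_matrix(num, layer, gene_symbols = syms, sample_ids = colnames(num))
}

#' Write an omics layer as TSV
#'
#' Inverse of [load_omics()]: first column `symbol`, one column per sample,
#' masked entries written as `NA`.
#'
#' @param m an [omics_matrix()].
#' @param path output path; a `.gz` suffix gives a gzipped file.
#' @export
write_omics <- function(m, path) {
  df <- data.frame(symbol = gene_symbols(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample table
#'
#' Columns: `sample_id`, `smoking` (never/current/former/ever), `age`,
#' `gender`, `stage`, `vital_status`. Unknown smoking categories are
#' rejected; clinical fields may be missing (see [filter_samples()]).
#'
#' @param path TSV path (gzip accepted).
#' @return A data.frame with the columns above.
#' @export
load_sample_table <- function(path) {
  st <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  need <- c("sample_id", "smoking", "age", "gender", "stage", "vital_status")
  miss <- setdiff(need, names(st))
  if (length(miss)) stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(stats::na.omit(unique(st$smoking)), SMOKING_LEVELS)
  if (length(bad)) stop("unknown smoking categories: ", paste(bad, collapse = ", "))
  st
}

SMOKING_LEVELS <- c("never", "current", "former", "ever")

#' @rdname load_sample_table
#' @param st sample-table data.frame.
#' @export
write_sample_table <- function(st, path) {
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a gene annotation table
#'
#' BED-like TSV with 1-based inclusive coordinates: `symbol`, `chromosome`,
#' `start`, `end`, `arm` (p/q), `promoter_start`, `promoter_end`.
#'
#' @param path TSV path.
#' @return data.frame of the columns above, one row per gene.
#' @export
load_annotation <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("symbol", "chromosome", "start", "end", "arm",
            "promoter_start", "promoter_end")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation lacks columns: ", paste(miss, collapse = ", "))
  if (any(ann$start > ann$end)) stop("annotation has start > end")
  if (any(ann$promoter_start > ann$promoter_end))
    stop("annotation has malformed promoter intervals")
  ann
}

#' @rdname load_annotation
#' @param ann annotation data.frame.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
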