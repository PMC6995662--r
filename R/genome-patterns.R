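#' Per-group median copy-number ("mountain") profile
#'
#' For every gene and every sample group, the median raw copy number over
#' the group's samples (missing values excluded), ordered along the genome
#' (chromosome, then position) with the arm recorded so centromere gaps can
#' be drawn. Uses raw copies — the diploid baseline is 2 and the normal
#' male chrY value is 1 — not the log2(CNV/2) classification scale.
#'
#' @param cnv_raw raw-scale CNV [omics_matrix()].
#' @param ann gene annotation; genes without annotation are dropped with a
#'   warning.
#' @param groups named list of sample-id vectors (e.g. current/never split
#'   by gender for the subgroup contrasts).
#' @return data.frame with `symbol`, `chromosome`, `arm`, `position`,
#'   one `median_<group>` column per group, ordered by genome position.
#' @export
mountain_profile <- function(cnv_raw, ann, groups) {
  if (!length(groups) || is.null(names(groups)))
    stop("'groups' must be a named list of sample-id vectors")
  for (g in names(groups)) {
    ids <- intersect(groups[[g]], sample_ids(cnv_raw))
    if (!length(ids)) stop("group '", g, "' has no samples in the matrix")
    groups[[g]] <- ids
  }
  covered <- intersect(gene_symbols(cnv_raw), ann$symbol)
  dropped <- setdiff(gene_symbols(cnv_raw), covered)
  if (length(dropped))
    warning(length(dropped), " gene(s) without annotation dropped")
  a <- ann[match(covered, ann$symbol), ]
  out <- data.frame(symbol = a$symbol, chromosome = a$chromosome,
                    arm = a$arm, position = a$start,
                    stringsAsFactors = FALSE)
  v <- cnv_raw$values[covered, , drop = FALSE]
  for (g in names(groups)) {
    block <- v[, groups[[g]], drop = FALSE]
    out[[paste0("median_", g)]] <- apply(block, 1, stats::median, na.rm = TRUE)
  }
  chrom_rank <- chrom_order(out$chromosome)
  out <- out[order(chrom_rank, out$position), ]
  rownames(out) <- NULL
  out
}

chrom_order <- function(chrom) {
  key <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(key))
  num[key == "X"] <- 23L
  num[key == "Y"] <- 24L
  num
}

#' Genome-wide copy-number deflection table
#'
#' Per-gene two-class comparison of copy numbers (Welch t-test, two-sided)
#' summarised as -log10 p with the direction of the larger group, plus the
#' Bonferroni cutoff for the retained gene count — the quantities behind a
#' deflection plot.
#'
#' @param cnv an [omics_matrix()] (any monotone scale; direction uses group
#'   medians).
#' @param labels binary 0/1 vector over samples (1 = smoker).
#' @param alpha family-wise level for the cutoff.
#' @return list with `table` (data.frame: `symbol`, `p_value`,
#'   `neg_log10_p`, `direction` in {"smoker", "nonsmoker"}, `exceeds`),
#'   `cutoff` (a [bonferroni_cutoff()]), and `fraction_exceeding`.
#' @export
deflection_table <- function(cnv, labels, alpha = 0.05) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("two classes required")
  v <- cnv$values
  p <- welch_p(v, labels)
  med1 <- apply(v[, labels == 1L, drop = FALSE], 1, stats::median, na.rm = TRUE)
  med0 <- apply(v[, labels == 0L, drop = FALSE], 1, stats::median, na.rm = TRUE)
  cut <- bonferroni_cutoff(sum(!is.na(p)), alpha)
  tab <- data.frame(symbol = gene_symbols(cnv), p_value = p,
                    neg_log10_p = -log10(p),
                    direction = ifelse(med1 >= med0, "smoker", "nonsmoker"),
                    exceeds = !is.na(p) & p < cut$per_test_p,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(table = tab, cutoff = cut,
       fraction_exceeding = mean(tab$exceeds[!is.na(p)]))
}

#' Focal amplicon peak calling on a mountain profile
#'
#' Finds local maxima of the per-gene median copy number along the genome
#' within each chromosome arm: a gene is a peak when it is the maximum of a
#' sliding window of `window` genes and rises at least `min_prominence`
#' copies above the window's baseline (the window minimum). All genes of
#' the peak plateau — within `tie_tol` copies of the peak maximum and
#' contiguous with it — are reported, so a flat planted amplicon yields its
#' full gene run.
#'
#' @param profile a [mountain_profile()] output.
#' @param group which group's median column to scan.
#' @param min_prominence minimum rise above the local baseline (copies).
#' @param window sliding-window width in genes.
#' @param tie_tol plateau tolerance in copies.
#' @return data.frame with one row per peak: `chromosome`, `arm`, `start`,
#'   `end`, `peak_median`, `n_genes`, `genes` (comma-joined plateau
#'   symbols).
#' @export
focal_peaks <- function(profile, group, min_prominence = 0.5, window = 25,
                        tie_tol = 0.1) {
  col <- paste0("median_", group)
  if (!col %in% names(profile)) stop("no such group column: ", col)
  peaks <- list()
  for (key in unique(paste(profile$chromosome, profile$arm))) {
    seg <- profile[paste(profile$chromosome, profile$arm) == key, ]
    y <- seg[[col]]
    m <- length(y)
    if (m < 3) next
    half <- max(1L, floor(window / 2))
    i <- 1L
    while (i <= m) {
      lo <- max(1L, i - half); hi <- min(m, i + half)
      win <- y[lo:hi]
      if (y[i] >= max(win) - 1e-12 && y[i] - min(win) >= min_prominence) {
        # plateau: contiguous genes within tie_tol of the peak value
        l <- i; while (l > 1L && y[l - 1L] >= y[i] - tie_tol) l <- l - 1L
        r <- i; while (r < m && y[r + 1L] >= y[i] - tie_tol) r <- r + 1L
        peaks[[length(peaks) + 1L]] <- data.frame(
          chromosome = seg$chromosome[1L], arm = seg$arm[1L],
          start = seg$position[l], end = seg$position[r],
          peak_median = max(y[l:r]), n_genes = r - l + 1L,
          genes = paste(seg$symbol[l:r], collapse = ","),
          stringsAsFactors = FALSE)
        i <- r + 1L
      } else i <- i + 1L
    }
  }
  if (!length(peaks))
    return(data.frame(chromosome = character(0), arm = character(0),
                      start = numeric(0), end = numeric(0),
                      peak_median = numeric(0), n_genes = integer(0),
                      genes = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, peaks)
  # merge duplicate reports of the same plateau
  out <- out[!duplicated(out[c("chromosome", "start", "end")]), ]
  rownames(out) <- NULL
  out
}

#' Chromosome-level median summary per group
#'
#' Convenience wrapper over [mountain_profile()]: the median of the
#' per-gene medians for one chromosome and each group — used to quantify
#' the broad chrY deficit of male never smokers.
#'
#' @param profile a [mountain_profile()] output.
#' @param chromosome chromosome name (e.g. `"chrY"`).
#' @return Named numeric vector, one entry per group column.
#' @export
chromosome_medians <- function(profile, chromosome) {
  seg <- profile[profile$chromosome == chromosome, ]
  if (!nrow(seg)) stop("no genes on ", chromosome)
  cols <- grep("^median_", names(profile), value = TRUE)
  out <- vapply(cols, function(cl) stats::median(seg[[cl]]), numeric(1))
  names(out) <- sub("^median_", "", cols)
  out
}
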