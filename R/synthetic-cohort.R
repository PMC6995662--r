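#' Configuration for a synthetic smoker/nonsmoker multi-omics cohort
#'
#' Defaults mirror the structure of the TCGA lung-adenocarcinoma training
#' cohort used throughout the package: 59 never smokers vs 82 current
#' smokers, a planted expression effect of two standard deviations on the
#' log2 scale, planted promoter-methylation genes anti-correlated with
#' their expression at r = -0.877, focal amplicons of +1.5 copies in
#' smokers placed in 7-gene runs, and a 0.4-copy chrY deficit in male never
#' smokers.
#'
#' @param n_never,n_current class sizes.
#' @param n_genes genome size (genes across chr1-22, X, Y).
#' @param n_signature_ge,n_signature_me,n_signature_cnv planted signature
#'   gene counts per layer (disjoint sets).
#' @param effect_size_ge standardized mean shift (Cohen's d) of planted GE
#'   genes between classes on the log2 scale.
#' @param me_ge_correlation target Pearson correlation, in \[-1, 0\],
#'   between a planted ME gene's beta values and its log2 expression.
#' @param amplicon_gain copy-number elevation of planted amplicons in the
#'   smoker class (copies above the diploid baseline).
#' @param amplicon_size genes per planted amplicon.
#' @param chry_deletion_depth copies subtracted from chrY in male never
#'   smokers.
#' @param missing_rate completely-at-random missingness fraction per layer,
#'   at most 0.05.
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_never = 59, n_current = 82, n_genes = 2000,
                          n_signature_ge = 40, n_signature_me = 40,
                          n_signature_cnv = 40, effect_size_ge = 2,
                          me_ge_correlation = -0.877,
                          amplicon_gain = 1.5, amplicon_size = 7,
                          chry_deletion_depth = 0.4,
                          missing_rate = 0.02, seed = 1L) {
  cfg <- list(n_never = n_never, n_current = n_current, n_genes = n_genes,
              n_signature_ge = n_signature_ge, n_signature_me = n_signature_me,
              n_signature_cnv = n_signature_cnv, effect_size_ge = effect_size_ge,
              me_ge_correlation = me_ge_correlation,
              amplicon_gain = amplicon_gain, amplicon_size = amplicon_size,
              chry_deletion_depth = chry_deletion_depth,
              missing_rate = missing_rate, seed = as.integer(seed))
  counts <- c("n_never", "n_current", "n_genes")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop("invalid cohort_config: '", f, "' must be a positive integer")
  for (f in c("n_signature_ge", "n_signature_me", "n_signature_cnv")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] != round(cfg[[f]]))
      stop("invalid cohort_config: '", f, "' must be a non-negative integer")
    if (cfg[[f]] > cfg$n_genes)
      stop("invalid cohort_config: '", f, "' exceeds n_genes")
  }
  if (!is.numeric(cfg$missing_rate) || cfg$missing_rate < 0 || cfg$missing_rate > 0.05)
    stop("invalid cohort_config: 'missing_rate' must lie in [0, 0.05]")
  if (!is.numeric(cfg$me_ge_correlation) ||
      cfg$me_ge_correlation < -1 || cfg$me_ge_correlation > 0)
    stop("invalid cohort_config: 'me_ge_correlation' must lie in [-1, 0]")
  if (!is.numeric(cfg$effect_size_ge) || cfg$effect_size_ge < 0)
    stop("invalid cohort_config: 'effect_size_ge' must be >= 0")
  if (!is.numeric(cfg$chry_deletion_depth) || cfg$chry_deletion_depth < 0 ||
      cfg$chry_deletion_depth >= 1)
    stop("invalid cohort_config: 'chry_deletion_depth' must lie in [0, 1)")
  structure(cfg, class = "cohort_config")
}

# Acrocentric chromosomes carry genes on the q arm only.
ACROCENTRIC <- c("chr13", "chr14", "chr15", "chr21", "chr22")

# Deterministic gene map: symbols, chromosome, position, arm, promoter.
synthetic_annotation <- function(n_genes) {
  chroms <- c(paste0("chr", 1:22), "chrX", "chrY")
  w <- c(10, 8, 8, 7, 7, 6.5, 6, 5.5, 5, 5, 5, 5, 4.5, 4.5, 4, 4, 4,
         3.5, 3.5, 3, 2.5, 2.5, 4, 1)
  counts <- pmax(4L, floor(n_genes * w / sum(w)))
  while (sum(counts) > n_genes) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n_genes) counts[which.max(w)] <- counts[which.max(w)] + 1L
  len <- 2.4e8 * w / max(w)
  cen <- 0.4 * len
  rows <- lapply(seq_along(chroms), function(i) {
    n <- counts[i]
    if (chroms[i] %in% ACROCENTRIC) {
      start <- round(seq(cen[i] + 1e6, len[i] - 1e5, length.out = n))
    } else {
      start <- round(seq(1e6, len[i] - 1e5, length.out = n))
      # keep gene bodies off the centromere
      start[start > cen[i] - 2e6 & start < cen[i] + 2e6] <- round(cen[i] + 2e6)
    }
    data.frame(chromosome = chroms[i], start = start, end = start + 5e4,
               arm = ifelse(start < cen[i], "p", "q"),
               centromere = round(cen[i]), stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  ann$symbol <- sprintf("SG%04d", seq_len(nrow(ann)))
  ann$promoter_start <- ann$start - 1500
  ann$promoter_end <- ann$start + 500
  ann[c("symbol", "chromosome", "start", "end", "arm",
        "promoter_start", "promoter_end", "centromere")]
}

#' Generate a seeded synthetic multi-omics cohort
#'
#' Draws a two-class (never vs current smoker) cohort with planted,
#' disjoint signature-gene sets per layer so that every downstream stage of
#' the pipeline is testable against known truth:
#' \itemize{
#'   \item GE: linear-scale expression whose log2 values are class-conditional
#'     Gaussians (unit residual SD); planted GE and ME genes are shifted by
#'     `effect_size_ge` between classes with a random sign.
#'   \item ME: beta values from a logit-normal construction; planted ME genes
#'     share a latent factor with their own expression, with sign-flipped
#'     loading, calibrated to the target Pearson correlation.
#'   \item CNV: raw copy numbers, piecewise constant along chromosome arms
#'     (per-sample arm offsets), diploid autosomal baseline; planted
#'     amplicons of `amplicon_size` contiguous genes gain `amplicon_gain`
#'     copies in current smokers and drive expression with a dosage slope of
#'     1 log2 unit per copy; chrY has a single copy in males, reduced by
#'     `chry_deletion_depth` in male never smokers, and a 0.05-copy sentinel
#'     in females (a small constant keeps the log2(CNV/2) transform finite).
#' }
#' Missing entries are placed completely at random at `missing_rate`.
#'
#' The genome structure — gene map, planted gene sets, amplicon placement,
#' shift signs and per-gene baselines — is drawn from `structure_seed`,
#' while samples, noise and missingness are drawn from `config$seed`. Two
#' cohorts generated with the same `structure_seed` but different sample
#' seeds therefore share the same underlying biology (an independent
#' validation cohort from the same generative process); by default
#' `structure_seed = config$seed`, so a single call is fully reproducible
#' from one seed.
#'
#' @param config a [cohort_config()].
#' @param structure_seed seed for the genome structure (defaults to
#'   `config$seed`).
#' @return list with `ge`, `me`, `cnv` ([omics_matrix()]; GE linear scale,
#'   ME beta scale, CNV raw copies), `samples` (sample table), `annotation`,
#'   and `truth` (planted gene sets and amplicon regions).
#' @export
generate_cohort <- function(config = cohort_config(),
                            structure_seed = config$seed) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)

  n <- config$n_never + config$n_current
  ann <- synthetic_annotation(config$n_genes)
  p <- nrow(ann)
  autosomal <- !(ann$chromosome %in% c("chrX", "chrY"))

  # ---- structural phase: planted gene sets and baselines ----------------
  set.seed(structure_seed)
  # amplicons: contiguous runs on distinct autosomal q arms
  planted_cnv <- character(0)
  amplicons <- list()
  if (config$n_signature_cnv > 0) {
    armtab <- table(ann[autosomal & ann$arm == "q", "chromosome"])
    arms <- names(armtab)[armtab >= config$amplicon_size + 2]
    need <- ceiling(config$n_signature_cnv / config$amplicon_size)
    if (need > length(arms)) stop("not enough arms to place amplicons")
    chosen_arms <- sample(arms, need)
    left <- config$n_signature_cnv
    for (a in chosen_arms) {
      idx <- which(ann$chromosome == a & ann$arm == "q")
      size <- min(config$amplicon_size, left)
      s <- sample(seq_len(length(idx) - size + 1 - 1) + 1, 1)  # not at arm edge
      run <- idx[s:(s + size - 1)]
      amplicons[[length(amplicons) + 1L]] <- list(
        chromosome = a, start = ann$start[run[1]], end = ann$end[run[length(run)]],
        genes = ann$symbol[run], gain = config$amplicon_gain, class = "current")
      planted_cnv <- c(planted_cnv, ann$symbol[run])
      left <- left - size
    }
  }
  pool <- setdiff(ann$symbol[autosomal], planted_cnv)
  planted_ge <- sort(sample(pool, config$n_signature_ge))
  pool <- setdiff(pool, planted_ge)
  planted_me <- sort(sample(pool, config$n_signature_me))
  shift_sign <- stats::setNames(sample(c(-1, 1), p, replace = TRUE), ann$symbol)
  mu <- stats::rnorm(p, 7, 1.5)      # per-gene log2 expression baseline
  mu_m <- stats::rnorm(p, 0, 0.5)    # per-gene logit-methylation baseline

  # ---- sampling phase: cohort, noise, missingness -----------------------
  set.seed(config$seed)
  ids <- sprintf("S%04d", seq_len(n))
  smoking <- c(rep("never", config$n_never), rep("current", config$n_current))
  gender <- sample(c("male", "female"), n, replace = TRUE)
  samples <- data.frame(
    sample_id = ids, smoking = smoking,
    age = round(stats::rnorm(n, 65, 8)), gender = gender,
    stage = sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                   prob = c(0.5, 0.25, 0.18, 0.07)),
    vital_status = sample(c("alive", "dead"), n, replace = TRUE, prob = c(0.6, 0.4)),
    stringsAsFactors = FALSE)
  is_current <- smoking == "current"
  is_male <- gender == "male"

  # ---- CNV layer --------------------------------------------------------
  cn <- matrix(2, p, n)
  arm_key <- paste(ann$chromosome, ann$arm)
  for (k in unique(arm_key)) {
    rows <- arm_key == k
    cn[rows, ] <- cn[rows, ] + rep(stats::rnorm(n, 0, 0.05), each = sum(rows))
  }
  chry <- ann$chromosome == "chrY"
  cn[chry, ] <- 1
  cn[chry, !is_male] <- 0.05
  if (any(chry) && config$chry_deletion_depth > 0) {
    grp <- is_male & !is_current
    cn[chry, grp] <- cn[chry, grp] - config$chry_deletion_depth
  }
  for (am in amplicons) {
    rows <- match(am$genes, ann$symbol)
    cn[rows, is_current] <- cn[rows, is_current] + am$gain
  }
  cn <- cn + matrix(stats::rnorm(p * n, 0, 0.1), p, n)
  cn <- pmax(cn, 0.05)

  # ---- GE layer (log2 scale, then to linear) ----------------------------
  z <- matrix(stats::rnorm(p * n), p, n) + mu
  shifted <- c(planted_ge, planted_me)
  if (length(shifted)) {
    rows <- match(shifted, ann$symbol)
    z[rows, is_current] <- z[rows, is_current] +
      config$effect_size_ge * shift_sign[shifted]
  }
  if (length(planted_cnv)) {     # dosage effect: 1 log2 unit per copy
    rows <- match(planted_cnv, ann$symbol)
    z[rows, ] <- z[rows, ] + (cn[rows, ] - 2)
  }
  ge <- pmax(2^z - 1, 0)

  # ---- ME layer (beta scale via logit-normal) ---------------------------
  rho <- abs(config$me_ge_correlation)
  logit_m <- mu_m + 0.6 * matrix(stats::rnorm(p * n), p, n)
  if (length(planted_me)) {
    rows <- match(planted_me, ann$symbol)
    for (r in rows) {
      zc <- (z[r, ] - mean(z[r, ])) / stats::sd(z[r, ])
      logit_m[r, ] <- mu_m[r] +
        0.6 * (-rho * zc + sqrt(1 - rho^2) * stats::rnorm(n))
    }
  }
  me <- stats::plogis(logit_m)

  # ---- MCAR missingness -------------------------------------------------
  drop_mcar <- function(v) {
    if (config$missing_rate <= 0) return(v)
    hit <- stats::runif(length(v)) < config$missing_rate
    v[hit] <- NA_real_
    v
  }
  ge <- drop_mcar(ge); me <- drop_mcar(me); cn <- drop_mcar(cn)

  truth <- list(planted_ge = planted_ge, planted_me = planted_me,
                planted_cnv = sort(planted_cnv),
                amplicon_regions = amplicons,
                ge_shift_sign = shift_sign[shifted])
  list(ge = omics_matrix(ge, "GE", ann$symbol, ids),
       me = omics_matrix(me, "ME", ann$symbol, ids),
       cnv = omics_matrix(cn, "CNV", ann$symbol, ids),
       samples = samples,
       annotation = ann,
       truth = truth,
       config = config)
}

#' Write a generated cohort to disk
#'
#' Emits the three layers as TSV matrices, the sample table and annotation
#' as TSV, and the ground truth as JSON, under `dir`.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ge = file.path(dir, "ge.tsv"), me = file.path(dir, "me.tsv"),
             cnv = file.path(dir, "cnv.tsv"),
             samples = file.path(dir, "samples.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth = file.path(dir, "truth.json"))
  write_omics(cohort$ge, paths["ge"])
  write_omics(cohort$me, paths["me"])
  write_omics(cohort$cnv, paths["cnv"])
  write_sample_table(cohort$samples, paths["samples"])
  write_annotation(cohort$annotation, paths["annotation"])
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
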