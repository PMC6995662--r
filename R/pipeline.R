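#' Default run configuration
#'
#' A single list drives an end-to-end run: cohort generation (or file
#' paths), preprocessing, selection thresholds, cross-validation and
#' kernel settings. Any subset of fields may be overridden; unknown fields
#' are rejected. The configuration round-trips through YAML.
#'
#' @param ... overrides of the default fields.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    layer = "GE",              # GE, ME or CNV
    cohort = list(),           # cohort_config() overrides for simulation
    validation_seed_offset = 1000L,  # seed shift for the held-out cohort
    fdr_cutoff = 0.1,
    cor_threshold = 0.5,
    n_permutations = 1000,
    max_A = 10,
    cv_folds = 5,
    patience = 10,
    seed = 1L,
    out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# Preprocess one generated cohort into analysis-ready (imputed, transformed)
# layer matrices plus labels. The reference cohort supplies imputation means
# when given (training-only imputation for validation data).
prepare_cohort <- function(cohort, reference = NULL) {
  ge <- transform_ge(filter_genes(cohort$ge))
  me <- filter_genes(cohort$me)
  cnv <- transform_cnv(filter_genes(cohort$cnv))
  ref <- if (is.null(reference)) list(ge = NULL, me = NULL, cnv = NULL)
         else reference$layers
  list(layers = list(ge = impute_gene_means(ge, ref$ge),
                     me = impute_gene_means(me, ref$me),
                     cnv = impute_gene_means(cnv, ref$cnv)),
       labels = smoking_labels(cohort$samples),
       samples = cohort$samples,
       annotation = cohort$annotation,
       truth = cohort$truth)
}

#' Run the full pipeline on synthetic cohorts
#'
#' Generates a training and an independent validation cohort from the same
#' generative configuration (different seeds), preprocesses both, runs the
#' three-stage signature identification on the requested layer, and
#' reports cross-validated, resubstitution and held-out metrics. A run
#' manifest recording every seed and parameter is attached (and written to
#' `out_dir` when set).
#'
#' @param config a [run_config()].
#' @param curated curated gene symbols injected at stage 2.
#' @return list with `signature` (a `signature_set`), `train`, `validation`
#'   (prepared cohorts), and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), curated = character(0)) {
  layer <- tolower(config$layer)
  ccfg <- do.call(cohort_config, utils::modifyList(
    config$cohort, list(seed = config$seed)))
  vcfg <- do.call(cohort_config, utils::modifyList(
    config$cohort, list(seed = config$seed + config$validation_seed_offset)))
  # the validation cohort shares the genome structure (planted sets,
  # baselines) but draws fresh samples
  train <- prepare_cohort(generate_cohort(ccfg))
  validation <- prepare_cohort(generate_cohort(vcfg,
                                               structure_seed = ccfg$seed))

  sig <- run_layer(train$layers[[layer]], train$layers$ge, train$labels,
                   layer = toupper(layer), curated = curated,
                   validation_matrix = validation$layers[[layer]],
                   validation_labels = validation$labels,
                   fdr_cutoff = config$fdr_cutoff,
                   cor_threshold = config$cor_threshold,
                   n_permutations = config$n_permutations,
                   max_A = config$max_A, k = config$cv_folds,
                   patience = config$patience, seed = config$seed)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tobsig")),
    layer = toupper(layer),
    cohort_config = unclass(ccfg),
    validation_seed = vcfg$seed,
    fdr_cutoff = config$fdr_cutoff, cor_threshold = config$cor_threshold,
    n_permutations = config$n_permutations, max_A = config$max_A,
    cv_folds = config$cv_folds, patience = config$patience,
    seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_signature_set(sig, config$out_dir)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(signature = sig, train = train, validation = validation,
       manifest = manifest)
}

#' Table-2-shaped metrics summary
#'
#' Flattens a `signature_set`'s metrics into the reporting layout used for
#' the study's classification table: one row per dataset role with SN, SP
#' and ACC as percentages to one decimal.
#'
#' @param sig a `signature_set`.
#' @return data.frame with `layer`, `dataset`, `n_signature`, `SN`, `SP`,
#'   `ACC` (percent, 1 decimal).
#' @export
metrics_table <- function(sig) {
  rows <- lapply(names(sig$metrics), function(nm) {
    m <- sig$metrics[[nm]]
    data.frame(layer = sig$layer, dataset = nm,
               n_signature = length(sig$genes),
               SN = round(100 * m$sensitivity, 1),
               SP = round(100 * m$specificity, 1),
               ACC = round(100 * m$accuracy, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Curated gene list shipped for tests and examples
#'
#' A small synthetic stand-in for a curated literature list (the symbols
#' follow the generator's `SGxxxx` scheme); real analyses should supply
#' their own list.
#'
#' @return character vector of symbols.
#' @export
curated_genes_synthetic <- function() {
  path <- system.file("extdata", "curated_genes_synthetic.txt",
                      package = "tobsig")
  if (path == "") stop("fixture not installed")
  readLines(path)
}
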