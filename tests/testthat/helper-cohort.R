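# Shared fixtures: cohorts are generated once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# small cohort for fast unit tests (not the study conditions)
small_cohort <- function(seed = 11) {
  cached(paste0("small", seed), generate_cohort(cohort_config(
    n_never = 30, n_current = 40, n_genes = 600,
    n_signature_ge = 12, n_signature_me = 12, n_signature_cnv = 14,
    amplicon_size = 7, seed = seed)))
}

small_prepared <- function(seed = 11) {
  cached(paste0("smallprep", seed), tobsig:::prepare_cohort(small_cohort(seed)))
}

# study-sized cohort (59 + 82, 2000 genes) shared by the acceptance tests
study_cohort <- function(seed = 1) {
  cached(paste0("study", seed), generate_cohort(cohort_config(seed = seed)))
}

study_prepared <- function(seed = 1) {
  cached(paste0("studyprep", seed), tobsig:::prepare_cohort(study_cohort(seed)))
}

null_cohort_config <- function(seed) {
  cohort_config(seed = seed, effect_size_ge = 0, n_signature_ge = 0,
                n_signature_me = 0, n_signature_cnv = 0,
                chry_deletion_depth = 0)
}

# tiny deterministic matrix fixture
toy_matrix <- function(p = 6, n = 10, seed = 5) {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("G%02d", 1:p), sprintf("s%02d", 1:n)))
  m
}
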