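test_that("statistical candidates follow the layer-specific rules", {
  prep <- small_prepared()
  truth <- small_cohort()$truth
  ge_cand <- statistical_candidates(prep$layers$ge, prep$layers$ge,
                                    prep$labels, "GE",
                                    n_permutations = 150, seed = 2)
  expect_gte(mean(truth$planted_ge %in% ge_cand), 0.9)
  # ME/CNV correlation power is assessed at the study sample size (n = 141)
  sprep <- study_prepared(1)
  struth <- study_cohort(1)$truth
  me_cand <- statistical_candidates(sprep$layers$me, sprep$layers$ge,
                                    sprep$labels, "ME")
  expect_gte(mean(struth$planted_me %in% me_cand), 0.95)
  cnv_cand <- statistical_candidates(sprep$layers$cnv, sprep$layers$ge,
                                     sprep$labels, "CNV")
  expect_gte(mean(struth$planted_cnv %in% cnv_cand), 0.9)
})

test_that("the correlation threshold is a strict boundary at |r| = 0.5", {
  n <- 200
  set.seed(17)
  g <- rnorm(n)
  make_with_r <- function(target) {
    eps <- rnorm(n)
    eps <- residuals(lm(eps ~ g))
    x <- target * g / sd(g) + sqrt(1 - target^2) * eps / sd(eps)
    x  # exact sample correlation = target by construction
  }
  ge <- omics_matrix(rbind(A = g, B = g), "GE",
                     sample_ids = paste0("s", 1:n))
  lv <- rbind(A = make_with_r(-0.49), B = make_with_r(-0.51))
  lv <- lv - min(lv) + 0.1                    # shift into valid CNV range
  lay <- omics_matrix(lv, "CNV", sample_ids = paste0("s", 1:n))
  sel <- correlation_filter(lay, ge, threshold = 0.5)
  expect_false("A" %in% sel)
  expect_true("B" %in% sel)
})

test_that("curated genes are merged, restricted to the universe, and flagged", {
  out <- merge_experimental(c("A", "B"), c("B", "C", "Z"),
                            universe = c("A", "B", "C", "D")) |>
    suppressWarnings()
  expect_setequal(as.character(out), c("A", "B", "C"))
  expect_identical(attr(out, "injected"), "C")
  expect_warning(merge_experimental(c("A"), c("Z"), c("A", "B")), "skipped")
  none <- merge_experimental(c("A", "B"), character(0), c("A", "B"))
  expect_setequal(as.character(none), c("A", "B"))
})

test_that("elimination removes one gene per iteration and returns the best set", {
  prep <- small_prepared()
  truth <- small_cohort()$truth
  cand <- union(truth$planted_ge,
                sample(setdiff(rownames(prep$layers$ge$values),
                               truth$planted_ge), 30))
  X <- t(prep$layers$ge$values[cand, ])
  elim <- iterative_elimination(X, prep$labels, max_A = 5, seed = 3,
                                patience = 5)
  tr <- elim$trace
  expect_identical(diff(tr$remaining_count), rep(-1L, nrow(tr) - 1L))
  expect_identical(max(tr$cv_accuracy), elim$best_accuracy)
  expect_gte(elim$best_accuracy, tr$cv_accuracy[1] - 0.01)
  expect_length(elim$signature, tr$remaining_count[elim$best_iteration])
  # determinism
  elim2 <- iterative_elimination(X, prep$labels, max_A = 5, seed = 3,
                                 patience = 5)
  expect_identical(elim$signature, elim2$signature)
  # two-gene boundary: at most one removal recorded, no removal applied
  e2 <- iterative_elimination(X[, 1:2], prep$labels, max_A = 2, seed = 1)
  expect_identical(nrow(e2$trace), 1L)
  expect_error(iterative_elimination(X[, 1, drop = FALSE], prep$labels),
               "at least 2")
})

test_that("a duplicated gene rarely survives elimination twice", {
  prep <- small_prepared()
  truth <- small_cohort()$truth
  base <- t(prep$layers$ge$values[truth$planted_ge[1:8], ])
  survived_both <- 0
  for (s in 1:10) {
    X <- cbind(base, DUP1 = base[, 1], DUP2 = base[, 1] + rnorm(nrow(base), 0, 1e-6))
    colnames(X)[1] <- "ORIG"
    elim <- iterative_elimination(X, prep$labels, max_A = 3, seed = s,
                                  patience = 3)
    copies <- sum(c("ORIG", "DUP1", "DUP2") %in% elim$signature)
    if (copies > 2) survived_both <- survived_both + 1
  }
  expect_lte(survived_both, 1)
})

test_that("run_layer chains the stages and reports all metric roles", {
  prep <- small_prepared()
  co_val <- generate_cohort(cohort_config(
    n_never = 30, n_current = 40, n_genes = 600, n_signature_ge = 12,
    n_signature_me = 12, n_signature_cnv = 14, amplicon_size = 7, seed = 207),
    structure_seed = 11)
  prep_val <- tobsig:::prepare_cohort(co_val)
  sig <- run_layer(prep$layers$ge, prep$layers$ge, prep$labels, "GE",
                   curated = character(0),
                   validation_matrix = prep_val$layers$ge,
                   validation_labels = prep_val$labels,
                   n_permutations = 150, max_A = 5, patience = 5, seed = 2)
  expect_s3_class(sig, "signature_set")
  expect_true(all(sig$genes %in% sig$candidates))
  expect_named(sig$metrics, c("cv", "resubstitution_pls", "resubstitution_kpls",
                              "validation_pls", "validation_kpls"))
  expect_gte(sig$metrics$validation_kpls$accuracy, 0.76)
  tab <- metrics_table(sig)
  expect_identical(nrow(tab), 5L)
  expect_true(all(tab$ACC >= 0 & tab$ACC <= 100))
  # curated injection shows up in provenance
  extra <- setdiff(rownames(prep$layers$ge$values), sig$candidates)[1]
  sig2 <- run_layer(prep$layers$ge, prep$layers$ge, prep$labels, "GE",
                    curated = extra, n_permutations = 150, max_A = 5,
                    patience = 5, seed = 2)
  expect_identical(sig2$injected, extra)
  # outputs round-trip to disk
  dir <- withr::local_tempdir()
  write_signature_set(sig, dir)
  expect_true(file.exists(file.path(dir, "signature_ge.tsv")))
  mj <- jsonlite::read_json(file.path(dir, "metrics_ge.json"))
  expect_equal(mj$n_signature, length(sig$genes))
})
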