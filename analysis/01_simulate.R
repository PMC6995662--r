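#!/usr/bin/env Rscript
# Simulate the study cohorts: a training cohort shaped like the TCGA LUAD
# never/current-smoker contrast (59 + 82 samples, 2000 genes, planted
# expression / methylation / copy-number signatures) and an independent
# validation cohort sharing the same genome structure, then write both to
# results/cohorts/ as TSV + JSON.

suppressMessages(library(tobsig))

seed <- 1L
cfg <- cohort_config(seed = seed)
train <- generate_cohort(cfg)
validation <- generate_cohort(cohort_config(seed = seed + 1000L),
                              structure_seed = seed)

dir.create("results/cohorts", showWarnings = FALSE, recursive = TRUE)
write_cohort(train, "results/cohorts/train")
write_cohort(validation, "results/cohorts/validation")

cat("Training cohort:\n")
print(table(train$samples$smoking, train$samples$gender))
cat(sprintf("Planted: %d GE, %d ME, %d CNV genes in %d amplicons\n",
            length(train$truth$planted_ge), length(train$truth$planted_me),
            length(train$truth$planted_cnv),
            length(train$truth$amplicon_regions)))
ge_log <- log2(train$ge$values + 1)
r <- vapply(train$truth$planted_me, function(g)
  cor(train$me$values[g, ], ge_log[g, ], use = "complete.obs"), numeric(1))
cat(sprintf("Mean ME-GE correlation over planted ME genes: %.3f\n", mean(r)))
cat("Cohorts written under results/cohorts/\n")
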