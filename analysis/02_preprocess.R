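#!/usr/bin/env Rscript
# Preprocess the simulated cohorts the way the study preprocesses TCGA
# level-3 data: drop all-missing genes, log2-transform expression,
# log2(CNV/2)-transform copy numbers, restrict to genes common to training
# and validation, and impute remaining gaps with training gene means.
# Writes analysis-ready matrices under results/prepared/.

suppressMessages(library(tobsig))

read_cohort <- function(dir) {
  list(ge = load_omics(file.path(dir, "ge.tsv"), "GE"),
       me = load_omics(file.path(dir, "me.tsv"), "ME"),
       cnv = load_omics(file.path(dir, "cnv.tsv"), "CNV"),
       samples = load_sample_table(file.path(dir, "samples.tsv")))
}
train <- read_cohort("results/cohorts/train")
validation <- read_cohort("results/cohorts/validation")

dir.create("results/prepared", showWarnings = FALSE, recursive = TRUE)
for (layer in c("ge", "me", "cnv")) {
  tr <- filter_genes(train[[layer]])
  va <- filter_genes(validation[[layer]])
  if (layer == "ge") { tr <- transform_ge(tr); va <- transform_ge(va) }
  if (layer == "cnv") { tr <- transform_cnv(tr); va <- transform_cnv(va) }
  both <- intersect_common_genes(tr, va)
  tr_i <- impute_gene_means(both$train)
  va_i <- impute_gene_means(both$validation, reference = both$train)
  write_omics(tr_i, sprintf("results/prepared/train_%s.tsv", layer))
  write_omics(va_i, sprintf("results/prepared/validation_%s.tsv", layer))
  cat(sprintf("%-4s %d common genes, %.1f%% cells imputed in training\n",
              toupper(layer), nrow(tr_i$values),
              100 * mean(both$train$missing_mask)))
}
write_sample_table(train$samples, "results/prepared/train_samples.tsv")
write_sample_table(validation$samples, "results/prepared/validation_samples.tsv")
cat("Prepared matrices written under results/prepared/\n")
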