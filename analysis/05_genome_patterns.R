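#!/usr/bin/env Rscript
# Genome-overview copy-number patterns: per-group median mountain
# profiles (current/never crossed with gender), the deflection table with
# its Bonferroni cutoff, chrY medians, and focal amplicon peak calls.
# Works on RAW copy numbers, where diploid = 2 and normal male chrY = 1.
# Writes tables under results/patterns/.

suppressMessages(library(tobsig))

co <- list(
  cnv = load_omics("results/cohorts/train/cnv.tsv", "CNV"),
  samples = load_sample_table("results/cohorts/train/samples.tsv"),
  annotation = load_annotation("results/cohorts/train/annotation.tsv"))
st <- co$samples
male <- st$gender == "male"
groups <- list(
  current = st$sample_id[st$smoking == "current"],
  never = st$sample_id[st$smoking == "never"],
  male_current = st$sample_id[male & st$smoking == "current"],
  male_never = st$sample_id[male & st$smoking == "never"],
  female_never = st$sample_id[!male & st$smoking == "never"])

dir.create("results/patterns", showWarnings = FALSE, recursive = TRUE)
prof <- mountain_profile(co$cnv, co$annotation, groups)
write.table(prof, "results/patterns/mountain_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

med <- chromosome_medians(prof, "chrY")
cat("chrY median copy number per group:\n")
print(round(med, 3))

# deflection on the classification scale
cnv_log <- transform_cnv(filter_genes(co$cnv))
y <- smoking_labels(st)
defl <- deflection_table(impute_gene_means(cnv_log), y)
write.table(defl$table, "results/patterns/deflection.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nDeflection: %.2f%% of %d genes beyond the Bonferroni line (-log10 p = %.2f)\n",
            100 * defl$fraction_exceeding, defl$cutoff$n_tests,
            defl$cutoff$neg_log10))

peaks <- focal_peaks(prof, "current", min_prominence = 0.5, window = 25)
write.table(peaks, "results/patterns/focal_peaks.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\n%d focal amplicon peak(s) in current smokers:\n", nrow(peaks)))
print(peaks[c("chromosome", "arm", "peak_median", "n_genes", "genes")],
      row.names = FALSE)
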