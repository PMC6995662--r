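#!/usr/bin/env Rscript
# Genome-wide differential landscape between current and never smokers:
# SAM permutation analysis of expression, the volcano table with its
# Bonferroni cutoff, and the ME-GE / CNV-GE correlation screens.
# Writes per-gene tables under results/differential/.

suppressMessages(library(tobsig))

ge <- load_omics("results/prepared/train_ge.tsv", "GE")
me <- load_omics("results/prepared/train_me.tsv", "ME")
cnv <- load_omics("results/prepared/train_cnv.tsv", "CNV")
st <- load_sample_table("results/prepared/train_samples.tsv")
y <- smoking_labels(st)

dir.create("results/differential", showWarnings = FALSE, recursive = TRUE)

sam <- sam_fdr(ge, y, n_permutations = 1000, seed = 1)
write.table(sam, "results/differential/sam_ge.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("SAM (s0 = %.3f): %d of %d genes at q <= 0.1\n",
            attr(sam, "s0"), sum(sam$selected), nrow(sam)))

# volcano: fold change on the linear scale, Welch p on the log scale
vt <- volcano_table(2^ge$values - 1, y, X_test = ge$values)
cut <- bonferroni_cutoff(nrow(vt), 0.05)
vt$exceeds <- vt$p_value < cut$per_test_p
write.table(vt, "results/differential/volcano_ge.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("Volcano: Bonferroni cutoff p = %.3g (-log10 = %.2f); %d genes beyond it\n",
            cut$per_test_p, cut$neg_log10, sum(vt$exceeds)))

for (nm in c("me", "cnv")) {
  layer <- if (nm == "me") me else cnv
  sel <- correlation_filter(layer, ge, threshold = 0.5)
  r <- attr(sel, "r")
  write.table(data.frame(symbol = names(r), r = unname(r),
                         selected = names(r) %in% sel),
              sprintf("results/differential/correlation_%s.tsv", nm),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s-GE screen: %d genes with |r| > 0.5 (strongest r = %.3f)\n",
              toupper(nm), length(sel), r[which.max(abs(r))]))
}
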