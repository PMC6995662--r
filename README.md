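# tobsig — tobacco-exposure signature genes from multi-omics LUAD cohorts

Lung adenocarcinoma (LUAD) in current smokers and never smokers is
thought to arise through different molecular mechanisms. `tobsig`
implements an integrated pipeline that, given gene expression (GE),
promoter methylation (ME, beta values) and copy number (CNV) for a
two-class cohort, identifies per-layer **signature genes** whose values
alone classify tobacco exposure, and computes the genome-overview
summaries (volcano tables, copy-number deflection and per-group median
"mountain" profiles, focal amplicon peaks) used to describe smoker vs
never-smoker differences genome-wide.

The selection funnel has three stages per layer:

1. **Statistical selection** — GE: SAM-style moderated statistic
   *d* = (x̄₁ − x̄₀)/(s + s₀) with permutation-estimated q-values,
   candidates at q ≤ 0.1. ME/CNV: genes whose layer values track their
   own expression with |Pearson r| > 0.5.
2. **Experimental selection** — a curated gene list is unioned in so
   established biology is not overwhelmed by ~20,000-gene search space.
3. **Iterative contribution selection** — backward elimination driven by
   linear PLS (NIPALS): genes are ranked by |autoscaled regression
   coefficient|, the least important gene is removed, the model refitted,
   and stratified 5-fold cross-validated accuracy tracked; the signature
   is the gene set at the best-accuracy iteration.

A kernel PLS classifier (linear/RBF, CV-tuned) is fitted on the final
signature; sensitivity (smoker recall), specificity (never-smoker
recall) and accuracy are reported for training CV, resubstitution and a
held-out validation cohort. A seeded synthetic multi-omics cohort
generator with planted signatures stands in for consortium downloads and
makes every stage testable against known ground truth.

## Worked example

```r
library(tobsig)

cfg <- cohort_config(seed = 1)              # 59 never / 82 current, 2000 genes
train      <- generate_cohort(cfg)
validation <- generate_cohort(cohort_config(seed = 1001), structure_seed = 1)

tr  <- tobsig:::prepare_cohort(train)       # transforms + imputation
va  <- tobsig:::prepare_cohort(validation)

sig <- run_layer(tr$layers$ge, tr$layers$ge, tr$labels, "GE",
                 validation_matrix = va$layers$ge,
                 validation_labels = va$labels,
                 n_permutations = 300, max_A = 5, seed = 1)
metrics_table(sig)
```

```
  layer             dataset n_signature  SN  SP ACC
1    GE                  cv         122 100 100 100
2    GE  resubstitution_pls         122 100 100 100
3    GE resubstitution_kpls         122 100 100 100
4    GE      validation_pls         122 100 100 100
5    GE     validation_kpls         122 100 100 100
```

All 40 planted expression genes are recovered in the 122-gene signature
(the remaining genes are the ME/CNV-coupled genes, which also shift
expression, plus a handful of borderline candidates), and the classifier
transfers perfectly to the independent validation cohort — the planted
effect (d = 2 on the log2 scale) is strongly separable by design.

The genome-pattern side, on raw copy numbers:

```r
st <- train$samples; male <- st$gender == "male"
prof <- mountain_profile(train$cnv, train$annotation, list(
  male_never   = st$sample_id[male & st$smoking == "never"],
  male_current = st$sample_id[male & st$smoking == "current"],
  current      = st$sample_id[st$smoking == "current"]))
chromosome_medians(prof, "chrY")
#>   male_never male_current      current
#>        0.602        1.009        0.215
focal_peaks(prof, "current", min_prominence = 0.5, window = 25)[, c("chromosome", "peak_median", "n_genes")]
```

The male never-smoker chrY median sits at 1 − 0.4 = 0.6 copies against
~1.0 in male current smokers (the planted broad deletion), and each
planted 7-gene +1.5-copy amplicon is reported as a single 7-gene peak
plateau.

## Analysis workflow

The numbered drivers under `analysis/` run the full study end to end,
writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generate training + validation cohorts, write TSV/JSON |
| `02_preprocess.R` | missing-gene filtering, log2 / log2(CNV/2), common genes, imputation |
| `03_differential_landscape.R` | SAM q-values, volcano table with Bonferroni cutoff, ME/CNV–GE correlation screens |
| `04_signature_selection.R` | three-stage selection + KPLS for all three layers |
| `05_genome_patterns.R` | mountain profiles, deflection table, chrY medians, focal peaks |

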