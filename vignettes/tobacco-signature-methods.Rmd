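---
title: "Methods: tobacco-exposure signature identification from multi-omics LUAD cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tobacco-exposure signature identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tobsig)
```

## The problem

Lung adenocarcinoma (LUAD) in current smokers and in never smokers is
believed to arise through different molecular routes. Given gene
expression (GE, linear-scale abundances), promoter methylation (ME, beta
values in $[0,1]$) and copy number (CNV, raw copies with diploid baseline
2) for a two-class cohort, `tobsig` identifies, per layer, a compact set
of *signature genes* whose values alone classify tobacco exposure, and
computes the genome-overview summaries (volcano, deflection and mountain
profiles) that describe how the two groups differ genome-wide.

The smoker class is the positive class throughout: sensitivity is the
smoker detection rate, specificity the never-smoker detection rate. The
default contrast is current-vs-never; cohorts that only record "ever"
smokers use the same machinery with `positive = "ever"`.

## The selection procedure

Identification is a three-stage funnel, applied independently per layer:

1. **Statistical selection.** For GE, a SAM-style moderated statistic
   $d_i = \frac{\bar x_{i,1} - \bar x_{i,0}}{s_i + s_0}$ is computed per
   gene, where $s_i$ is the pooled standard-error term of the two-sample
   $t$ statistic and $s_0$ a fudge factor stabilising low-variance genes
   ($s_0 = 0$ recovers the pooled $t$ exactly — a tested equivalence).
   $q$-values come from a permutation null: labels are permuted with
   proportional stratification across the true classes, the expected
   number of null genes beyond each observed $|d_i|$ is compared with the
   observed count, and the ratio — with the null proportion $\pi_0$ fixed
   conservatively at 1 — is made monotone in $|d|$ and capped at 1. Genes
   with $q \le 0.1$ are candidates. For ME and CNV, candidates are genes
   whose layer values track their own expression with $|r| > 0.5$
   (Pearson, pairwise-complete): coupling to transcription is evidence the
   variation is not platform noise.
2. **Experimental selection.** A curated list of genes with prior
   experimental support is unioned into the candidates (restricted to
   genes present in the data), so that a handful of biologically
   established genes is not overwhelmed by the genome-wide search. The
   shipped list (`curated_genes_synthetic()`) is a synthetic stand-in
   matching the generator's symbol scheme.
3. **Iterative contribution selection.** A linear PLS discriminant model
   is fitted on the remaining genes; each gene's *contribution* is the
   absolute value of its regression coefficient on autoscaled predictors.
   The least-contributing gene is removed, the model refitted, and
   stratified 5-fold cross-validated accuracy recorded at every step. The
   loop stops when the running best accuracy has not improved for
   `patience` consecutive removals (default 10) or two genes remain; the
   signature is the set at the best-accuracy iteration, ties resolved
   toward fewer genes.

A kernel PLS classifier is then fitted on the final signature — selection
itself always uses linear PLS — with the kernel and component count chosen
by cross-validation over a small grid (linear plus RBF with
$\gamma \in 2^{-3..3}/p$), ties resolved toward the simplest kernel.

### Numerical choices

* **PLS.** Univariate-response NIPALS with deflation; predictors are
  autoscaled (centered, unit variance) and the 0/1 label centered.
  Autoscaling is what makes coefficients comparable across genes, which
  the contribution ranking requires. There is no random initialisation:
  fits are deterministic. At full rank the coefficients equal ordinary
  least squares (tested at 1e-8); successive scores are orthogonal.
  Contribution ties are broken by ascending gene symbol. The number of
  components is chosen per refit by the same 5-fold CV (smallest count at
  maximal accuracy, capped at `max_A`, default 10; the analysis scripts
  use 5).
* **KPLS.** The Gram matrix of the autoscaled inputs is double-centered
  ($K_c = (I - \tfrac{1}{n}J)K(I - \tfrac{1}{n}J)$) and deflated per
  component; prediction centers the test block against the training
  geometry. With a linear kernel the model reproduces linear PLS to 1e-6
  — the module's main correctness anchor, exercised in the tests.
* **"Could not be further improved"** is operationalised with a patience
  counter because a literal reading (stop at the first non-improvement)
  is brittle under CV noise. With strongly separable data accuracy
  saturates immediately and the stop rule then triggers after `patience`
  tie removals, so signatures stay close to the candidate set; with
  noisier data the trace wanders and the best iteration sits deeper into
  the elimination.
* **Cross-validation folds** are stratified by class, dealt from the
  lightest fold first so overall fold sizes differ by at most one, and
  fixed per run by a single seed. With the default 59 + 82 cohort every
  fold holds 11–12 never and 16–17 current smokers.
* **Missing values** are kept when a gene is observed in at least one
  sample (genes missing everywhere are dropped) and mean-imputed per gene
  before modeling; validation cohorts are imputed with *training* gene
  means so no validation information leaks into the models.
* **Transforms.** GE uses $\log_2(x+1)$ — level-3 RNA-seq quantifications
  contain zeros, which a bare $\log_2$ cannot tolerate. CNV uses
  $\log_2(x/2)$ for classification (diploid $\mapsto 0$), while all
  mountain/peak summaries stay on raw copies where the diploid baseline
  is 2 and a normal male chrY is 1. ME stays on the beta scale; promoter
  aggregation averages probes inside the annotated promoter interval
  (1-based inclusive; when an annotation lacks explicit bounds, TSS−1500
  to TSS+500 is the intended convention).

## Genome-overview summaries

* **Volcano / deflection tables** use a two-sided Welch $t$-test per gene
  (the unequal-variance form is the safer default when the test behind a
  genome-wide scatter is unspecified) and a Bonferroni family-wise cutoff
  $\alpha/m$. For $m = 21342$ expression genes at $\alpha = 0.05$ this is
  $2.34\times10^{-6}$, i.e. $-\log_{10} = 5.63$; for $m = 23494$ CNV
  genes the exact chain gives 5.67 while the commonly printed rounded
  chain via $2.10\times10^{-6}$ gives 5.68 — both are computed and
  neither silently corrected.
* **Mountain profiles** report the per-gene median raw copy number per
  sample group, ordered along the genome, with subgroup partitions
  (smoking × gender) as first-class inputs because the interesting broad
  events — the chrY deficit of male never smokers, stronger MDM2-like
  amplification in female never smokers — are subgroup contrasts.
* **Focal peaks** are local maxima of the median profile within a
  sliding window (default 25 genes) rising at least `min_prominence`
  (default 0.5 copies) above the window baseline. All genes of the *peak
  plateau* — contiguous genes within `tie_tol` (default 0.1 copies) of
  the maximum — are reported: exact ties between noisy medians are
  measure-zero, so a plateau tolerance is what makes "the genes on the
  peak" well defined. Defaults are pragmatic knobs, not estimates.

## The synthetic cohort generator

`generate_cohort()` draws seeded two-class cohorts emulating the
structure of the TCGA LUAD training data so the whole pipeline is
testable against known truth without any external download:

* class sizes default to 59 never / 82 current smokers; 2000 genes across
  chr1–22, X, Y with acrocentric chromosomes (13, 14, 15, 21, 22)
  carrying q-arm genes only;
* log2 expression is class-conditionally Gaussian (unit residual SD);
  40 planted GE genes shift by $d = 2$ between classes;
* 40 planted ME genes couple to their own expression through a shared
  latent factor with sign-flipped loading on the logit scale, calibrated
  to a Pearson correlation of −0.877 between beta and log2 expression
  (the strength reported for GSTM1-like promoter hypermethylation that
  silences expression); background ME is independent logit-normal noise;
* CNV is piecewise constant along arms (per-sample arm offsets, SD 0.05;
  per-gene noise, SD 0.1) with a diploid autosomal baseline; 40 planted
  CNV genes sit in 7-gene focal amplicons gaining +1.5 copies in current
  smokers and drive their own expression at 1 log2 unit per copy (a
  dosage effect strong enough for the $|r|>0.5$ candidate rule to be
  attainable); chrY is single-copy in males, reduced by 0.4 copies in
  male never smokers, and a 0.05-copy sentinel in females (a small
  constant keeps $\log_2(\mathrm{CNV}/2)$ finite); chrX is generated
  diploid for both sexes to keep gender out of the classification signal;
* entries go missing completely at random at rate 0.02 (≤ 0.05 by
  validation), and sample covariates (age, gender, stage, vital status)
  are drawn independently of class.

The genome *structure* (gene map, planted sets, signs, baselines) is
seeded separately from the *samples*, so an independent validation cohort
drawn from the same generative process shares its biology with the
training cohort while sharing no sample-level noise:
`generate_cohort(cfg_val, structure_seed = cfg_train$seed)`.

What the generator deliberately does **not** emulate: platform chemistry
(27K vs 450K probes, SNP-array waviness), batch effects, correlated
gene-gene expression structure beyond the planted couplings, ancestry
structure, or clinical covariates that correlate with exposure. Passing
tests on these cohorts therefore demonstrates that the *procedure* is
implemented correctly and recovers planted structure at realistic sizes
and noise levels — not that it would attain any particular accuracy on
real tumor cohorts.

## Problem sizes used by the tests and the acceptance script

Unit tests run on a 30 + 40 sample, 600-gene cohort; the recovery,
null-control and pattern checks run at the study conditions (59 + 82,
2000 genes, 40 planted per layer). The recovery criterion takes the
median over 3 generator seeds; the null control uses 20 seeds with 200
label permutations; the acceptance script uses one pipeline run plus 5
null seeds with 300/200 permutations. These sizes are the package's
choices for a desk-scale, single-process analysis; all of them are plain
function arguments and scale up freely.

## Known limitations

* With the default strongly separable conditions, CV accuracy saturates
  at the first elimination iteration, so the backward elimination prunes
  only modestly (the stop rule is accuracy-driven, not sparsity-driven);
  signature compactness on real, noisier data depends on the accuracy
  trace actually peaking.
* Permutation $q$-values are conservative ($\pi_0 = 1$) and granular at
  small permutation counts; at least 100 permutations are required, 1000
  recommended.
* The elimination refits on the full training set each iteration
  (ranking is not per-fold), matching the single-model description of
  the procedure; CV accuracy is therefore an optimistic model-selection
  signal, which is why held-out validation metrics are reported
  separately.
* No segmentation is performed on CNV input: real segmented calls are
  accepted as-is, and the generator emits segment-structured data.
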