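Package: tobsig
Title: Tobacco-Exposure Signature Gene Identification from Multi-Omics
    Lung Adenocarcinoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies tobacco-exposure signature genes that distinguish
    current smokers from never smokers in lung adenocarcinoma cohorts using
    gene expression, promoter methylation and copy-number layers. Implements
    the integrated three-stage selection: SAM-style permutation FDR and
    expression-correlation candidate filtering, curated-gene merging, and
    iterative backward elimination driven by partial least squares (PLS)
    regression coefficients under stratified five-fold cross-validation,
    with a kernel PLS classifier for the final signature. Also provides
    genome-overview summaries (volcano tables with Bonferroni cutoffs,
    copy-number deflection and per-group median "mountain" profiles, focal
    amplicon peak calling) and a seeded synthetic multi-omics cohort
    generator with planted signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
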