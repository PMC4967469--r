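Package: pharmacoscape
Title: Pharmacogenomic Landscape Analysis for Cancer Cell Line Drug Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pharmacogenomic biomarker discovery in
    large cancer cell line drug screens. Maps tumor-derived catalogs of binary
    cancer functional events (driver-gene mutations, recurrent copy-number
    segments, hypermethylated promoter CpG islands) onto cell line cohorts,
    summarizes dose-response curves into log IC50 and AUC, scans drug-event
    pairs with covariate-adjusted ANOVA gated on Glass delta and Cohen's d
    effect sizes, infers AND/OR logic-formula biomarkers of drug sensitivity by
    exhaustive weighted optimization with cross-validated complexity selection
    and permutation significance, benchmarks combinations of molecular data
    types with penalized linear and random forest predictors under a
    mixture-derived predictiveness threshold, and quantifies tumor/cell-line
    molecular concordance and patient stratification landscapes. Ships a
    seeded synthetic-data generator with planted ground truth for validating
    every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    glmnet,
    ranger
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
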