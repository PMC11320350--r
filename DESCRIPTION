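Package: protclock
Title: Mortality-Trained Proteomic Aging Clocks with Competing-Risks
    Validation
Version: 0.99.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Construction and validation of proteomic aging clocks trained
    on all-cause mortality. Provides a synthetic cohort generator with
    known ground truth (age-trended protein expression, Gompertz
    mortality, competing-risk incident diseases, administrative
    censoring), preprocessing (missingness filtering, k-nearest-neighbour
    imputation, rank-based inverse normal transformation), LASSO-penalized
    Cox protein selection, Gompertz proportional-hazards fitting, the
    risk-matching transform from model risk to a proteomic age in years,
    and a validation suite: Cox and Fine-Gray association models with
    tiered covariate adjustment, Benjamini-Hochberg FDR, Harrell's
    concordance comparisons, and hypergeometric gene-set enrichment of
    clock-associated proteins.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    glmnet,
    survival,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    cmprsk,
    flexsurv,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Proteomics, Survival, Epidemiology, Regression
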