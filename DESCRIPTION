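Package: glioscreen
Title: Drug-Response Imputation and Causal Biomarker Discovery for Glioma Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico drug discovery pipeline for glioblastoma. Trains
    per-drug ridge-regression models on cancer cell-line screens to impute
    drug-sensitivity AUC from tumor transcriptomes, nominates candidate drugs
    by Wilcoxon rank-sum testing with Benjamini-Hochberg FDR control and
    Hodges-Lehmann effect-size ranking intersected across patient cohorts,
    and discovers candidate causal biomarkers of drug response with a
    Spearman pre-filter followed by constraint-based Bayesian-network
    learning (MMPC parent-child discovery with Fisher-z partial-correlation
    tests and PC-style collider orientation). Includes a synthetic-data
    generator with known causal ground truth so every stage is verifiable
    without external downloads, and trapezoidal dose-response AUC utilities
    for comparing imputed against measured response.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
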