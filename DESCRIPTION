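Package: trisign
Title: miRNA/mRNA Signatures Across Normal, Tumor and Nodal Metastasis
    Tissue in Triple-Negative Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated analysis pipeline for three-tissue-class
    (adjacent normal / primary tumor / nodal metastasis) nCounter-style
    miRNA and mRNA profiling studies of triple-negative breast cancer.
    Provides negative-control-based detection filtering and quantile or
    invariant-set normalization; per-feature linear models with contrast
    matrices, empirical-Bayes moderated t-statistics, Benjamini-Hochberg
    correction and Venn partitioning of the three pairwise comparisons;
    permutation-validated Cox proportional-hazards miRNA survival
    signatures with risk-score classification, Kaplan-Meier curves and
    log-rank tests; target-prediction-filtered miRNA-mRNA
    anti-correlation; Spearman-distance average-linkage clustering with
    correlation-threshold tree cutting; and a seeded synthetic-cohort
    generator that emulates the assumed data structure with known ground
    truth, so every stage is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    withr
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
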