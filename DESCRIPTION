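Package: mdmpanel
Title: Methylated DNA Marker Discovery and qMSP Panel Evaluation for
    Esophageal Cancer Early Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for plasma cell-free DNA methylation
    biomarkers in esophageal cancer. Screens hypermethylated candidate
    regions from region-level methylation matrices (tumor vs adjacent
    normal tissue, with a white-blood-cell background filter), applies a
    one-hot plasma transform thresholded at the 95th percentile of
    cancer-free controls, selects a marker panel by regularized logistic
    regression, interprets quantitative methylation-specific PCR (qMSP)
    readouts with ACTB reference-gene quality gating and parallel (OR-rule)
    panel combination, and computes the full set of diagnostic-performance
    statistics (sensitivity, specificity, PPV, NPV, Youden index, Cohen's
    kappa, binomial confidence intervals, empirical ROC/AUC, stratified
    tables, paired pre/post tests). Includes a synthetic cohort simulator
    and fixture tables reconstructed from printed clinical counts so the
    whole pipeline is testable without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
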