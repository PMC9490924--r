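Package: tmescan
Title: Spatial Tumor-Microenvironment Features from Patch-Level Tissue Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the spatial composition of the tumor
    microenvironment (TME) from patch-level tissue classification maps of
    H&E-stained lung-cancer slides, and for relating those features to
    patient outcomes. Provides slide tiling with a Rec. 601 luma relevance
    filter and Reinhard color normalization, argmax labeling of per-patch
    class probabilities with entropy-based uncertainty summaries,
    slide-level spatial features (tissue prevalence, tumor-neighborhood
    composition, intra-tumor lymphocyte ratio, Shannon and Simpson
    diversity), cutpoint-based survival stratification via maximally
    selected rank statistics with Kaplan-Meier/log-rank testing and
    Benjamini-Hochberg control, cross-validated Cox proportional hazards
    modeling with Harrell's c-index, and oversampling-balanced
    cross-validated mutation-status classification. A seeded synthetic-data
    generator produces label grids, probability tables, patch images and
    clinical/survival/mutation cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    png,
    randomForest,
    stats,
    survival,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
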