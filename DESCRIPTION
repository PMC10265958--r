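Package: woundage
Title: Wound-Age Estimation from Skeletal-Muscle Metabolomics with
    Tandem Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the time elapsed since a skeletal-muscle
    contusion from untargeted metabolomics peak tables.  Implements the
    SIMCA-style chemometrics core (NIPALS PLS, multiclass OPLS-DA with VIP
    scores, stratified Q2 cross-validation, permutation testing, CV-ANOVA),
    differential-metabolite screening (VIP > 1 with FDR-adjusted P < 0.05),
    supervised two-dimensional reduction (PLS-DR), and a two-level tandem
    classifier that first assigns a coarse post-injury phase and then a
    group-specific wound-age window (seven windows between 4 and 48 hours).
    A synthetic-data generator reproduces the study design (control plus 12
    contusion time points, n = 9, pooled QC injections, external test
    samples) for desk-scale validation, and a curated 43-metabolite panel
    with molecular-formula mass arithmetic is included.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    grDevices,
    nnet,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
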