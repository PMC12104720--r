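Package: collateralq
Title: Quantitative Cerebral Collateral Scoring from CTA Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of cerebral collateral circulation in
    acute ischemic stroke from CT angiography. Provides a seeded synthetic
    cerebrovascular phantom generator with controlled hemisphere volume
    ratios, intensity windowing and midline-symmetry alignment, a nested
    residual-U segmentation network with deep supervision (trainable on one
    CPU at a scaled preset), case-level stratified cross-validation with
    grid search and early stopping, the quantitative collateral score
    (affected-to-healthy hemisphere vessel-volume percentage) with
    binary/quaternary/six-class grading and a threshold refinement sweep,
    and an agreement-statistics suite (Dice, confusion-matrix metrics, MCC,
    rank-based AUC, Spearman correlation, ICC(2,1)).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
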