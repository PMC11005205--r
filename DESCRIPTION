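Package: gwrct
Title: Automated Gray-White Matter Ratio from Non-Contrast Head CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated measurement of the gray-white matter ratio (GWR) on
    non-contrast head CT volumes for early neuroprognostication after
    cardiac arrest. Implements atlas-based ROI segmentation via deformable
    registration to an ROI-bearing template, K-means tissue clustering with
    morphological refinement of the atlas masks, inverse mapping of refined
    ROIs to native space, basal-ganglia and simplified GWR computation,
    automated quality-control exclusion, and the prognostic evaluation
    statistics (ROC/AUC with DeLong comparisons, Youden cutoffs, diagnostic
    metrics, covariate screening and multiple logistic regression). A
    synthetic head-phantom and cohort generator provides ground truth for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
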