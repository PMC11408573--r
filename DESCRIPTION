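Package: fairCAM
Title: Patient-Wise Splitting, Leakage Auditing and CAM Interpretability
    for CT Nodule Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing patient-identity data leakage in slice-based
    medical-image classification. Generates a fully synthetic phantom CT
    cohort with ground-truth nodule masks and a controllable per-patient
    identity signature, builds image-wise ("unfair") and patient-wise
    ("fair") splits with per-epoch Monte Carlo cross-validation, trains a
    small convolutional two-class classifier on CPU, computes gradient-based
    class activation heat maps, and scores interpretability via nodule
    locality statistics and heatmap-mask shape correlations. A paired
    experiment driver contrasts the two splitting regimes on identical
    cohorts and renders accuracy and interpretability reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'utils.R'
    'annotation.R'
    'classifier.R'
    'heatmap.R'
    'scoring.R'
    'splitting.R'
    'phantom.R'
    'experiment.R'
    'fairCAM-package.R'
    'study.R'
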