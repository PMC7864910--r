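Package: cbfocal
Title: Class-Balanced Positive/Negative Weighting and Weighted Focal Loss
    for Imbalanced Multilabel Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating multilabel image classifiers
    under severe class imbalance, as found in chest-radiograph finding
    labels where the rarest class appears in roughly 0.2% of images.
    Implements effective-number class weights with a positive/negative
    split, prevalence (inverse-frequency) weights, weighted binary
    cross-entropy and weighted focal losses over sigmoid outputs,
    prevalence-aware precision-recall evaluation with the random-classifier
    AU-PRC baseline, a two-stage progressive-image-resizing training
    harness with a reference convolutional backbone, and a synthetic
    imbalanced multilabel image generator so every component is testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
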