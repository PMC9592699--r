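Package: afmtl
Title: Adaptive Feature-Matching Dual-Source Heterogeneous Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Heterogeneous transfer learning for small-sample medical image
    classification. Implements diverse-branch-block convolutional target
    networks with exact post-training reparameterization into single kernels,
    selective feature-map matching from two frozen source networks via
    learned channel and layer-pair weights, a four-stage alternating training
    strategy, per-patient deep-feature extraction with Mann-Whitney
    screening, and a bagging ensemble of sparse Bayesian extreme learning
    machines with automatic relevance determination. Includes synthetic image
    and cohort generators so the full pipeline runs at desk scale on a CPU,
    CT/whole-slide preprocessing utilities (ROI crop, slice stacking, tiling,
    blank-tile filtering), and binary-classification evaluation metrics with
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
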