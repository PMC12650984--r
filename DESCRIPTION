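Package: hyperbrix
Title: Dual-Branch Attention Networks for Soluble Solids Content from
    Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts soluble solids content (SSC, degrees Brix) of fruit
    from hyperspectral reflectance cubes with a dual-branch convolutional
    network that combines channel attention on a spectral branch and
    spatial attention on a spatial branch, with cross-layer propagation of
    attention weights. Provides reflectance calibration against white and
    black references, band-ratio region-of-interest masking, rotation and
    mirroring augmentation, pixel-centred patch-pair extraction, Bayesian
    hyperparameter optimisation with a Gaussian-process surrogate and the
    probability-of-improvement acquisition, chemometric evaluation
    (R-squared, RMSE, RPD), and a synthetic hyperspectral scene generator
    so that the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    withr,
    rlang,
    ggplot2,
    generics,
    lhs,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
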