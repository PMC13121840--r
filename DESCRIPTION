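Package: lsjml
Title: Latent Space Item Response Models by Regularized Joint Maximum
    Likelihood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits latent space item response models (LSIRMs), in which
    persons and items are embedded in a low-dimensional Euclidean space and
    the person-item distance lowers the response probability, by two fast
    regularized joint maximum likelihood estimators: an L2-penalized variant
    (pJML) and a norm-constrained variant with gradient projection (cJML).
    Includes echelon-rotation identification of the latent space, sequential
    (continuation-ratio) models for ordinal items via cumulative binary dummy
    expansion, cell-wise K-fold cross-validation for selecting the latent
    dimension, nonparametric bootstrap standard errors with confidence
    ellipses, and a synthetic-data generator with parameter-recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
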