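Package: traitRBF
Title: Radial Basis Function Network Imputation of Morphological Traits
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Imputes missing continuous morphological trait values in
    specimen-level tables with a three-stage hybrid framework: a radial
    basis function regression network whose centers are initialized by
    K-means clustering of the training inputs, Gaussian-process Bayesian
    optimization of the number of basis functions and the kernel width
    by expected improvement, and an exhaustive correlation-guided search
    over small predictor combinations. Includes the seven standard
    regression evaluation metrics, mean-substitution / complete-case
    ablation harnesses, k-nearest-neighbor and random-forest baseline
    comparisons, and a synthetic generator of allometrically covarying
    avian-style trait tables with controlled MCAR/MAR missingness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    MASS,
    lhs,
    FNN,
    randomForest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
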