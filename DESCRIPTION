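Package: twinade
Title: Multivariate ADE Twin Models with Rater Effects by Full-Information
    Maximum Likelihood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits univariate and multivariate ADE (additive genetic,
    dominance, unshared environment) Cholesky models to raw twin-pair data
    by casewise full-information maximum likelihood, with a latent
    teacher-rater factor whose cross-twin correlation is one for pairs
    rated by the same teacher and zero otherwise, sex main effects, and
    robust (sandwich) standard errors.  Includes Box-Cox preprocessing
    with profile-likelihood estimation of the transformation exponent,
    subscale scoring with a missing-item rule, a synthetic twin-pair
    generator that reproduces the assumed covariance structure, the
    derivation chain from fitted parameters to broad-sense heritabilities,
    genetic and environmental correlation matrices, covariance
    proportions, and model-implied phenotypic correlations, and
    independent-pathway (biometric two-factor) models on raw data or on a
    genetic correlation matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    MASS,
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
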