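Package: mdcfa
Title: Fixed-Links Factor Analysis of Binary Data with Planned Missingness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structural investigation of binary item-response data from
    planned missing data designs without imputation. Missing responses are
    modeled, not replaced: probability-based covariances of the 0/1
    indicators are rescaled to the latent-normal metric and analyzed with
    fixed-links confirmatory factor analysis models in which an extra
    latent variable, with loadings fixed to the expected per-item missing
    frequencies, absorbs the systematic variation that the missingness
    layout induces. Provides a one-factor reference model, the missing-data
    two-factor model, and the semi-hierarchical model with square-root
    subsample weights; maximum-likelihood estimation with analytic
    gradients; chi-square, RMSEA, SRMR, TLI, CFI and AIC fit statistics;
    loading adjustment and standardization; a seeded synthetic-data
    generator; and a Monte Carlo study driver with tidy summaries and
    ggplot2 graphics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
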