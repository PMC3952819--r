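Package: geopoisson
Title: Bivariate Multilevel Poisson Models for County-Level Disease Incidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for modelling the joint geographic incidence of two
    related phenotypes (such as autism spectrum disorders and intellectual
    disability) recorded as gender-stratified case counts per county nested
    within states. Implements a bivariate-response, three-level mixed-effects
    Poisson regression with correlated state- and county-level random
    effects, estimated by Metropolis-within-Gibbs Markov chain Monte Carlo
    with conjugate inverse-Wishart covariance updates, and cross-checked by
    Laplace / adaptive Gauss-Hermite marginal maximum likelihood. Includes a
    synthetic-data generator that emulates the state-county hierarchy,
    county covariates, state special-education policy codes and patient-level
    comorbidity tables; empirical-Bayes random-effect prediction for disease
    mapping; and descriptive utilities (per-capita county rates, decile
    profiles of predictors, cross-phenotype correlations, and exact-test
    comorbidity odds ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
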