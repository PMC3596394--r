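Package: genmh
Title: Generalized Mantel-Haenszel Odds Ratios via Multinomial Logistic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Covariate-adjusted odds ratios between two dichotomous variables
    that are symmetrical in both variables. The classical Mantel-Haenszel
    estimator is extended to continuous and vector-valued covariates by
    replacing observed stratum cell counts with subject-specific
    classification probabilities from a four-category multinomial logistic
    model for the joint distribution of the two binary variables. Includes
    constrained maximum-likelihood estimation under the homogeneity
    hypothesis, Wald and likelihood-ratio homogeneity tests, delta-method
    and bootstrap standard errors, comparison with the two binary logistic
    regressions, and a simulator for parameter-recovery and coverage studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
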