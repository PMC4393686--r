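Package: twinace
Title: Twin-Pair Simulation and ACE Variance-Component Modelling by
    Full-Information Maximum Likelihood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classical twin design: simulation of monozygotic and
    dizygotic twin cohorts with known additive-genetic (A), common-environment
    (C) and unique-environment (E) structure; preprocessing of bounded, skewed
    questionnaire scales (scale scoring, square-root transformation, sex/age
    residualization); descriptive twin statistics (intraclass and cross-twin
    cross-trait correlations, Cronbach's alpha, sex-by-zygosity ANOVA); and a
    from-scratch full-information maximum-likelihood engine for univariate and
    bivariate ACE variance-component models, including saturated reference
    models, likelihood-ratio tests, Mx-style BIC, profile-likelihood confidence
    intervals, Falconer closed-form estimators, and derived bivariate
    quantities (bivariate heritability, genetic and environmental
    correlations). A pipeline orchestrates the full analysis from a cohort
    table to a study report, including covariate-adjusted refits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
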