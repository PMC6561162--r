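Package: pathtrial
Title: Causal Path Modelling of Randomized-Trial Outcomes
Version: 0.1.0
Authors@R: person("pathtrial", "maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to compare competing causal (path) models of treatment
    effects in longitudinal randomized trials, built around the two-arm
    simvastatin trial design in secondary progressive multiple sclerosis.
    Provides a synthetic trial-cohort generator driven by a user-specified
    structural model, annualized-change preprocessing with mixed-effects
    variable screening, full-information maximum-likelihood estimation of
    recursive path models with robust (sandwich) standard errors and
    CFI/SRMR/RMSEA fit indices, Akaike and Schwarz weight model comparison
    with nonparametric bootstrap, conjugate Gibbs samplers for
    three-variable Bayesian mediation (direct, indirect and
    proportion-mediated effects), and per-region longitudinal atrophy-rate
    screening with false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
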