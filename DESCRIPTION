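Package: panelmsm
Title: Three-State Health Transition Models for Interval-Censored Panel Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time multistate Markov modelling of self-perceived
    health trajectories in ageing cohorts. Implements an illness-death model
    with recovery (good health, poor health, death) for panel data in which
    live states are observed only at interview dates while death times are
    exact, with proportional covariate effects (education, birth cohort,
    country group) on every transition intensity. Provides maximum-likelihood
    estimation with Wald inference and hazard-ratio tables, prediction of
    covariate-specific transition probabilities with simulation-based
    confidence intervals, descriptive tables of sample composition and
    poor-health prevalence by wave, and a synthetic generator of SHARE-like
    panel data (irregular wave schedules, attrition, exact death dates) so
    the whole pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    deSolve,
    ggplot2,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
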