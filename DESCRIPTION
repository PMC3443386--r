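Package: jmsre
Title: Shared Random Effects Joint Models for Longitudinal Markers and
    Event Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits shared random effects joint models linking a
    continuous longitudinal marker (such as aneurysm diameter measured
    by ultrasound) to the hazard of a clinical event (such as rupture),
    with a constant or piecewise-constant baseline hazard and a
    closed-form cumulative hazard.  Provides the two common approximate
    alternatives for comparison: a naive exponential survival model with
    the observed measurements as a last-observation-carried-forward
    time-dependent covariate, and a two-stage model that plugs fitted
    values from a linear mixed model into the survival likelihood on a
    refinable time grid.  Includes a fully parameterised simulator of
    joint datasets with random and threshold censoring, a replicated
    simulation-study harness reporting bias and coverage of each
    estimator, a Bayesian implementation via Metropolis-within-Gibbs
    sampling, and posterior-predictive prediction of future marker
    values and conditional event risk for a new subject.
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
    lme4,
    mvtnorm,
    purrr,
    rlang,
    stats,
    statmod,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
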