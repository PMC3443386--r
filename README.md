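# jmsre

Shared random effects joint models for a longitudinal marker and a
time-to-event outcome, motivated by abdominal aortic aneurysm (AAA)
screening: sparse, error-prone ultrasound diameter measurements per
subject, a rare rupture event, and informative end of follow-up (referral
to surgery once an observed diameter reaches 55 mm).

## The model

Measurements follow a linear mixed model with random intercept and slope,

    y_ij = beta11 + beta12 t_ij + U_1i + U_2i t_ij + e_ij,
    U_i ~ N2(0, Sigma),  e_ij ~ N(0, sigma^2),

and the hazard of the event is multiplicative in the same random effects,

    h_i(t) = lambda * exp{ alpha1 U_1i + alpha2 U_2i + alpha3 (m_i(t) - c) },

where `m_i(t)` is the error-free current marker value and `c` a fixed
centering constant (47.15 mm by default).  With linear trajectories the
cumulative hazard is available in closed form,
`H_i(t) = lambda e^a (e^{bt} - 1)/b`, which makes both maximum-likelihood
fitting (adaptive Gauss-Hermite quadrature over the random effects) and
MCMC practical.

The package provides, each behind a data-frame-in / tibble-out interface:

* `simulate_joint()`, `make_scenario()` — the fully parameterised
  simulator of the published study scenarios (linear and quadratic
  truths, uniform random censoring, 55 mm threshold censoring);
* `episodes_locf()`, `fit_exponential_td()` — the naive time-dependent
  covariate model (last observation carried forward);
* `fit_lmm()`, `episodes_fitted()` — the two-stage plug-in model (BLUP
  fitted values on a refinable grid);
* `fit_joint()`, `marginal_loglik()` — the shared random effects joint
  model by maximum likelihood;
* `run_mcmc()`, `predict_longitudinal()`, `predict_survival()` — the
  Bayesian implementation and posterior-predictive prediction for a new
  subject;
* `run_study()` — replicated bias/coverage studies comparing the
  estimators;
* `read_joint_dataset()`, `write_joint_dataset()`, `cli_main()` and the
  thin `inst/cli/jmsre` script — CSV I/O and a command line
  (`simulate` / `fit` / `study` / `predict`).

Fitted objects have `tidy()`/`glance()` methods; datasets, study results
and predictions have `autoplot()` methods.

## A worked example

```r
library(jmsre)

dat <- simulate_joint(make_scenario("table1", n_subjects = 1000), seed = 11)
dat
#> <joint_data> 1000 subjects, 2896 measurements, 101 events

tidy(fit_exponential_td(
  episodes_locf(dat$longitudinal, dat$survival, center = 47.15)))
#> # A tibble: 2 x 5
#>   term       estimate std.error conf.low conf.high
#> 1 log_lambda   -4.30     0.157    -4.61     -3.99
#> 2 alpha         0.199    0.0121    0.176     0.223

fit <- fit_joint(dat)
fit
#> <joint_fit> logLik -9242.43 (converged), 101 events / 4768 person-years
#>   log lambda -4.840 (SE 0.203), alpha3 0.2130 (SE 0.0145)
```

The dataset was generated with true `log lambda = log(0.008) = -4.83` and
`alpha3 = 0.2`.  The naive time-dependent model overestimates the baseline
hazard (-4.30) and attenuates the association; the joint model recovers
both (-4.84, 0.213 with SE 0.015).  Replicated over many datasets with
`run_study()`, these single-dataset impressions become the familiar
bias/coverage comparison between the three estimators.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the replication targets from scratch by running the installed
package: it simulates 1000 replicates of each published scenario and
records mean event counts and follow-up, then refits the three estimators
over replicated datasets (the naive model and two-stage model at the
published 1000 subjects per replicate; the joint model over 100 replicates
at a reduced subject count to fit the time budget) and records the mean
estimates and the joint model's interval coverage.  Results are written as
a flat JSON object, one number per target.

The methods vignette (`vignettes/joint-modelling.Rmd`) documents the model,
the numerical choices, the simulator's stated world — including a
documented discrepancy between that world's mean event counts and the
published summaries in three scenarios — and the package's limitations.
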