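test_that("trajectory evaluates the linear and quadratic mean models", {
  p <- ref_params()
  expect_equal(trajectory(p, subject_effects(0, 0), 0), 38.5)
  expect_equal(trajectory(p, subject_effects(0, 0), 10), 55.8)
  # random effects shift intercept and slope
  expect_equal(trajectory(p, subject_effects(2, -0.5), 4), 38.5 + 2 + 1.23 * 4)
  # quadratic fixed effects (gross-misspecification truth)
  pq <- joint_params(38.5, 0.8, beta13 = 0.3, sigma = 2.8,
                     Sigma = diag(c(43.5, 1.7, 0.08)),
                     log_lambda = log(0.008))
  expect_equal(trajectory(pq, subject_effects(0, 0, 0), 8), 64.1)
  expect_error(trajectory(p, subject_effects(0, 0), -1), "nonnegative")
  expect_error(subject_effects(Inf, 0), "finite")
})

test_that("hazard is the centred proportional-hazards form", {
  p0 <- ref_params(alpha3 = 0)
  expect_equal(hazard(p0, subject_effects(0, 0), 3), exp(-4.82831),
               tolerance = 1e-4)
  p <- ref_params()
  expect_equal(p$center, 47.15)
  # population-mean trajectory crosses the centring value at t = 5
  expect_equal(hazard(p, subject_effects(0, 0), 5), 0.008)
  # a 5 mm increase in m - c multiplies the hazard by exp(0.2 * 5) = e
  h1 <- hazard(p, subject_effects(0, 0), 5)
  h2 <- hazard(p, subject_effects(5, 0), 5)
  expect_equal(h2 / h1, exp(1))
})

test_that("closed-form cumulative hazard matches trivial cases", {
  p0 <- ref_params(alpha3 = 0)
  expect_equal(cumulative_hazard(p0, subject_effects(0, 0), 10), 0.08)
  expect_equal(cumulative_hazard(p0, subject_effects(0, 0), 0), 0)
  # b = 0 limit: slope random effect cancels the population slope
  p <- ref_params()
  e0 <- subject_effects(1.5, -1.73)
  a <- 0.2 * (38.5 + 1.5 - 47.15)
  expect_equal(cumulative_hazard(p, e0, 7), 0.008 * exp(a) * 7)
})

test_that("closed-form cumulative hazard agrees with the quadrature oracle", {
  set.seed(17)
  for (i in 1:100) {
    p <- joint_params(beta11 = runif(1, 30, 45), beta12 = runif(1, 0.5, 2.5),
                      sigma = 2.8, Sigma = matrix(c(43.5, 3.2, 3.2, 1.7), 2),
                      log_lambda = runif(1, -6, -4),
                      alpha1 = runif(1, -0.1, 0.1),
                      alpha2 = runif(1, -0.3, 0.3),
                      alpha3 = runif(1, -0.3, 0.3))
    e <- subject_effects(rnorm(1, 0, 6), rnorm(1, 0, 1.2))
    t <- runif(1, 0.1, 10)
    H <- cumulative_hazard(p, e, t)
    expect_equal(H, oracle_H(p, e, t), tolerance = 1e-8)
  }
})

test_that("series and ratio branches agree at the switch tolerance", {
  # exercise the integral kernel directly at b just below / above the
  # switch, where both branches are valid
  for (s in c(-1, 1)) {
    lo <- jmsre:::exp_segment(s * 0.9999999e-8, 0, 8)   # series branch
    hi <- jmsre:::exp_segment(s * 1.0000001e-8, 0, 8)   # ratio branch
    expect_equal(lo, hi, tolerance = 1e-10)
  }
})

test_that("hazard is invariant under the centring reparameterisation", {
  p <- ref_params()
  delta <- 3.7
  p2 <- joint_params(38.5, 1.73, sigma = 2.8,
                     Sigma = matrix(c(43.5, 3.2, 3.2, 1.7), 2),
                     log_lambda = log(0.008) + 0.2 * delta,
                     alpha3 = 0.2, center = 47.15 + delta)
  e <- subject_effects(2, 0.4)
  tt <- c(0.5, 3, 9)
  expect_equal(hazard(p, e, tt), hazard(p2, e, tt))
  expect_equal(cumulative_hazard(p, e, tt), cumulative_hazard(p2, e, tt))
})

test_that("H is nonnegative, nondecreasing and zero at the origin", {
  set.seed(4)
  p <- ref_params()
  for (i in 1:20) {
    e <- subject_effects(rnorm(1, 0, 6), rnorm(1, 0, 1.3))
    tt <- sort(runif(8, 0, 10))
    H <- cumulative_hazard(p, e[rep(1, 8), ], tt)
    expect_true(all(H >= 0))
    expect_true(all(diff(H) >= 0))
  }
  expect_equal(cumulative_hazard(p, subject_effects(3, 1), 0), 0)
})

test_that("piecewise cumulative hazard generalises the single band", {
  p <- ref_params()
  e <- subject_effects(2, 0.5)
  tt <- c(1, 4.5, 9)
  # degenerate partition: one band reproduces cumulative_hazard
  expect_equal(
    piecewise_cumulative_hazard(p, numeric(0), log(0.008), e, tt),
    cumulative_hazard(p, e, tt))
  # equal rates across two bands: partition invariance
  expect_equal(
    piecewise_cumulative_hazard(p, 5, c(log(0.008), log(0.008)), e, tt),
    cumulative_hazard(p, e, tt))
  # arbitrary bands against the quadrature oracle
  cuts <- c(2, 6)
  ll <- log(c(0.004, 0.012, 0.02))
  for (t in tt) {
    expect_equal(
      piecewise_cumulative_hazard(p, cuts, ll, e, t),
      oracle_H(p, e, t, piecewise = list(cutpoints = cuts, log_lambdas = ll)),
      tolerance = 1e-8)
  }
  # t beyond the last cutpoint uses the final band's rate
  expect_gt(piecewise_cumulative_hazard(p, c(1), log(c(0.008, 0.05)), e, 10),
            piecewise_cumulative_hazard(p, c(1), log(c(0.008, 0.008)), e, 10))
  expect_error(piecewise_cumulative_hazard(p, c(3, 2), log(c(1, 2, 3)), e, 5),
               "increasing")
  expect_error(piecewise_cumulative_hazard(p, 2, log(0.008), e, 5),
               "per band")
})

test_that("survival log-likelihood contribution is delta log h - H", {
  p0 <- ref_params(alpha3 = 0)
  e <- subject_effects(0, 0)
  expect_equal(
    survival_loglik_contribution(p0, e, list(observed_time = 10, event = 0)),
    -0.08)
  expect_equal(
    survival_loglik_contribution(p0, e, list(observed_time = 10, event = 1)),
    log(0.008) - 0.08)
  # general case against independently computed pieces
  p <- ref_params()
  e <- subject_effects(4, 0.8)
  ll <- survival_loglik_contribution(p, e, list(observed_time = 6, event = 1))
  expect_equal(ll, log(hazard(p, e, 6)) - oracle_H(p, e, 6),
               tolerance = 1e-8)
  expect_error(
    survival_loglik_contribution(p, e, list(observed_time = -1, event = 1)),
    "invalid")
})

test_that("longitudinal log-likelihood contribution sums Normal densities", {
  p <- joint_params(38.5, 1.73, sigma = 1,
                    Sigma = matrix(c(43.5, 3.2, 3.2, 1.7), 2),
                    log_lambda = log(0.008))
  e <- subject_effects(0, 0)
  on_line <- data.frame(time = 2, y = 38.5 + 1.73 * 2)
  expect_equal(longitudinal_loglik_contribution(p, e, on_line),
               -0.5 * log(2 * pi))
  two <- data.frame(time = c(0, 2), y = c(38.5 + 1, 38.5 + 1.73 * 2 - 1))
  expect_equal(longitudinal_loglik_contribution(p, e, two),
               -log(2 * pi) - 1)
  # arbitrary case against dnorm directly
  set.seed(11)
  p2 <- ref_params()
  e2 <- subject_effects(3, -0.4)
  df <- data.frame(time = c(0, 2, 4, 6), y = rnorm(4, 45, 8))
  expected <- sum(dnorm(df$y,
                        (38.5 + 3) + (1.73 - 0.4) * df$time, 2.8,
                        log = TRUE))
  expect_equal(longitudinal_loglik_contribution(p2, e2, df), expected)
  expect_error(longitudinal_loglik_contribution(p2, e2, df[0, ]),
               "at least one")
})

test_that("parameter validation rejects degenerate inputs", {
  expect_error(joint_params(38.5, 1.73, sigma = -1,
                            Sigma = diag(2), log_lambda = -4.8), "sigma")
  expect_error(joint_params(38.5, 1.73, sigma = 2.8,
                            Sigma = matrix(0, 2, 2), log_lambda = -4.8),
               "positive definite")
  expect_error(joint_params(38.5, 1.73, sigma = 2.8,
                            Sigma = matrix(c(1, 0.5, 0.2, 1), 2),
                            log_lambda = -4.8), "symmetric")
  expect_error(joint_params(NA, 1.73, sigma = 2.8, Sigma = diag(2),
                            log_lambda = -4.8), "finite")
  # quadratic fixed effect requires a 3x3 covariance
  expect_error(joint_params(38.5, 1.73, beta13 = 0.1, sigma = 2.8,
                            Sigma = diag(2), log_lambda = -4.8), "3x3")
})
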