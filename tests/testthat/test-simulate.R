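test_that("random effects are drawn from the stated covariance", {
  spec <- make_scenario("table1", n_subjects = 1e5)
  set.seed(31)
  U <- draw_subject_effects(spec)
  # sample moments within 3 Monte-Carlo SEs of the truth
  mc_se_var <- function(v, n) sqrt(2 / (n - 1)) * v
  expect_lt(abs(var(U$u1) - 43.5), 3 * mc_se_var(43.5, 1e5))
  expect_lt(abs(var(U$u2) - 1.7), 3 * mc_se_var(1.7, 1e5))
  rho <- 3.2 / sqrt(43.5 * 1.7)
  expect_lt(abs(cor(U$u1, U$u2) - rho), 3 * (1 - rho^2) / sqrt(1e5))
  expect_error(
    draw_subject_effects(joint_params(38.5, 1.73, sigma = 2.8,
                                      Sigma = matrix(0, 2, 2),
                                      log_lambda = -4.8), n = 5),
    "positive definite")
})

test_that("measurements are the trajectory plus residual noise", {
  spec <- make_scenario("table1", n_subjects = 2000)
  # sigma -> 0 limit: observations sit on the subject's line
  spec0 <- spec
  spec0$params$sigma <- 1e-12
  set.seed(32)
  e <- draw_subject_effects(spec0, n = 50)
  m <- simulate_measurements(spec0, e)
  truth <- trajectory(spec0$params, e[m$id, ], m$time)
  expect_equal(m$y, truth, tolerance = 1e-6)
  # moments at t = 0 over many subjects
  set.seed(33)
  big <- make_scenario("table1", n_subjects = 1e5)
  eb <- draw_subject_effects(big)
  yb <- simulate_measurements(big, eb)
  y0 <- yb$y[yb$time == 0]
  v0 <- 43.5 + 2.8^2  # Sigma11 + sigma^2 = 51.34
  expect_lt(abs(mean(y0) - 38.5), 3 * sqrt(v0 / 1e5))
  expect_lt(abs(var(y0) - v0), 3 * sqrt(2 / (1e5 - 1)) * v0)
})

test_that("event times invert the cumulative hazard", {
  # alpha = 0: plain exponential with rate lambda
  p0 <- ref_params(alpha3 = 0)
  set.seed(34)
  e <- subject_effects(rnorm(1e5, 0, 6.6), rnorm(1e5, 0, 1.3))
  tt <- simulate_event_time(p0, e)
  expect_lt(abs(mean(tt) - 125), 3 * 125 / sqrt(1e5))
  # Kolmogorov-Smirnov agreement with exp(-H) for a fixed effects vector
  p <- ref_params()
  ef <- subject_effects(2, 0.5)[rep(1, 1e4), ]
  set.seed(35)
  ts <- simulate_event_time(p, ef)
  # independent numeric integration of the hazard on a dense grid
  grid <- seq(0, 60, by = 0.001)
  h <- hazard(p, subject_effects(2, 0.5)[rep(1, length(grid)), ], grid)
  Hg <- c(0, cumsum((h[-1] + h[-length(h)]) / 2 * diff(grid)))
  cdf <- stats::approxfun(grid, 1 - exp(-Hg), yright = 1)
  ks <- suppressWarnings(stats::ks.test(ts[is.finite(ts)], cdf))
  expect_gt(ks$p.value, 0.01)
  # b < 0 and a draw above the total hazard: the subject never fails
  pneg <- ref_params()
  eneg <- subject_effects(-15, -3)  # strongly shrinking trajectory
  set.seed(36)
  tneg <- simulate_event_time(pneg, eneg[rep(1, 2000), ])
  expect_true(any(is.infinite(tneg)))
})

test_that("censoring combines event, random, threshold and admin times", {
  spec <- make_scenario("table1", n_subjects = 2)
  meas <- tibble::tibble(id = rep(1:2, each = 5),
                         time = rep(c(0, 2, 4, 6, 8), 2),
                         y = c(40, 42, 44, 46, 48, 39, 41, 43, 45, 47))
  e <- subject_effects(c(0, 0), c(0, 0))
  # threshold off: event at T = 3 truncates measurements to t = 0, 2
  withr::with_seed(37, {
    d <- apply_censoring(spec, c(3, 20), meas, e)
  })
  expect_equal(d$survival$event[1], 1L)
  expect_equal(d$survival$time[1], 3)
  expect_equal(d$longitudinal$time[d$longitudinal$id == 1], c(0, 2))
  # threshold rule: first measurement >= 55 censors at that examination
  spec2 <- make_scenario("table2", n_subjects = 1)
  spec2$random_censoring_range <- 1e6  # keep random censoring out of the way
  meas2 <- tibble::tibble(id = 1, time = c(0, 2, 4, 6, 8),
                          y = c(40, 45, 56, 58, 60))
  withr::with_seed(38, {
    d2 <- apply_censoring(spec2, 7, meas2, subject_effects(0, 0))
  })
  expect_equal(d2$survival$time, 4)
  expect_equal(d2$survival$event, 0L)
  # the threshold-triggering measurement itself is retained
  expect_equal(max(d2$longitudinal$time), 4)
})

test_that("simulated datasets satisfy the joint invariants", {
  for (sc in c("table1", "table2", "table3_gross")) {
    d <- simulate_joint(make_scenario(sc, n_subjects = 400), seed = 39)
    obs <- d$survival$time[match(d$longitudinal$id, d$survival$id)]
    expect_true(all(d$longitudinal$time <= obs))
    expect_true(all(d$survival$time <= 10))
    expect_true(all(table(d$longitudinal$id) >= 1))
    ev <- d$survival$event == 1
    expect_true(all(d$survival$time[ev] < 10))
    if (sc != "table1") {
      # no retained measurement strictly before the observed time is >= 55
      strictly_before <- d$longitudinal$time <
        obs - 1e-9
      expect_true(all(d$longitudinal$y[strictly_before] < 55))
    }
  }
})

test_that("the same seed reproduces a dataset bit for bit", {
  spec <- make_scenario("table2", n_subjects = 150)
  d1 <- simulate_joint(spec, seed = 40)
  d2 <- simulate_joint(spec, seed = 40)
  expect_identical(d1$longitudinal, d2$longitudinal)
  expect_identical(d1$survival, d2$survival)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_joint(spec, seed = 41)
  expect_false(identical(d1$survival, d3$survival))
})

test_that("published scenarios carry the published parameterisation", {
  s1 <- make_scenario("table1")
  expect_equal(s1$params$alpha3, 0.2)
  expect_equal(s1$params$log_lambda, log(0.008))
  expect_true(is.na(s1$threshold))
  expect_equal(s1$exam_times, c(0, 2, 4, 6, 8))
  s2 <- make_scenario("table2")
  expect_equal(s2$params$alpha3, 0.22)
  expect_equal(s2$threshold, 55)
  expect_equal(s2$params$Sigma, s1$params$Sigma)
  s3 <- make_scenario("table3_gross")
  expect_equal(s3$params$beta12, 0.8)
  expect_equal(s3$params$beta13, 0.3)
  expect_equal(s3$params$Sigma,
               matrix(c(43.5, 3.2, -0.3, 3.2, 1.7, -0.2, -0.3, -0.2, 0.08),
                      3, 3))
  expect_equal(make_scenario("table3_mild")$params$beta13, 0.1)
  expect_error(make_scenario("table9"))
})

test_that("quadratic-truth event times match the closed form when the
          quadratic terms vanish", {
  # same world expressed with a 3x3 covariance whose quadratic variance is
  # negligible: event-time quantiles must agree with the linear closed form
  p3 <- joint_params(38.5, 1.73, beta13 = 1e-9, sigma = 2.8,
                     Sigma = diag(c(43.5, 1.7, 1e-12)),
                     log_lambda = log(0.008), alpha3 = 0.2,
                     center = 47.15)
  p2 <- joint_params(38.5, 1.73, sigma = 2.8, Sigma = diag(c(43.5, 1.7)),
                     log_lambda = log(0.008), alpha3 = 0.2, center = 47.15)
  e <- subject_effects(2, 0.3)
  set.seed(42)
  tq <- simulate_event_time(p3, subject_effects(2, 0.3, 0)[rep(1, 4e4), ])
  set.seed(42)
  tl <- simulate_event_time(p2, e[rep(1, 4e4), ])
  # same exponential draws, so paired times agree up to grid interpolation
  fin <- is.finite(tl) & tl < 10
  expect_lt(max(abs(tq[fin] - tl[fin])), 2e-3)
})
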