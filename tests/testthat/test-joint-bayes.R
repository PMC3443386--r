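test_that("a prior-only run recovers the prior", {
  empty <- list(longitudinal = tibble::tibble(id = integer(),
                                              time = numeric(),
                                              y = numeric()),
                survival = tibble::tibble(id = integer(), time = numeric(),
                                          event = integer()))
  post <- suppressWarnings(
    run_mcmc(empty, settings = mcmc_settings(chains = 1, warmup = 1000,
                                             iterations = 6000, seed = 3)))
  b11 <- post$draws$beta11
  # prior is N(0, 100^2); MCMC sd within a broad band around 100
  expect_gt(sd(b11), 55)
  expect_lt(sd(b11), 160)
  expect_lt(abs(mean(post$draws$sigma) - 50), 20)  # U(0, 100) prior
})

test_that("sampling is reproducible and the covariance draws stay PD", {
  d <- table1_data_small()
  s <- mcmc_settings(chains = 1, warmup = 300, iterations = 300, seed = 7)
  p1 <- suppressWarnings(run_mcmc(d, settings = s))
  p2 <- suppressWarnings(run_mcmc(d, settings = s))
  expect_identical(p1$draws, p2$draws)
  dets <- p1$draws$Sigma11 * p1$draws$Sigma22 - p1$draws$Sigma12^2
  expect_true(all(dets > 0))
  expect_true(all(p1$draws$Sigma11 > 0))
})

test_that("posterior agrees with the MLE on table1 data at n = 300", {
  post <- mcmc_n300()
  fit <- joint_fit_n300()
  td <- tidy(post)
  for (p in c("alpha3", "log_lambda", "beta12")) {
    pm <- td$mean[td$term == p]
    psd <- td$sd[td$term == p]
    mle <- if (p == "alpha3") fit$estimates$alpha3
           else if (p == "log_lambda") fit$estimates$log_lambda
           else fit$estimates$beta12
    expect_lt(abs(pm - mle), 3 * psd)
  }
  # diagnostics computed on every parameter
  expect_setequal(post$diagnostics$parameter,
                  c("beta11", "beta12", "log_lambda", "alpha3", "sigma",
                    "Sigma11", "Sigma12", "Sigma22"))
  expect_true(all(is.finite(post$diagnostics$ess)))
})

test_that("conditional survival predictions behave like probabilities", {
  draws <- fake_draws(alpha3 = 0.2)
  ns <- new_subject_data(tibble::tibble(time = c(0, 1, 2),
                                        y = c(44, 42, 40)),
                         survival_to = 2)
  set.seed(21)
  ps <- predict_survival(draws, ns, t = c(2, 3, 4, 6, 9))
  # t = s: probability exactly 1 with a zero-width interval
  expect_equal(ps$mean[1], 1)
  expect_equal(ps$lo95[1], 1)
  expect_equal(ps$hi95[1], 1)
  # nonincreasing in t, bounded in [0, 1]
  expect_true(all(diff(ps$mean) <= 0))
  expect_true(all(ps$mean >= 0 & ps$mean <= 1))
  expect_equal(ps$cum_inc, 1 - ps$mean)
  expect_error(predict_survival(draws, ns, t = 1), "precede")
})

test_that("with no association the prediction reduces to the exponential", {
  draws <- fake_draws(alpha3 = 0, log_lambda = log(0.02))
  ns <- new_subject_data(tibble::tibble(time = c(0, 1), y = c(40, 41)),
                         survival_to = 1.5)
  set.seed(22)
  ps <- predict_survival(draws, ns, t = c(3, 6), n_use = 400)
  lam <- exp(draws$draws$log_lambda)
  expect_equal(ps$mean, c(mean(exp(-lam * 1.5)), mean(exp(-lam * 4.5))),
               tolerance = 1e-3)
  # and survival information leaves the longitudinal prediction unchanged
  set.seed(23)
  pl_near <- predict_longitudinal(draws, ns, horizon_times = 4,
                                  n_use = 400, k_imp = 30)
  ns_far <- new_subject_data(tibble::tibble(time = c(0, 1), y = c(40, 41)),
                             survival_to = 3.9)
  set.seed(23)
  pl_far <- predict_longitudinal(draws, ns_far, horizon_times = 4,
                                 n_use = 400, k_imp = 30)
  expect_equal(pl_near$mean, pl_far$mean, tolerance = 0.25)
})

test_that("a well-measured subject is predicted near its own line", {
  draws <- fake_draws(alpha3 = 0.2, sigma = 0.5)
  tt <- seq(0, 2, by = 0.25)
  ns <- new_subject_data(tibble::tibble(time = tt, y = 38.5 + 1.73 * tt),
                         survival_to = 2)
  set.seed(24)
  pl <- predict_longitudinal(draws, ns, horizon_times = 5)
  expect_lt(abs(pl$mean - (38.5 + 1.73 * 5)), 1)
  expect_lt(pl$lo95, pl$mean)
  expect_gt(pl$hi95, pl$mean)
})

test_that("predictions are invariant to measurement ordering", {
  draws <- fake_draws(alpha3 = 0.2)
  m <- tibble::tibble(time = c(0, 1, 2), y = c(30, 35, 40))
  set.seed(25)
  a <- predict_survival(draws, new_subject_data(m, 2), t = 4)
  set.seed(25)
  b <- predict_survival(draws, new_subject_data(m[c(3, 1, 2), ], 2), t = 4)
  expect_equal(a$mean, b$mean)
})

test_that("survival prediction matches a nested Monte-Carlo oracle", {
  draws <- fake_draws(alpha3 = 0.2, seed = 2)
  m <- tibble::tibble(time = c(0, 1, 2), y = c(40, 43, 46))
  ns <- new_subject_data(m, survival_to = 2)
  set.seed(26)
  ps <- predict_survival(draws, ns, t = 5, n_use = 400, k_imp = 40)
  # oracle: for each theta draw, many U from the measurement posterior,
  # importance-weighted by exp(-H(s)); average exp(-(H(t)-H(s)))
  th <- draws$draws
  K <- 400
  est <- vapply(seq_len(nrow(th)), function(j) {
    S <- matrix(c(th$Sigma11[j], th$Sigma12[j], th$Sigma12[j],
                  th$Sigma22[j]), 2)
    Z <- cbind(1, m$time)
    P <- crossprod(Z) / th$sigma[j]^2 + solve(S)
    r <- crossprod(Z, m$y - th$beta11[j] - th$beta12[j] * m$time) /
      th$sigma[j]^2
    mu <- solve(P, r)
    U <- mvtnorm::rmvnorm(K, as.numeric(mu), solve(P))
    a <- 0.2 * (th$beta11[j] + U[, 1] - 47.15)
    b <- 0.2 * (th$beta12[j] + U[, 2])
    lam <- exp(th$log_lambda[j])
    Hs <- lam * exp(a) * (exp(b * 2) - 1) / b
    Ht <- lam * exp(a) * (exp(b * 5) - 1) / b
    w <- exp(-Hs)
    sum(w * exp(-(Ht - Hs))) / sum(w)
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est)) + 0.003
  expect_lt(abs(ps$mean - mean(est)), 2 * mc_se + 0.01)
})

test_that("an empty measurement history is allowed but flagged", {
  draws <- fake_draws(alpha3 = 0.2)
  ns <- new_subject_data(tibble::tibble(time = numeric(), y = numeric()),
                         survival_to = 2)
  set.seed(27)
  expect_warning(ps <- predict_survival(draws, ns, t = 4), "no measurements")
  expect_true(ps$mean > 0 && ps$mean < 1)
})

test_that("posterior draws survive a CSV round trip", {
  post <- mcmc_n300()
  path <- withr::local_tempfile(fileext = ".csv")
  posterior_draws_to_csv(post, path)
  post2 <- posterior_draws_from_csv(path)
  expect_equal(post2$center, post$center)
  expect_equal(post2$draws$alpha3, post$draws$alpha3, tolerance = 1e-12)
  ns <- new_subject_data(tibble::tibble(time = 0:2, y = c(30, 35, 40)), 2)
  set.seed(28)
  p1 <- predict_survival(post, ns, 4)
  set.seed(28)
  p2 <- predict_survival(post2, ns, 4)
  expect_equal(p1$mean, p2$mean, tolerance = 1e-9)
})
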