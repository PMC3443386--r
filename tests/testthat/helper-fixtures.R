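# Shared fixtures and independent oracles, built in code.

# reference linear-world truth used across tests
ref_params <- function(alpha3 = 0.2, alpha1 = 0, alpha2 = 0) {
  joint_params(beta11 = 38.5, beta12 = 1.73, sigma = 2.8,
               Sigma = matrix(c(43.5, 3.2, 3.2, 1.7), 2),
               log_lambda = log(0.008),
               alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3)
}

# quadrature oracle for the cumulative hazard: numerically integrate the
# hazard function itself (independent of the closed form under test)
oracle_H <- function(params, effects, t, piecewise = NULL) {
  h <- function(s) {
    base <- hazard(params, effects[rep(1, length(s)), ], s)
    if (is.null(piecewise)) return(base)
    band <- findInterval(s, piecewise$cutpoints) + 1L
    base * exp(piecewise$log_lambdas[band] - params$log_lambda)
  }
  stats::integrate(h, 0, t, rel.tol = 1e-11, abs.tol = 0)$value
}

# dense multivariate-normal marginal likelihood of the linear mixed model,
# computed subject by subject from first principles
oracle_lmm_loglik <- function(longitudinal, beta11, beta12, sigma, Sigma) {
  sum(vapply(split(longitudinal, longitudinal$id), function(df) {
    Z <- cbind(1, df$time)
    V <- Z %*% Sigma %*% t(Z) + sigma^2 * diag(nrow(df))
    mvtnorm::dmvnorm(df$y, Z %*% c(beta11, beta12), V, log = TRUE)
  }, numeric(1)))
}

# small cached fixtures shared across test files (test_dir runs files in
# one process, so this avoids repeating the expensive simulations)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

table1_data_small <- function() {
  cached("t1_small",
         simulate_joint(make_scenario("table1", n_subjects = 120),
                        seed = 421))
}

table1_data_n300 <- function() {
  cached("t1_n300",
         simulate_joint(make_scenario("table1", n_subjects = 300),
                        seed = 422))
}

joint_fit_n300 <- function() {
  cached("jfit_n300", fit_joint(table1_data_n300()))
}

mcmc_n300 <- function() {
  cached("mcmc_n300", suppressWarnings(
    run_mcmc(table1_data_n300(),
             settings = mcmc_settings(chains = 2, warmup = 1000,
                                      iterations = 2000, seed = 99))))
}

# hand-built posterior_draws object with known parameter values, for
# prediction tests that need controlled parameters
fake_draws <- function(n = 400, alpha3 = 0, log_lambda = log(0.008),
                       sigma = 2.8, seed = 1) {
  set.seed(seed)
  jitter <- function(x, s) x + stats::rnorm(n, 0, s)
  structure(
    list(draws = tibble::tibble(
      chain = 1L, iteration = seq_len(n),
      beta11 = jitter(38.5, 1e-3), beta12 = jitter(1.73, 1e-4),
      log_lambda = jitter(log_lambda, 1e-4), alpha3 = alpha3,
      sigma = jitter(sigma, 1e-4),
      Sigma11 = 43.5, Sigma12 = 3.2, Sigma22 = 1.7),
      u_draws = NULL, diagnostics = NULL, converged = TRUE,
      settings = NULL, priors = NULL, association = "current",
      center = 47.15, free_alphas = "alpha3"),
    class = "posterior_draws")
}
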