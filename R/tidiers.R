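#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a time-dependent exponential fit
#'
#' @param x A `"td_fit"` from [fit_exponential_td()].
#' @param conf.level Confidence level for the Wald intervals.
#' @param ... Ignored.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @method tidy td_fit
#' @export
tidy.td_fit <- function(x, conf.level = 0.95, ...) {
  z <- stats::qnorm((1 + conf.level) / 2)
  est <- c(log_lambda = x$log_lambda_hat, alpha = x$alpha_hat)
  se <- c(x$se_log_lambda, x$se_alpha)
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = se, conf.low = unname(est) - z * se,
                 conf.high = unname(est) + z * se)
}

#' @rdname tidy.td_fit
#' @method glance td_fit
#' @export
glance.td_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_events = x$n_events,
                 person_time = x$person_time, converged = x$converged)
}

#' Tidy a linear mixed model fit
#'
#' @param x An `"lmm_fit"` from [fit_lmm()].
#' @param ... Ignored.
#' @return A tibble with `term` and `estimate` for the fixed effects and
#'   variance components.
#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, ...) {
  e <- x$estimates
  tibble::tibble(
    term = c("beta11", "beta12", "sigma", "Sigma11", "Sigma12", "Sigma22"),
    estimate = c(e$beta11, e$beta12, e$sigma,
                 e$Sigma[1, 1], e$Sigma[1, 2], e$Sigma[2, 2]))
}

#' @rdname tidy.lmm_fit
#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 n_subjects = if (is.null(x$blups)) 0L else nrow(x$blups))
}

#' Tidy a maximum-likelihood joint model fit
#'
#' @param x A `"joint_fit"` from [fit_joint()].
#' @param conf.level Confidence level for Wald intervals (where a standard
#'   error is available).
#' @param ... Ignored.
#' @return A tibble with `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high`; variance components are reported on their natural scale
#'   without standard errors.
#' @method tidy joint_fit
#' @export
tidy.joint_fit <- function(x, conf.level = 0.95, ...) {
  z <- stats::qnorm((1 + conf.level) / 2)
  e <- x$estimates
  terms <- c("beta11", "beta12", "sigma", "Sigma11", "Sigma12", "Sigma22",
             "log_lambda", intersect(c("alpha1", "alpha2", "alpha3"),
                                     names(x$ses)))
  est <- c(e$beta11, e$beta12, e$sigma, e$Sigma[1, 1], e$Sigma[1, 2],
           e$Sigma[2, 2], e$log_lambda,
           unlist(e[intersect(c("alpha1", "alpha2", "alpha3"),
                              names(x$ses))]))
  se <- unname(x$ses[terms])  # variance components have no SE: NA
  tibble::tibble(term = terms, estimate = unname(est),
                 std.error = unname(se),
                 conf.low = unname(est - z * se),
                 conf.high = unname(est + z * se))
}

#' @rdname tidy.joint_fit
#' @method glance joint_fit
#' @export
glance.joint_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, converged = x$converged,
                 n_events = x$n_events, person_time = x$person_time,
                 quad_points = x$quad_points)
}

#' Tidy posterior draws
#'
#' @param x A `"posterior_draws"` from [run_mcmc()].
#' @param ... Ignored.
#' @return A tibble per parameter: posterior `mean`, `sd`, central 95%
#'   interval, and (when diagnostics were computed) `rhat` and `ess`.
#' @method tidy posterior_draws
#' @export
tidy.posterior_draws <- function(x, ...) {
  pars <- setdiff(names(x$draws), c("chain", "iteration"))
  out <- purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(term = p, mean = mean(v), sd = stats::sd(v),
                   lo95 = unname(stats::quantile(v, 0.025)),
                   hi95 = unname(stats::quantile(v, 0.975)))
  })
  if (!is.null(x$diagnostics)) {
    out <- dplyr::left_join(
      out, dplyr::rename(x$diagnostics, term = "parameter"), by = "term")
  }
  out
}

#' @rdname tidy.posterior_draws
#' @method glance posterior_draws
#' @export
glance.posterior_draws <- function(x, ...) {
  tibble::tibble(chains = x$settings$chains,
                 iterations = x$settings$iterations,
                 converged = x$converged)
}

#' Tidy a simulation-study result
#'
#' @param x A `"scenario_result"` from [run_study()].
#' @param ... Ignored.
#' @return The per-method, per-parameter summary tibble.
#' @method tidy scenario_result
#' @export
tidy.scenario_result <- function(x, ...) {
  x$summary
}

#' @rdname tidy.scenario_result
#' @method glance scenario_result
#' @export
glance.scenario_result <- function(x, ...) {
  tibble::tibble(scenario = x$config$scenario, n_reps = x$config$n_reps,
                 n_subjects = x$config$n_subjects,
                 mean_events = x$mean_events,
                 mean_person_years = x$mean_person_years)
}
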