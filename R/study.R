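#' Configure a replicated simulation study
#'
#' @param scenario Scenario name understood by [make_scenario()].
#' @param n_reps Number of replicate datasets.
#' @param n_subjects Subjects per replicate (default 1000, the published
#'   design).
#' @param methods Character subset of `c("td_locf", "twostage_2y",
#'   "twostage_6m", "twostage_1m", "joint_mle")`.
#' @param master_seed Integer master seed; replicate r is simulated under
#'   seed `master_seed + r`, a pure function of `(master_seed, r)`, so any
#'   single replicate can be reproduced in isolation and adding a method
#'   never perturbs the simulated data.
#' @param quad_points Quadrature points for the joint fits.
#' @param true_alpha Optional override of the scenario's true association.
#' @return A `"study_config"` list.
#' @export
study_config <- function(scenario = "table1", n_reps = 100,
                         n_subjects = 1000,
                         methods = c("td_locf", "joint_mle"),
                         master_seed = 1, quad_points = 9,
                         true_alpha = NULL) {
  methods <- match.arg(methods, c("td_locf", "twostage_2y", "twostage_6m",
                                  "twostage_1m", "joint_mle"),
                       several.ok = TRUE)
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  structure(list(scenario = scenario, n_reps = as.integer(n_reps),
                 n_subjects = as.integer(n_subjects), methods = methods,
                 master_seed = as.integer(master_seed),
                 quad_points = quad_points, true_alpha = true_alpha),
            class = "study_config")
}

fit_one_method <- function(method, data, lmm, center, quad_points) {
  grid <- c(twostage_2y = 2, twostage_6m = 0.5, twostage_1m = 1 / 12)
  if (method == "td_locf") {
    fit <- fit_exponential_td(
      episodes_locf(data$longitudinal, data$survival, center = center))
  } else if (method %in% names(grid)) {
    if (is.null(lmm) || !lmm$converged) return(NULL)
    fit <- fit_exponential_td(
      episodes_fitted(lmm, data$survival, grid_step = grid[[method]],
                      center = center))
  } else {  # joint_mle
    fit <- tryCatch(
      fit_joint(data, association = "current", quad_points = quad_points,
                center = center),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || !fit$hessian_pd) return(NULL)
    return(tibble::tibble(parameter = c("log_lambda", "alpha"),
                          estimate = c(fit$estimates$log_lambda,
                                       fit$estimates$alpha3),
                          se = c(fit$ses[["log_lambda"]],
                                 fit$ses[["alpha3"]])))
  }
  if (!fit$converged) return(NULL)
  tibble::tibble(parameter = c("log_lambda", "alpha"),
                 estimate = c(fit$log_lambda_hat, fit$alpha_hat),
                 se = c(fit$se_log_lambda, fit$se_alpha))
}

#' Run a replicated simulation study
#'
#' For each replicate, simulates a dataset under the scenario's true
#' parameters and fits every requested method, then aggregates the
#' estimates of the log baseline hazard and the current-value association
#' into the standard simulation-study summaries: mean estimate, mean
#' asymptotic SE, empirical SD of the estimates, and coverage of nominal
#' 95% Wald intervals around the truth.  Replicates on which a method
#' fails (no events, non-convergence, non-positive-definite Hessian) are
#' excluded from that method's aggregation and counted.
#'
#' @param config A [study_config()].
#' @param progress Print a dot every 10 replicates.
#' @return A `"scenario_result"` list with `summary` (per method and
#'   parameter), `details` (per replicate), `mean_events`,
#'   `mean_person_years` and the config.
#' @examples
#' \donttest{
#' res <- run_study(study_config("table1", n_reps = 5, n_subjects = 200,
#'                               methods = "td_locf", master_seed = 7))
#' res$summary
#' }
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  spec <- make_scenario(config$scenario, n_subjects = config$n_subjects,
                        true_alpha = config$true_alpha)
  center <- spec$params$center
  truth <- c(log_lambda = spec$params$log_lambda,
             alpha = spec$params$alpha3)
  needs_lmm <- any(grepl("^twostage", config$methods))
  details <- purrr::map(seq_len(config$n_reps), function(r) {
    if (progress && r %% 10 == 0) cat(".")
    data <- simulate_joint(spec, seed = config$master_seed + r)
    lmm <- if (needs_lmm) fit_lmm(data$longitudinal) else NULL
    rows <- purrr::map(config$methods, function(m) {
      out <- if (sum(data$survival$event) == 0) NULL
             else fit_one_method(m, data, lmm, center, config$quad_points)
      if (is.null(out)) {
        tibble::tibble(method = m, parameter = c("log_lambda", "alpha"),
                       estimate = NA_real_, se = NA_real_)
      } else {
        dplyr::mutate(out, method = m, .before = 1)
      }
    })
    dplyr::bind_rows(rows) |>
      dplyr::mutate(rep = r,
                    events = sum(data$survival$event),
                    person_years = sum(data$survival$time))
  }) |> dplyr::bind_rows()
  if (progress) cat("\n")
  z <- stats::qnorm(0.975)
  summary <- details |>
    dplyr::mutate(truth = truth[.data$parameter],
                  covered = abs(.data$estimate - .data$truth) <=
                    z * .data$se) |>
    dplyr::group_by(.data$method, .data$parameter) |>
    dplyr::summarise(
      mean = mean(.data$estimate, na.rm = TRUE),
      mean_se = mean(.data$se, na.rm = TRUE),
      empirical_sd = stats::sd(.data$estimate, na.rm = TRUE),
      coverage = 100 * mean(.data$covered, na.rm = TRUE),
      n_ok = sum(!is.na(.data$estimate)),
      n_failed = sum(is.na(.data$estimate)),
      .groups = "drop")
  per_rep <- dplyr::distinct(details, .data$rep, .data$events,
                             .data$person_years)
  structure(
    list(summary = summary, details = details,
         mean_events = mean(per_rep$events),
         mean_person_years = mean(per_rep$person_years),
         truth = truth, config = config),
    class = "scenario_result"
  )
}

#' Monte-Carlo half-width of an estimated 95% coverage
#'
#' The binomial precision of a coverage estimated from `n_reps`
#' replicates: \eqn{1.96\sqrt{0.95 \times 0.05 / n} \times 100} percentage
#' points (about 1.35 at 1000 replicates, 4.3 at 100).
#'
#' @param n_reps Number of replicates.
#' @return Half-width in percentage points.
#' @export
coverage_tolerance <- function(n_reps) {
  stopifnot(n_reps >= 1)
  1.96 * sqrt(0.95 * 0.05 / n_reps) * 100
}

#' Render a scenario result as a fixed-width text table
#'
#' One block per parameter, one row per method, in the layout
#' `method | mean | SE | coverage`.
#'
#' @param result A [run_study()] result.
#' @return A character vector of lines (invisibly printed with `cat`).
#' @export
format_table <- function(result) {
  stopifnot(inherits(result, "scenario_result"))
  lines <- sprintf("Scenario %s: %d replicates of %d subjects",
                   result$config$scenario, result$config$n_reps,
                   result$config$n_subjects)
  lines <- c(lines, sprintf("Mean events %.1f, mean follow-up %.0f person-years",
                            result$mean_events, result$mean_person_years))
  for (p in unique(result$summary$parameter)) {
    lines <- c(lines, "",
               sprintf("%s (truth %.3f)", p, result$truth[[p]]),
               sprintf("%-14s %10s %10s %12s", "method", "mean", "SE",
                       "coverage(%)"))
    sub <- dplyr::filter(result$summary, .data$parameter == p)
    lines <- c(lines, sprintf("%-14s %10.4f %10.4f %12.1f",
                              sub$method, sub$mean, sub$mean_se,
                              sub$coverage))
  }
  lines
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(format_table(x), sep = "\n")
  invisible(x)
}

#' @rdname autoplot.scenario_result
#' @export
plot_study <- function(result) {
  df <- dplyr::mutate(result$summary,
                      truth = result$truth[.data$parameter])
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$method)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$truth),
                        linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$mean - .data$empirical_sd,
                   xmax = .data$mean + .data$empirical_sd)) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::labs(x = "Mean estimate (+/- empirical SD); dashed = truth",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot estimator bias across methods
#'
#' Mean estimate with an empirical-SD bar per method, against the true
#' value, one panel per parameter.
#'
#' @param object,result A `"scenario_result"` from [run_study()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  plot_study(object)
}
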