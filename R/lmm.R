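#' Fit the linear mixed model stage of the two-stage approach
#'
#' Maximum-likelihood (not REML) fit of the random intercept and slope
#' model \eqn{y_{ij} = \beta_{11} + \beta_{12} t_{ij} + U_{1i} + U_{2i}
#' t_{ij} + \varepsilon_{ij}} with \eqn{U_i \sim N_2(0, \Sigma)} and
#' \eqn{\varepsilon_{ij} \sim N(0, \sigma^2)}, together with the best
#' linear unbiased predictors (BLUPs) of each subject's random effects,
#' \eqn{\hat U_i = \hat\Sigma Z_i' \hat V_i^{-1}(y_i - X_i\hat\beta)} with
#' \eqn{V_i = Z_i \hat\Sigma Z_i' + \hat\sigma^2 I}.  The fit is delegated
#' to [lme4::lmer()] with `REML = FALSE`; its conditional modes coincide
#' with the BLUPs for a linear mixed model.
#'
#' ML is used throughout because the joint model's likelihood is ML-based
#' and the estimator comparisons must compare like with like.
#'
#' @param longitudinal A data frame with columns `id`, `time`, `y`; at
#'   least two subjects, at least one with two or more measurements.
#' @return An `"lmm_fit"` list with elements `estimates` (named list
#'   `beta11`, `beta12`, `sigma`, `Sigma`), `blups` (tibble `id`, `u1`,
#'   `u2`), `loglik`, and `converged`.  Degenerate designs (for example
#'   every subject measured once) yield `converged = FALSE` rather than an
#'   error.
#' @examples
#' dat <- simulate_joint(make_scenario("table1", n_subjects = 100), seed = 2)
#' fit <- fit_lmm(dat$longitudinal)
#' fit$estimates$beta12  # close to the true slope 1.73
#' @export
fit_lmm <- function(longitudinal) {
  longitudinal <- as.data.frame(longitudinal)
  stopifnot(all(c("id", "time", "y") %in% names(longitudinal)))
  failed <- function() {
    structure(list(estimates = NULL, blups = NULL, loglik = NA_real_,
                   converged = FALSE), class = "lmm_fit")
  }
  if (length(unique(longitudinal$id)) < 2L) return(failed())
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ time + (time | id), data = longitudinal, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.nobs.vs.nRE = "ignore"))
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) return(failed())
  beta <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  Sigma <- matrix(as.numeric(vc$id), 2, 2)
  re <- lme4::ranef(fit)$id
  blups <- tibble::tibble(
    id = utils::type.convert(rownames(re), as.is = TRUE),
    u1 = re[["(Intercept)"]], u2 = re[["time"]]
  )
  conv <- is.null(fit@optinfo$conv$lme4$code)
  structure(
    list(estimates = list(beta11 = unname(beta[1]), beta12 = unname(beta[2]),
                          sigma = stats::sigma(fit), Sigma = Sigma),
         blups = blups,
         loglik = as.numeric(stats::logLik(fit)),
         converged = conv),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  if (!x$converged && is.null(x$estimates)) {
    cat("<lmm_fit> did not converge\n")
    return(invisible(x))
  }
  with(x$estimates, cat(sprintf(
    "<lmm_fit> intercept %.3f, slope %.3f, sigma %.3f, logLik %.2f\n",
    beta11, beta12, sigma, x$loglik)))
  invisible(x)
}

#' Fitted marker value for a subject
#'
#' Evaluates \eqn{\hat\beta_{11} + \hat\beta_{12} t + \hat U_{1i} +
#' \hat U_{2i} t}, the plug-in trajectory of the two-stage approach, at any
#' nonnegative time (continuous interpolation or extrapolation).
#'
#' @param fit An [fit_lmm()] result.
#' @param subject_id A single subject identifier present in the fit.
#' @param t Numeric vector of times (years).
#' @return Numeric vector of fitted marker values (mm).
#' @export
fitted_value <- function(fit, subject_id, t) {
  stopifnot(inherits(fit, "lmm_fit"), fit$converged)
  i <- match(subject_id, fit$blups$id)
  if (is.na(i)) stop("unknown subject: ", subject_id, call. = FALSE)
  fit$estimates$beta11 + fit$blups$u1[i] +
    (fit$estimates$beta12 + fit$blups$u2[i]) * t
}
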