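#' Joint model parameters
#'
#' Bundles every parameter of the shared random effects joint model: the
#' fixed effects of the marker trajectory, the residual and between-subject
#' variance components, the (log) constant baseline hazard, and the
#' association parameters linking the random effects and the current
#' underlying marker value to the hazard.
#'
#' The marker trajectory for a subject with random effects
#' \eqn{(U_1, U_2, U_3)} is
#' \deqn{m(t) = \beta_{11} + \beta_{12} t + \beta_{13} t^2
#'   + U_1 + U_2 t + U_3 t^2,}
#' and the event hazard is
#' \deqn{h(t) = \lambda \exp\{\alpha_1 U_1 + \alpha_2 U_2
#'   + \alpha_3 (m(t) - c)\},}
#' where \eqn{c} is a fixed centering constant, so that \eqn{\lambda} is the
#' hazard of a subject whose current marker value equals \eqn{c}.  By default
#' \eqn{c = \beta_{11} + 5\beta_{12}}, the population-mean marker value
#' halfway through a ten-year follow-up, which makes fitted log baseline
#' hazards comparable across models.  \eqn{c} is a stored constant, never an
#' estimated parameter.
#'
#' @param beta11 Population intercept of the marker (mm).
#' @param beta12 Population slope (mm/year).
#' @param beta13 Population quadratic coefficient (mm/year^2); zero for the
#'   linear model.
#' @param sigma Residual (measurement error) standard deviation (mm).
#' @param Sigma Between-subject covariance matrix of the random effects;
#'   2x2 for the linear model, 3x3 when a random quadratic term is present.
#'   Must be symmetric positive definite.
#' @param log_lambda Log constant baseline hazard (log events per year).
#' @param alpha1,alpha2 Association of the hazard with the random intercept
#'   and random slope (log hazard ratio per mm, per mm/year).
#' @param alpha3 Association with the current underlying marker value
#'   (log hazard ratio per mm).
#' @param center Centering constant \eqn{c} (mm) for the current-value
#'   covariate; defaults to `beta11 + 5 * beta12`.
#'
#' @return An object of class `"joint_params"`: a named list with the fields
#'   above plus `q`, the random-effect dimension.
#' @examples
#' p <- joint_params(beta11 = 38.5, beta12 = 1.73, sigma = 2.8,
#'                   Sigma = matrix(c(43.5, 3.2, 3.2, 1.7), 2),
#'                   log_lambda = log(0.008), alpha3 = 0.2)
#' p$center  # 47.15
#' @export
joint_params <- function(beta11, beta12, beta13 = 0, sigma, Sigma,
                         log_lambda, alpha1 = 0, alpha2 = 0, alpha3 = 0,
                         center = beta11 + 5 * beta12) {
  Sigma <- as.matrix(Sigma)
  vals <- c(beta11, beta12, beta13, sigma, Sigma, log_lambda,
            alpha1, alpha2, alpha3, center)
  if (!all(is.finite(vals))) {
    stop("all joint model parameters must be finite", call. = FALSE)
  }
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  q <- nrow(Sigma)
  if (!q %in% c(2L, 3L) || ncol(Sigma) != q) {
    stop("`Sigma` must be a 2x2 or 3x3 matrix", call. = FALSE)
  }
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma)))) {
    stop("`Sigma` must be symmetric", call. = FALSE)
  }
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("`Sigma` must be positive definite", call. = FALSE)
  }
  if (q == 2L && beta13 != 0) {
    stop("a quadratic fixed effect requires a 3x3 `Sigma`", call. = FALSE)
  }
  structure(
    list(beta11 = beta11, beta12 = beta12, beta13 = beta13,
         sigma = sigma, Sigma = Sigma, log_lambda = log_lambda,
         alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
         center = center, q = q),
    class = "joint_params"
  )
}

#' @export
print.joint_params <- function(x, ...) {
  cat("<joint_params> q =", x$q, "random effects\n")
  cat(sprintf("  trajectory : %.4g + %.4g t%s  (sigma = %.4g)\n",
              x$beta11, x$beta12,
              if (x$beta13 != 0) sprintf(" + %.4g t^2", x$beta13) else "",
              x$sigma))
  cat(sprintf("  hazard     : exp(%.4g) * exp(%.3g U1 + %.3g U2 + %.3g (m(t) - %.4g))\n",
              x$log_lambda, x$alpha1, x$alpha2, x$alpha3, x$center))
  cat("  Sigma      :", paste(signif(x$Sigma[upper.tri(x$Sigma, diag = TRUE)], 4),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Subject-level random effects
#'
#' A tibble of per-subject random-effect deviations: `u1` (intercept, mm),
#' `u2` (slope, mm/year) and optionally `u3` (quadratic, mm/year^2, zero when
#' absent).  Rows are subjects; most model functions are vectorised over the
#' rows of this tibble.
#'
#' @param u1,u2,u3 Numeric vectors (recycled to a common length).
#' @return A tibble with class `"subject_effects"` prepended.
#' @examples
#' subject_effects(u1 = c(0, 2), u2 = c(0, -0.5))
#' @export
subject_effects <- function(u1 = 0, u2 = 0, u3 = 0) {
  out <- tibble::tibble(u1 = u1, u2 = u2, u3 = u3)
  if (!all(is.finite(c(out$u1, out$u2, out$u3)))) {
    stop("random effects must be finite", call. = FALSE)
  }
  class(out) <- c("subject_effects", class(out))
  out
}

# Coerce anything effects-like (vector, list, data frame) to the canonical
# three-column tibble.
as_effects <- function(effects) {
  if (inherits(effects, "subject_effects")) return(effects)
  if (is.numeric(effects) && is.null(dim(effects))) {
    effects <- as.list(effects)
    names(effects) <- c("u1", "u2", "u3")[seq_along(effects)]
    return(do.call(subject_effects, effects))
  }
  effects <- as.data.frame(effects)
  if (!"u3" %in% names(effects)) effects$u3 <- 0
  subject_effects(u1 = effects$u1, u2 = effects$u2, u3 = effects$u3)
}
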