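#' Underlying marker trajectory
#'
#' Evaluates the error-free marker value
#' \eqn{m(t) = \beta_{11} + \beta_{12} t + \beta_{13} t^2 + U_1 + U_2 t +
#' U_3 t^2} for one or more subjects.  This is the "current underlying
#' value": the subject's true trajectory, as opposed to a noisy observed
#' measurement.
#'
#' @param params A [joint_params()] object.
#' @param effects Random effects: a [subject_effects()] tibble (or anything
#'   coercible, e.g. a numeric vector `c(u1, u2)`).
#' @param t Time in years since the subject's first examination.  `t` and
#'   the rows of `effects` are recycled to a common length.
#' @return Numeric vector of marker values (mm).
#' @examples
#' p <- joint_params(38.5, 1.73, sigma = 2.8,
#'                   Sigma = diag(c(43.5, 1.7)), log_lambda = log(0.008))
#' trajectory(p, subject_effects(0, 0), t = c(0, 10))
#' @export
trajectory <- function(params, effects, t) {
  stopifnot(inherits(params, "joint_params"))
  effects <- as_effects(effects)
  if (!all(is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and nonnegative", call. = FALSE)
  }
  n <- max(length(t), nrow(effects))
  t <- rep_len(t, n)
  u1 <- rep_len(effects$u1, n)
  u2 <- rep_len(effects$u2, n)
  u3 <- rep_len(effects$u3, n)
  (params$beta11 + u1) + (params$beta12 + u2) * t + (params$beta13 + u3) * t^2
}

#' Event hazard under the shared random effects model
#'
#' The hazard at time `t` for a subject with random effects `effects`:
#' \deqn{h(t) = \lambda \exp\{\alpha_1 U_1 + \alpha_2 U_2 +
#'   \alpha_3 (m(t) - c)\}.}
#'
#' @inheritParams trajectory
#' @return Numeric vector of hazard rates (per year), strictly positive.
#' @examples
#' p <- joint_params(38.5, 1.73, sigma = 2.8,
#'                   Sigma = diag(c(43.5, 1.7)),
#'                   log_lambda = log(0.008), alpha3 = 0.2)
#' hazard(p, subject_effects(0, 0), t = 5)  # = 0.008 at the centering value
#' @export
hazard <- function(params, effects, t) {
  stopifnot(inherits(params, "joint_params"))
  effects <- as_effects(effects)
  m <- trajectory(params, effects, t)
  n <- length(m)
  u1 <- rep_len(effects$u1, n)
  u2 <- rep_len(effects$u2, n)
  exp(params$log_lambda + params$alpha1 * u1 + params$alpha2 * u2 +
        params$alpha3 * (m - params$center))
}

# Per-subject log-linear hazard coefficients: h(t) = exp(log_lambda + a + b t)
# with a = alpha1 u1 + alpha2 u2 + alpha3 (beta11 + u1 - c) and
# b = alpha3 (beta12 + u2).  Only valid for linear trajectories.
hazard_ab <- function(params, effects) {
  effects <- as_effects(effects)
  if (params$beta13 != 0 || any(effects$u3 != 0)) {
    stop("closed-form cumulative hazard requires a linear trajectory ",
         "(beta13 = 0 and u3 = 0)", call. = FALSE)
  }
  list(
    a = params$alpha1 * effects$u1 + params$alpha2 * effects$u2 +
      params$alpha3 * (params$beta11 + effects$u1 - params$center),
    b = params$alpha3 * (params$beta12 + effects$u2)
  )
}

# Integral of exp(b s) over (s0, s1], with a second-order series continuation
# for |b| below `tol` to avoid catastrophic cancellation near b = 0.
exp_segment <- function(b, s0, s1, tol = 1e-8) {
  small <- abs(b) < tol
  out <- numeric(length(b))
  if (any(!small)) {
    bb <- b[!small]
    # expm1 keeps full precision when b(s1 - s0) is small
    out[!small] <- exp(bb * s0[!small]) *
      expm1(bb * (s1[!small] - s0[!small])) / bb
  }
  if (any(small)) {
    d <- s1[small] - s0[small]
    out[small] <- d * (1 + b[small] * (s0[small] + s1[small]) / 2)
  }
  out
}

#' Closed-form cumulative hazard
#'
#' For a linear trajectory the hazard is log-linear in time,
#' \eqn{h(t) = \lambda e^{a + b t}} with
#' \eqn{a = \alpha_1 U_1 + \alpha_2 U_2 + \alpha_3(\beta_{11} + U_1 - c)} and
#' \eqn{b = \alpha_3(\beta_{12} + U_2)}, so the integrated hazard has the
#' closed form \eqn{H(t) = \lambda e^{a} (e^{bt} - 1)/b}.  For
#' \eqn{|b| < 10^{-8}} a second-order series \eqn{\lambda e^a t (1 + bt/2)}
#' is used instead.
#'
#' @inheritParams trajectory
#' @param t Nonnegative time (years); vectorised with the rows of `effects`.
#' @return Numeric vector, nonnegative and nondecreasing in `t`, with
#'   \eqn{H(0) = 0}.
#' @examples
#' p <- joint_params(38.5, 1.73, sigma = 2.8,
#'                   Sigma = diag(c(43.5, 1.7)),
#'                   log_lambda = log(0.008), alpha3 = 0)
#' cumulative_hazard(p, subject_effects(0, 0), t = 10)  # lambda * t = 0.08
#' @export
cumulative_hazard <- function(params, effects, t) {
  stopifnot(inherits(params, "joint_params"))
  effects <- as_effects(effects)
  if (!all(is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and nonnegative", call. = FALSE)
  }
  ab <- hazard_ab(params, effects)
  n <- max(length(t), length(ab$a))
  t <- rep_len(t, n)
  a <- rep_len(ab$a, n)
  b <- rep_len(ab$b, n)
  if (!all(is.finite(c(a, b)))) {
    stop("non-finite hazard coefficients", call. = FALSE)
  }
  exp(params$log_lambda + a) * exp_segment(b, numeric(n), t)
}

#' Cumulative hazard with a piecewise-constant baseline
#'
#' Generalises [cumulative_hazard()] to a baseline hazard that is constant
#' within time bands.  `cutpoints` partition follow-up into
#' `length(cutpoints) + 1` bands `(0, c1], (c1, c2], ..., (ck, Inf)`, each
#' with its own log baseline hazard; within a band the integral retains the
#' closed form, and the total is the sum over bands.  With a single band
#' (no cutpoints) this reduces exactly to [cumulative_hazard()].
#'
#' @inheritParams cumulative_hazard
#' @param cutpoints Strictly increasing positive band boundaries (years);
#'   may be empty.
#' @param log_lambdas One log baseline hazard per band
#'   (`length(cutpoints) + 1` values); the final band is open-ended, so `t`
#'   beyond the last cutpoint uses the last band's rate.
#' @return Numeric vector of cumulative hazards.
#' @export
piecewise_cumulative_hazard <- function(params, cutpoints, log_lambdas,
                                        effects, t) {
  stopifnot(inherits(params, "joint_params"))
  cutpoints <- as.numeric(cutpoints)
  if (length(cutpoints) &&
      (any(cutpoints <= 0) || any(diff(cutpoints) <= 0))) {
    stop("`cutpoints` must be strictly increasing and positive",
         call. = FALSE)
  }
  if (length(log_lambdas) != length(cutpoints) + 1L) {
    stop("need one log baseline hazard per band ",
         "(length(cutpoints) + 1 values)", call. = FALSE)
  }
  effects <- as_effects(effects)
  ab <- hazard_ab(params, effects)
  n <- max(length(t), length(ab$a))
  t <- rep_len(t, n)
  a <- rep_len(ab$a, n)
  b <- rep_len(ab$b, n)
  lo <- c(0, cutpoints)
  hi <- c(cutpoints, Inf)
  H <- numeric(n)
  for (k in seq_along(log_lambdas)) {
    s1 <- pmin(t, hi[k])
    s0 <- pmin(t, lo[k])
    act <- s1 > s0
    if (any(act)) {
      H[act] <- H[act] + exp(log_lambdas[k] + a[act]) *
        exp_segment(b[act], s0[act], s1[act])
    }
  }
  H
}

#' Survival log-likelihood contribution of one subject
#'
#' The standard right-censored parametric contribution
#' \eqn{\delta \log h(\tilde T) - H(\tilde T)} for a subject with observed
#' time \eqn{\tilde T} and event indicator \eqn{\delta}, evaluated at the
#' closed-form hazard of the linear-trajectory model.
#'
#' @inheritParams cumulative_hazard
#' @param record A list or one-row data frame with `observed_time` and
#'   `event` (0/1); vectorised when given several rows with matching
#'   `effects` rows.
#' @return Numeric vector of log-likelihood contributions.
#' @export
survival_loglik_contribution <- function(params, effects, record) {
  record <- as.data.frame(record)
  stopifnot(all(c("observed_time", "event") %in% names(record)))
  if (any(record$observed_time <= 0) || !all(record$event %in% c(0, 1))) {
    stop("invalid survival record", call. = FALSE)
  }
  h <- hazard(params, effects, record$observed_time)
  H <- cumulative_hazard(params, effects, record$observed_time)
  record$event * log(h) - H
}

#' Longitudinal log-likelihood contribution of one subject
#'
#' Sum over a subject's measurements of the Normal log-density of the
#' observed value around the subject's trajectory, with residual SD
#' \eqn{\sigma}.
#'
#' @inheritParams trajectory
#' @param records A data frame of the subject's measurements with columns
#'   `time` and `y` (nonempty).
#' @return A single numeric log-likelihood value.
#' @export
longitudinal_loglik_contribution <- function(params, effects, records) {
  records <- as.data.frame(records)
  stopifnot(all(c("time", "y") %in% names(records)))
  if (nrow(records) == 0L) {
    stop("`records` must contain at least one measurement", call. = FALSE)
  }
  effects <- as_effects(effects)
  if (nrow(effects) != 1L) {
    stop("one subject at a time: `effects` must have a single row",
         call. = FALSE)
  }
  m <- trajectory(params, effects[rep(1L, nrow(records)), ], records$time)
  sum(stats::dnorm(records$y, mean = m, sd = params$sigma, log = TRUE))
}
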