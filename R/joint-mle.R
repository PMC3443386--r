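# ---- internal machinery for the marginal likelihood -------------------------
#
# The subject-level integrand factorises into a term exactly Gaussian in
# U = (U1, U2) (longitudinal likelihood, random-effect prior, and the
# event-indicator term, which is linear in U) and the survivor factor
# exp(-H(T; U)).  Per-subject sufficient statistics make every likelihood
# evaluation a set of O(1) vectorised operations across subjects.

# g(b, T) = (exp(bT) - 1)/b and its first two b-derivatives, with series
# continuations below |b| = 1e-8 (catastrophic cancellation guard).
g_funs <- function(b, T) {
  ebt <- exp(b * T)
  g <- expm1(b * T) / b
  gb <- (T * ebt - g) / b
  gbb <- (T^2 * ebt - 2 * gb) / b
  small <- abs(b) < 1e-8
  if (any(small)) {
    bs <- b[small]
    Ts <- if (length(T) == 1L) T else T[small]
    g[small] <- Ts * (1 + bs * Ts / 2 + (bs * Ts)^2 / 6)
    gb[small] <- Ts^2 * (1 / 2 + bs * Ts / 3 + (bs * Ts)^2 / 8)
    gbb[small] <- Ts^3 * (1 / 3 + bs * Ts / 4 + (bs * Ts)^2 / 10)
  }
  list(g = g, gb = gb, gbb = gbb)
}

# Per-subject sufficient statistics, ordered as in `survival`.
prep_joint <- function(data) {
  long <- tibble::as_tibble(data$longitudinal)
  surv <- tibble::as_tibble(data$survival)
  stopifnot(all(c("id", "time", "y") %in% names(long)),
            all(c("id", "time", "event") %in% names(surv)))
  if (!all(long$id %in% surv$id)) {
    stop("longitudinal subjects missing from the survival table",
         call. = FALSE)
  }
  f <- factor(long$id, levels = surv$id)
  agg <- function(v) {
    out <- numeric(nrow(surv))
    s <- rowsum(v, f)
    out[match(rownames(s), as.character(surv$id))] <- s
    out
  }
  list(
    id = surv$id,
    n = agg(rep(1, nrow(long))),
    St = agg(long$time), Stt = agg(long$time^2),
    Sy = agg(long$y), Syt = agg(long$y * long$time),
    Syy = agg(long$y^2),
    T = surv$time, delta = surv$event,
    m = nrow(surv)
  )
}

gh_nodes <- function(quad_points) {
  gq <- statmod::gauss.quad(quad_points, kind = "hermite")
  grid <- expand.grid(k1 = seq_len(quad_points), k2 = seq_len(quad_points))
  z1 <- gq$nodes[grid$k1]
  z2 <- gq$nodes[grid$k2]
  list(z1 = z1, z2 = z2,
       logw = log(gq$weights[grid$k1]) + log(gq$weights[grid$k2]) +
         z1^2 + z2^2)
}

logsumexp_rows <- function(M) {
  mx <- M[, 1]
  for (k in 2:ncol(M)) mx <- pmax.int(mx, M[, k])
  mx + log(rowSums(exp(M - mx)))
}

# Evaluate the marginal log-likelihood (and, optionally, the per-subject
# posterior modes) for natural-scale parameters.  `prep` from prep_joint(),
# `quad` from gh_nodes().
joint_ll_engine <- function(params, prep, quad, want_modes = FALSE) {
  b11 <- params$beta11; b12 <- params$beta12
  sig2 <- params$sigma^2
  Sinv <- solve(params$Sigma)
  logdetS <- determinant(params$Sigma, logarithm = TRUE)$modulus[1]
  a1 <- params$alpha1; a2 <- params$alpha2; a3 <- params$alpha3
  ll <- params$log_lambda; cc <- params$center

  n <- prep$n; St <- prep$St; Stt <- prep$Stt
  Se <- prep$Sy - b11 * n - b12 * St
  Set <- prep$Syt - b11 * St - b12 * Stt
  See <- prep$Syy - 2 * b11 * prep$Sy - 2 * b12 * prep$Syt +
    b11^2 * n + 2 * b11 * b12 * St + b12^2 * Stt
  T <- prep$T; delta <- prep$delta

  # Gaussian part: precision P, linear coefficient r (event term is linear)
  p11 <- n / sig2 + Sinv[1, 1]
  p12 <- St / sig2 + Sinv[1, 2]
  p22 <- Stt / sig2 + Sinv[2, 2]
  r1 <- Se / sig2 + delta * (a1 + a3)
  r2 <- Set / sig2 + delta * (a2 + a3 * T)

  # survivor factor H(U) = exp(la0 + k1 U1 + a2 U2) * g(b(U2), T)
  la0 <- ll + a3 * (b11 - cc)
  k1 <- a1 + a3

  H_parts <- function(u1, u2, need = 0L) {
    b <- a3 * (b12 + u2)
    gf <- g_funs(b, T)
    eh <- exp(la0 + k1 * u1 + a2 * u2)
    H <- eh * gf$g
    if (need == 0L) return(list(H = H))
    dH2 <- a2 * H + eh * a3 * gf$gb
    out <- list(H = H, d1 = k1 * H, d2 = dH2)
    if (need == 2L) {
      out$d11 <- k1^2 * H
      out$d12 <- k1 * dH2
      out$d22 <- a2 * dH2 + a3 * (a2 * eh * gf$gb + eh * a3 * gf$gbb)
    }
    out
  }
  fval <- function(u1, u2, H) {
    r1 * u1 + r2 * u2 -
      0.5 * (p11 * u1^2 + 2 * p12 * u1 * u2 + p22 * u2^2) - H
  }

  # Newton search for the per-subject posterior mode, started at the mode of
  # the Gaussian part (exact when alpha = 0); vectorised across subjects.
  detP <- p11 * p22 - p12^2
  u1 <- (p22 * r1 - p12 * r2) / detP
  u2 <- (p11 * r2 - p12 * r1) / detP
  f_old <- fval(u1, u2, H_parts(u1, u2)$H)
  for (it in 1:30) {
    hp <- H_parts(u1, u2, need = 2L)
    g1 <- r1 - (p11 * u1 + p12 * u2) - hp$d1
    g2 <- r2 - (p12 * u1 + p22 * u2) - hp$d2
    q11 <- p11 + hp$d11; q12 <- p12 + hp$d12; q22 <- p22 + hp$d22
    detQ <- q11 * q22 - q12^2
    bad <- !(is.finite(detQ) & detQ > 0 & q11 > 0)
    if (any(bad)) {  # fall back to the Gaussian curvature
      q11[bad] <- p11[bad]; q12[bad] <- p12[bad]; q22[bad] <- p22[bad]
      detQ[bad] <- detP[bad]
    }
    s1 <- (q22 * g1 - q12 * g2) / detQ
    s2 <- (q11 * g2 - q12 * g1) / detQ
    step_sz <- pmax(abs(s1), abs(s2))
    if (max(step_sz) < 1e-10) break
    scale <- rep(1, length(u1))
    for (h in 1:12) {
      cand1 <- u1 + scale * s1
      cand2 <- u2 + scale * s2
      f_new <- fval(cand1, cand2, H_parts(cand1, cand2)$H)
      worse <- !is.finite(f_new) | f_new < f_old - 1e-12
      if (!any(worse)) break
      scale[worse] <- scale[worse] / 2
    }
    u1 <- cand1; u2 <- cand2; f_old <- f_new
  }

  # curvature at the mode -> adaptive rescaling
  hp <- H_parts(u1, u2, need = 2L)
  q11 <- p11 + hp$d11; q12 <- p12 + hp$d12; q22 <- p22 + hp$d22
  bad <- !(is.finite(q11 * q22 - q12^2) & (q11 * q22 - q12^2) > 0 & q11 > 0)
  if (any(bad)) {
    q11[bad] <- p11[bad]; q12[bad] <- p12[bad]; q22[bad] <- p22[bad]
  }
  l11 <- sqrt(q11); l21 <- q12 / l11; l22 <- sqrt(q22 - l21^2)
  log_detA <- -(log(l11) + log(l22))

  const <- -n * log(params$sigma) - n / 2 * log(2 * pi) - See / (2 * sig2) +
    delta * (ll + a3 * (b11 + b12 * T - cc)) -
    log(2 * pi) - 0.5 * logdetS

  # all K nodes at once: n x K matrices, length-n vectors recycle down columns
  sq2 <- sqrt(2)
  X2 <- sq2 * outer(1 / l22, quad$z2)
  X1 <- sq2 * outer(1 / l11, quad$z1) - X2 * (l21 / l11)
  U1 <- u1 + X1
  U2 <- u2 + X2
  bM <- a3 * (b12 + U2)
  smallb <- abs(bM) < 1e-8
  gM <- expm1(bM * T) / bM
  if (any(smallb)) {
    gM[smallb] <- (T[row(gM)[smallb]]) *
      (1 + bM[smallb] * T[row(gM)[smallb]] / 2)
  }
  HM <- exp(la0 + k1 * U1 + a2 * U2) * gM
  M <- r1 * U1 + r2 * U2 -
    0.5 * (p11 * U1^2 + 2 * p12 * U1 * U2 + p22 * U2^2) - HM
  M <- sweep(M, 2, quad$logw, "+")
  ll_i <- const + log(2) + log_detA + logsumexp_rows(M)
  if (any(!is.finite(ll_i))) {
    stop("quadrature failure (non-finite integral) for subject(s): ",
         paste(utils::head(prep$id[!is.finite(ll_i)], 5), collapse = ", "),
         call. = FALSE)
  }
  if (want_modes) {
    list(loglik = sum(ll_i), modes = tibble::tibble(id = prep$id,
                                                    u1 = u1, u2 = u2))
  } else {
    sum(ll_i)
  }
}

#' Marginal log-likelihood of the shared random effects joint model
#'
#' Computes \eqn{\sum_i \log \int \exp\{\ell_i^{long}(U) +
#' \ell_i^{surv}(U)\}\, \phi(U; 0, \Sigma)\, dU}, the joint likelihood with
#' the bivariate random effects integrated out, by adaptive Gauss-Hermite
#' quadrature: the nodes are recentred at each subject's posterior mode and
#' rescaled by the curvature there, so a modest number of points per
#' dimension (default 9) suffices even for subjects with many measurements.
#'
#' @param params A [joint_params()] object (linear trajectory).
#' @param data A `"joint_data"` object, or any list with `longitudinal`
#'   (`id`, `time`, `y`) and `survival` (`id`, `time`, `event`) tables.
#' @param quad_points Number of quadrature points per dimension (>= 3).
#' @return The marginal log-likelihood (a single number).
#' @examples
#' dat <- simulate_joint(make_scenario("table1", n_subjects = 40), seed = 4)
#' marginal_loglik(make_scenario("table1")$params, dat)
#' @export
marginal_loglik <- function(params, data, quad_points = 9) {
  stopifnot(inherits(params, "joint_params"))
  if (quad_points < 3) stop("`quad_points` must be >= 3", call. = FALSE)
  if (params$beta13 != 0 || params$q != 2L) {
    stop("the marginal likelihood is implemented for the linear ",
         "(two random effect) model", call. = FALSE)
  }
  prep <- prep_joint(data)
  joint_ll_engine(params, prep, gh_nodes(quad_points))
}

# pack/unpack between the optimiser's unconstrained vector and natural
# parameters: log sigma and the log-diagonal Cholesky factor of Sigma keep
# the variance components positive definite.
pack_theta <- function(params, association) {
  L <- t(chol(params$Sigma))
  th <- c(params$beta11, params$beta12, log(params$sigma),
          log(L[1, 1]), L[2, 1], log(L[2, 2]), params$log_lambda)
  nm <- c("beta11", "beta12", "log_sigma", "lchol1", "chol21", "lchol2",
          "log_lambda")
  if ("intercept" %in% association) { th <- c(th, params$alpha1); nm <- c(nm, "alpha1") }
  if ("slope" %in% association) { th <- c(th, params$alpha2); nm <- c(nm, "alpha2") }
  if ("current" %in% association) { th <- c(th, params$alpha3); nm <- c(nm, "alpha3") }
  stats::setNames(th, nm)
}

unpack_theta <- function(th, association, center) {
  L <- matrix(c(exp(th[4]), th[5], 0, exp(th[6])), 2, 2, byrow = FALSE)
  al <- c(alpha1 = 0, alpha2 = 0, alpha3 = 0)
  k <- 7
  if ("intercept" %in% association) { k <- k + 1; al["alpha1"] <- th[k] }
  if ("slope" %in% association) { k <- k + 1; al["alpha2"] <- th[k] }
  if ("current" %in% association) { k <- k + 1; al["alpha3"] <- th[k] }
  list(beta11 = th[1], beta12 = th[2], sigma = exp(th[3]),
       Sigma = L %*% t(L), log_lambda = th[7],
       alpha1 = unname(al["alpha1"]), alpha2 = unname(al["alpha2"]),
       alpha3 = unname(al["alpha3"]), center = center, beta13 = 0, q = 2L)
}

# central-difference Hessian with relative step 1e-4 per parameter
fd_hessian <- function(fn, theta, rel_step = 1e-4) {
  p <- length(theta)
  h <- rel_step * pmax(abs(theta), 1)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(theta)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (fn(theta + ei) - 2 * f0 + fn(theta - ei)) / h[i]^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(p), j, h[j])
        H[i, j] <- H[j, i] <-
          (fn(theta + ei + ej) - fn(theta + ei - ej) -
             fn(theta - ei + ej) + fn(theta - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Fit the shared random effects joint model by maximum likelihood
#'
#' Maximises the marginal likelihood of [marginal_loglik()] over the fixed
#' effects, variance components (via log-sigma and the log-diagonal
#' Cholesky factor of Sigma, keeping them positive), the log baseline
#' hazard and the requested association parameters; excluded association
#' parameters are fixed at zero.  Standard errors come from the inverse of
#' a central finite-difference Hessian at the optimum.  Starting values are
#' the linear mixed model fit for the longitudinal parameters, events per
#' person-year for the baseline hazard, and zero for the associations.
#'
#' @param data A `"joint_data"` object or list with `longitudinal` and
#'   `survival` tables.
#' @param association Character subset of `c("intercept", "slope",
#'   "current")` choosing which of \eqn{\alpha_1, \alpha_2, \alpha_3} are
#'   free.
#' @param quad_points Gauss-Hermite points per dimension (default 9).
#' @param center Centering constant c (mm) for the current-value covariate
#'   (default 47.15, the reference parameterisation used throughout the
#'   package's simulation studies).
#' @param compute_se Compute the finite-difference Hessian and standard
#'   errors (default `TRUE`); skip for speed when only point estimates are
#'   needed.
#' @return A `"joint_fit"` list: `estimates` ([joint_params()]), `ses`
#'   (named numeric: `beta11`, `beta12`, `log_lambda`, free alphas),
#'   `vcov`, `loglik`, `converged`, `eb_effects` (per-subject
#'   empirical-Bayes modes), `quad_points`, `association`.
#' @examples
#' \donttest{
#' dat <- simulate_joint(make_scenario("table1", n_subjects = 300), seed = 5)
#' fit <- fit_joint(dat)
#' tidy(fit)
#' }
#' @export
fit_joint <- function(data, association = "current", quad_points = 9,
                      center = 47.15, compute_se = TRUE) {
  association <- match.arg(association,
                           c("intercept", "slope", "current"),
                           several.ok = TRUE)
  prep <- prep_joint(data)
  if (sum(prep$delta) == 0) {
    stop("cannot fit the joint model without any events", call. = FALSE)
  }
  quad <- gh_nodes(quad_points)

  lmm <- fit_lmm(data$longitudinal)
  if (!lmm$converged) {
    stop("linear mixed model starting fit failed", call. = FALSE)
  }
  Sig0 <- lmm$estimates$Sigma
  # keep the starting covariance safely positive definite
  ev <- eigen(Sig0, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-4)
  Sig0 <- ev$vectors %*% diag(ev$values) %*% t(ev$vectors)
  start <- list(beta11 = lmm$estimates$beta11, beta12 = lmm$estimates$beta12,
                sigma = lmm$estimates$sigma, Sigma = Sig0,
                log_lambda = log(sum(prep$delta) / sum(prep$T)),
                alpha1 = 0, alpha2 = 0, alpha3 = 0, center = center,
                beta13 = 0, q = 2L)
  th0 <- pack_theta(start, association)
  negll <- function(th) {
    p <- unpack_theta(th, association, center)
    out <- tryCatch(-joint_ll_engine(p, prep, quad), error = function(e) Inf)
    if (!is.finite(out)) 1e12 else out
  }
  opt <- stats::nlminb(th0, negll,
                       control = list(rel.tol = 1e-10, iter.max = 500,
                                      eval.max = 2000))
  th <- stats::setNames(opt$par, names(th0))
  est <- unpack_theta(th, association, center)
  params <- joint_params(beta11 = est$beta11, beta12 = est$beta12,
                         sigma = est$sigma, Sigma = est$Sigma,
                         log_lambda = est$log_lambda, alpha1 = est$alpha1,
                         alpha2 = est$alpha2, alpha3 = est$alpha3,
                         center = center)
  ses <- rep(NA_real_, length(th))
  V <- matrix(NA_real_, length(th), length(th))
  hess_pd <- NA
  if (compute_se) {
    H <- fd_hessian(negll, th)
    hess_pd <- all(is.finite(H)) &&
      all(eigen(H, symmetric = TRUE, only.values = TRUE)$values > 0)
    if (hess_pd) {
      V <- solve(H)
      ses <- sqrt(diag(V))
    }
  }
  names(ses) <- names(th)
  dimnames(V) <- list(names(th), names(th))
  final <- joint_ll_engine(est, prep, quad, want_modes = TRUE)
  structure(
    list(estimates = params, ses = ses, vcov = V,
         loglik = final$loglik,
         converged = opt$convergence == 0, hessian_pd = hess_pd,
         eb_effects = final$modes, quad_points = quad_points,
         association = association, n_events = sum(prep$delta),
         person_time = sum(prep$T), theta = th),
    class = "joint_fit"
  )
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf(
    "<joint_fit> logLik %.2f (%s), %d events / %.0f person-years\n",
    x$loglik, if (x$converged) "converged" else "NOT converged",
    x$n_events, x$person_time))
  cat(sprintf("  log lambda %.3f (SE %.3f)", x$estimates$log_lambda,
              x$ses["log_lambda"]))
  for (a in c("alpha1", "alpha2", "alpha3")) {
    if (a %in% names(x$ses)) {
      cat(sprintf(", %s %.4f (SE %.4f)", a, x$estimates[[a]], x$ses[a]))
    }
  }
  cat("\n")
  invisible(x)
}

#' Wald confidence interval for a joint-model parameter
#'
#' @param fit A [fit_joint()] result (or any object with `estimates` and
#'   `ses` in the same layout).
#' @param param Parameter name: one of `names(fit$ses)`, e.g. `"alpha3"` or
#'   `"log_lambda"`.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' f <- list(estimates = list(alpha3 = 0.202), ses = c(alpha3 = 0.015))
#' wald_interval(f, "alpha3")
#' @export
wald_interval <- function(fit, param, level = 0.95) {
  se <- unname(fit$ses[param])
  if (length(se) != 1 || is.na(se)) {
    stop("no standard error available for ", param, call. = FALSE)
  }
  est <- if (param %in% c("beta11", "beta12", "log_lambda", "alpha1",
                          "alpha2", "alpha3")) {
    fit$estimates[[param]]
  } else {
    fit$theta[[param]]
  }
  z <- stats::qnorm((1 + level) / 2)
  c(lower = est - z * se, upper = est + z * se)
}
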