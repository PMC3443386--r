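#' Prior specification for the Bayesian joint model
#'
#' Minimally informative priors: zero-mean normal with SD
#' `fixed_effect_sd` (default 100, i.e. variance 10^4) on every fixed
#' effect parameter (trajectory intercept and slope, log baseline hazard,
#' association parameters), Uniform(0, `sigma_upper`) on the residual SD,
#' and a scaled inverse-Wishart prior on the between-subject covariance:
#' \eqn{\Sigma = \mathrm{Diag}(\xi)\, Q\, \mathrm{Diag}(\xi)} with
#' \eqn{Q \sim \mathrm{invWishart}(q + 1, I)} and independent half-uniform
#' `U(0, scale_upper)` priors on the scale factors \eqn{\xi_j}
#' (Gelman-Hill construction).
#'
#' @param fixed_effect_sd Prior SD of the normal priors (default 100).
#' @param sigma_upper Upper bound of the uniform prior on sigma.
#' @param wishart_df Degrees of freedom of the inverse-Wishart (default
#'   `q + 1 = 3` for the bivariate random effects).
#' @param scale_upper Upper bound of the half-uniform priors on the
#'   scale factors.
#' @return A `"prior_spec"` list.
#' @export
prior_spec <- function(fixed_effect_sd = 100, sigma_upper = 100,
                       wishart_df = 3, scale_upper = 100) {
  stopifnot(fixed_effect_sd > 0, sigma_upper > 0, wishart_df > 0,
            scale_upper > 0)
  structure(list(fixed_effect_sd = fixed_effect_sd,
                 sigma_upper = sigma_upper, wishart_df = wishart_df,
                 scale_upper = scale_upper),
            class = "prior_spec")
}

#' MCMC settings
#'
#' @param chains Number of chains (default 3).
#' @param warmup Adaptation iterations discarded per chain (default 2000).
#' @param iterations Retained iterations per chain (default 5000).
#' @param seed Integer seed; chain c runs under `seed + c - 1`.
#' @param u_thin Thinning applied to the stored per-subject random-effect
#'   draws (parameter draws are never thinned).
#' @return An `"mcmc_settings"` list.
#' @export
mcmc_settings <- function(chains = 3, warmup = 2000, iterations = 5000,
                          seed = 1, u_thin = 10) {
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed), u_thin = as.integer(u_thin)),
            class = "mcmc_settings")
}

# per-subject survival log-likelihood, vectorised (linear trajectory)
surv_ll_vec <- function(b11, b12, loglam, a1, a2, a3, cc, u1, u2, T, delta) {
  eh <- exp(loglam + a3 * (b11 - cc) + (a1 + a3) * u1 + a2 * u2)
  H <- eh * g_funs(a3 * (b12 + u2), T)$g
  delta * (loglam + a1 * u1 + a2 * u2 +
             a3 * (b11 + b12 * T - cc + u1 + u2 * T)) - H
}

# per-subject residual sum of squares given random effects
rss_vec <- function(prep, b11, b12, u1, u2) {
  Se <- prep$Sy - b11 * prep$n - b12 * prep$St
  Set <- prep$Syt - b11 * prep$St - b12 * prep$Stt
  See <- prep$Syy - 2 * b11 * prep$Sy - 2 * b12 * prep$Syt +
    b11^2 * prep$n + 2 * b11 * b12 * prep$St + b12^2 * prep$Stt
  See - 2 * u1 * Se - 2 * u2 * Set + u1^2 * prep$n +
    2 * u1 * u2 * prep$St + u2^2 * prep$Stt
}

# zero-mean bivariate normal log-density terms for rows (u1, u2)
mvn2_ll <- function(u1, u2, Sigma) {
  det <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  i11 <- Sigma[2, 2] / det; i22 <- Sigma[1, 1] / det
  i12 <- -Sigma[1, 2] / det
  -log(2 * pi) - 0.5 * log(det) -
    0.5 * (i11 * u1^2 + 2 * i12 * u1 * u2 + i22 * u2^2)
}

split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_chains <- function(chains) {
  n <- min(lengths(chains))
  C <- length(chains)
  vars <- vapply(chains, stats::var, 0)
  W <- mean(vars)
  B <- if (C > 1) n * stats::var(vapply(chains, mean, 0)) else 0
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus <= 0) return(NA_real_)
  L <- min(n - 2, 200)
  acov <- sapply(chains, function(x) {
    stats::acf(x[seq_len(n)], lag.max = L, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  })
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_plus
  # Geyer initial positive sequence on paired sums
  s <- 0
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    s <- s + pair
    t <- t + 2
  }
  C * n / (1 + 2 * s)
}

#' Sample the Bayesian joint model posterior
#'
#' Metropolis-within-Gibbs sampling of the shared random effects joint
#' model with a constant baseline hazard and the closed-form cumulative
#' hazard in the survival likelihood.  Update blocks: the trajectory fixed
#' effects; the log baseline hazard together with the free association
#' parameters; every subject's random-effect pair (vectorised
#' random-walk proposals, one adaptive scale per subject); log sigma; the
#' decorrelated covariance matrix Q by its conjugate inverse-Wishart full
#' conditional; and the log scale factors xi.  Proposal scales adapt
#' during warmup toward 20-40% acceptance and are then frozen.
#'
#' @param data A `"joint_data"` object or list with `longitudinal` and
#'   `survival` tables.
#' @param priors A [prior_spec()].
#' @param settings An [mcmc_settings()].
#' @param association Character subset of
#'   `c("intercept", "slope", "current")`; excluded association parameters
#'   are fixed at zero.
#' @param center Centering constant c (mm) of the current-value covariate.
#' @return A `"posterior_draws"` list: `draws` (tibble, one row per
#'   retained draw with `chain`, `iteration` and one column per
#'   parameter), `u_draws` (thinned per-subject random-effect draws),
#'   `diagnostics` (split-chain Rhat and effective sample size per
#'   parameter, post-warmup only), `acceptance`, plus the settings, priors,
#'   association and center.  A warning is raised (and `$converged` set
#'   `FALSE`) if any Rhat exceeds 1.05.
#' @examples
#' \donttest{
#' dat <- simulate_joint(make_scenario("table1", n_subjects = 100), seed = 8)
#' post <- run_mcmc(dat, settings = mcmc_settings(chains = 2, warmup = 500,
#'                                                iterations = 500))
#' post$diagnostics
#' }
#' @export
run_mcmc <- function(data, priors = prior_spec(),
                     settings = mcmc_settings(),
                     association = "current", center = 47.15) {
  stopifnot(inherits(priors, "prior_spec"),
            inherits(settings, "mcmc_settings"))
  association <- if (length(association)) {
    match.arg(association, c("intercept", "slope", "current"),
              several.ok = TRUE)
  } else character()
  empty <- is.null(data) ||
    (is.list(data) && nrow(tibble::as_tibble(data$survival)) == 0)
  prep <- if (empty) {
    list(id = integer(), n = numeric(), St = numeric(), Stt = numeric(),
         Sy = numeric(), Syt = numeric(), Syy = numeric(),
         T = numeric(), delta = numeric(), m = 0L)
  } else {
    prep_joint(data)
  }
  m <- prep$m
  if (!empty && sum(prep$delta) == 0) {
    stop("cannot fit the joint model without any events", call. = FALSE)
  }
  free_a <- c("alpha1", "alpha2", "alpha3")[
    c("intercept", "slope", "current") %in% association]
  par_names <- c("beta11", "beta12", "log_lambda", free_a, "sigma",
                 "Sigma11", "Sigma12", "Sigma22")
  n_eta <- 1L + length(free_a)
  psd <- priors$fixed_effect_sd

  # starting state from the two-stage quantities (weakly data-dependent)
  if (!empty) {
    lmm <- fit_lmm(data$longitudinal)
  } else {
    lmm <- list(converged = FALSE)
  }
  if (lmm$converged) {
    st_b <- c(lmm$estimates$beta11, lmm$estimates$beta12)
    st_sig <- lmm$estimates$sigma
    S0 <- lmm$estimates$Sigma
    xi0 <- sqrt(pmax(diag(S0), 1e-2))
    Q0 <- diag(1 / xi0) %*% S0 %*% diag(1 / xi0)
    if (Q0[1, 1] * Q0[2, 2] - Q0[1, 2]^2 < 1e-4) Q0 <- diag(2)
    U0 <- as.matrix(lmm$blups[match(prep$id, lmm$blups$id), c("u1", "u2")])
    U0[is.na(U0)] <- 0
    st_ll <- log(max(sum(prep$delta), 1) / max(sum(prep$T), 1))
  } else {
    st_b <- c(0, 0); st_sig <- 1; xi0 <- c(1, 1); Q0 <- diag(2)
    U0 <- matrix(0, m, 2); st_ll <- 0
  }

  run_chain <- function(chain_id) {
    set.seed(settings$seed + chain_id - 1L)
    b <- st_b
    eta <- c(st_ll, rep(0, length(free_a)))
    lsig <- log(st_sig)
    xi <- xi0
    Q <- Q0
    U <- U0
    al <- function() {
      a <- c(alpha1 = 0, alpha2 = 0, alpha3 = 0)
      a[free_a] <- eta[-1]
      a
    }
    Sig <- function() diag(xi) %*% Q %*% diag(xi)
    total_surv <- function(b, eta_, U) {
      if (m == 0) return(0)
      a <- c(alpha1 = 0, alpha2 = 0, alpha3 = 0)
      a[free_a] <- eta_[-1]
      sum(surv_ll_vec(b[1], b[2], eta_[1], a[["alpha1"]], a[["alpha2"]],
                      a[["alpha3"]], center, U[, 1], U[, 2],
                      prep$T, prep$delta))
    }
    total_long <- function(b, lsig_, U) {
      if (m == 0) return(0)
      rss <- rss_vec(prep, b[1], b[2], U[, 1], U[, 2])
      -sum(prep$n) * lsig_ - sum(rss) / (2 * exp(2 * lsig_))
    }
    scales <- list(u = rep(1.5, m), beta = 0.2, eta = 0.3, sig = 0.1,
                   xi = 0.15, sw = c(0.8, 0.3))
    batch <- list(u = rep(0, m), beta = 0, eta = 0, sig = 0, xi = 0,
                  sw = c(0, 0))
    post <- c(u = 0, beta = 0, eta = 0, sig = 0, xi = 0)
    bump <- function(acc_take) {
      if (it > settings$warmup) {
        post[names(acc_take)] <<- post[names(acc_take)] + acc_take
      }
    }
    n_tot <- settings$warmup + settings$iterations
    keep <- matrix(NA_real_, settings$iterations, length(par_names),
                   dimnames = list(NULL, par_names))
    u_keep <- list()
    for (it in seq_len(n_tot)) {
      a <- al()
      Sg <- Sig()
      # --- subject random effects, vectorised MH
      if (m > 0) {
        cur <- -rss_vec(prep, b[1], b[2], U[, 1], U[, 2]) /
          (2 * exp(2 * lsig)) +
          surv_ll_vec(b[1], b[2], eta[1], a[["alpha1"]], a[["alpha2"]],
                      a[["alpha3"]], center, U[, 1], U[, 2],
                      prep$T, prep$delta) +
          mvn2_ll(U[, 1], U[, 2], Sg)
        prop1 <- U[, 1] + scales$u * stats::rnorm(m)
        prop2 <- U[, 2] + scales$u * stats::rnorm(m) * 0.35
        new <- -rss_vec(prep, b[1], b[2], prop1, prop2) /
          (2 * exp(2 * lsig)) +
          surv_ll_vec(b[1], b[2], eta[1], a[["alpha1"]], a[["alpha2"]],
                      a[["alpha3"]], center, prop1, prop2,
                      prep$T, prep$delta) +
          mvn2_ll(prop1, prop2, Sg)
        take <- log(stats::runif(m)) < new - cur
        U[take, 1] <- prop1[take]
        U[take, 2] <- prop2[take]
        batch$u <- batch$u + take
        bump(c(u = mean(take)))
      }
      # --- trajectory fixed effects
      cur <- total_long(b, lsig, U) + total_surv(b, eta, U) +
        sum(stats::dnorm(b, 0, psd, log = TRUE))
      prop <- b + scales$beta * stats::rnorm(2)
      new <- total_long(prop, lsig, U) + total_surv(prop, eta, U) +
        sum(stats::dnorm(prop, 0, psd, log = TRUE))
      if (log(stats::runif(1)) < new - cur) {
        b <- prop
        batch$beta <- batch$beta + 1
        bump(c(beta = 1))
      }
      # --- translation (sweep) moves: shift a fixed effect against the
      # matching random-effect column; the longitudinal likelihood is
      # exactly invariant, so only the random-effect prior, the fixed
      # effect prior and the survival term enter the ratio
      if (m > 0) {
        Sg2 <- Sig()
        for (w in 1:2) {
          dlt <- scales$sw[w] * stats::rnorm(1)
          b_new <- b
          b_new[w] <- b[w] + dlt
          U_new <- U
          U_new[, w] <- U[, w] - dlt
          cur <- sum(mvn2_ll(U[, 1], U[, 2], Sg2)) +
            stats::dnorm(b[w], 0, psd, log = TRUE) + total_surv(b, eta, U)
          new <- sum(mvn2_ll(U_new[, 1], U_new[, 2], Sg2)) +
            stats::dnorm(b_new[w], 0, psd, log = TRUE) +
            total_surv(b_new, eta, U_new)
          if (log(stats::runif(1)) < new - cur) {
            b <- b_new
            U <- U_new
            batch$sw[w] <- batch$sw[w] + 1
          }
        }
      }
      # --- log baseline hazard and associations
      cur <- total_surv(b, eta, U) + sum(stats::dnorm(eta, 0, psd, log = TRUE))
      prop <- eta + scales$eta * stats::rnorm(n_eta) *
        c(1, rep(0.1, length(free_a)))
      new <- total_surv(b, prop, U) + sum(stats::dnorm(prop, 0, psd, log = TRUE))
      if (log(stats::runif(1)) < new - cur) {
        eta <- prop
        batch$eta <- batch$eta + 1
        bump(c(eta = 1))
      }
      # --- residual SD (uniform prior, sampled on the log scale)
      cur <- total_long(b, lsig, U) + lsig
      prop <- lsig + scales$sig * stats::rnorm(1)
      if (exp(prop) < priors$sigma_upper) {
        new <- total_long(b, prop, U) + prop
        if (log(stats::runif(1)) < new - cur) {
          lsig <- prop
          batch$sig <- batch$sig + 1
          bump(c(sig = 1))
        }
      }
      # --- decorrelated covariance: conjugate inverse-Wishart
      Ut <- if (m > 0) sweep(U, 2, xi, "/") else matrix(0, 0, 2)
      Sn <- diag(2) + crossprod(Ut)
      W <- stats::rWishart(1, priors$wishart_df + m, solve(Sn))[, , 1]
      Q <- solve(W)
      Q <- (Q + t(Q)) / 2
      # --- scale factors
      cur <- sum(mvn2_ll(U[, 1], U[, 2], Sig())) + sum(log(xi))
      lprop <- log(xi) + scales$xi * stats::rnorm(2)
      if (all(exp(lprop) < priors$scale_upper)) {
        xi_new <- exp(lprop)
        Sg_new <- diag(xi_new) %*% Q %*% diag(xi_new)
        new <- sum(mvn2_ll(U[, 1], U[, 2], Sg_new)) + sum(lprop)
        if (log(stats::runif(1)) < new - cur) {
          xi <- xi_new
          batch$xi <- batch$xi + 1
          bump(c(xi = 1))
        }
      }
      # --- warmup adaptation every 50 iterations, frozen afterwards
      if (it <= settings$warmup && it %% 50 == 0) {
        tune <- function(s, rate) s * exp(rate - 0.3)
        scales$u <- pmin(pmax(tune(scales$u, batch$u / 50), 1e-3), 50)
        scales$beta <- tune(scales$beta, batch$beta / 50)
        scales$eta <- tune(scales$eta, batch$eta / 50)
        scales$sig <- tune(scales$sig, batch$sig / 50)
        scales$xi <- tune(scales$xi, batch$xi / 50)
        scales$sw <- tune(scales$sw, batch$sw / 50)
        batch <- list(u = rep(0, m), beta = 0, eta = 0, sig = 0, xi = 0,
                      sw = c(0, 0))
      }
      if (it > settings$warmup) {
        j <- it - settings$warmup
        Sg <- Sig()
        keep[j, ] <- c(b, eta, exp(lsig), Sg[1, 1], Sg[1, 2], Sg[2, 2])
        if (m > 0 && j %% settings$u_thin == 0) {
          u_keep[[length(u_keep) + 1L]] <- tibble::tibble(
            chain = chain_id, iteration = j, id = prep$id,
            u1 = U[, 1], u2 = U[, 2])
        }
      }
    }
    list(draws = tibble::as_tibble(keep) |>
           dplyr::mutate(chain = chain_id,
                         iteration = seq_len(settings$iterations),
                         .before = 1),
         u = dplyr::bind_rows(u_keep),
         acc = post / settings$iterations)
  }
  chains <- purrr::map(seq_len(settings$chains), run_chain)
  draws <- dplyr::bind_rows(purrr::map(chains, "draws"))
  diag_tbl <- purrr::map_dfr(par_names, function(p) {
    per_chain <- purrr::map(chains, ~.x$draws[[p]])
    tibble::tibble(parameter = p, rhat = split_rhat(per_chain),
                   ess = ess_chains(per_chain))
  })
  converged <- all(is.na(diag_tbl$rhat) | diag_tbl$rhat < 1.05)
  if (!converged) {
    warning("split-chain Rhat exceeds 1.05 for: ",
            paste(diag_tbl$parameter[which(diag_tbl$rhat >= 1.05)],
                  collapse = ", "), call. = FALSE)
  }
  structure(
    list(draws = draws, u_draws = dplyr::bind_rows(purrr::map(chains, "u")),
         diagnostics = diag_tbl, converged = converged,
         acceptance = Reduce(`+`, purrr::map(chains, "acc")) /
           length(chains),
         settings = settings, priors = priors, association = association,
         center = center, free_alphas = free_a),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d chains x %d iterations (%s)\n",
              x$settings$chains, x$settings$iterations,
              if (x$converged) "Rhat < 1.05" else "convergence warning"))
  print(x$diagnostics)
  invisible(x)
}

#' Data from a new subject for posterior prediction
#'
#' @param measurements Tibble with columns `time`, `y` (possibly empty).
#' @param survival_to Known event-free time s (years); must not precede
#'   the last measurement.
#' @return A `"new_subject_data"` list.
#' @export
new_subject_data <- function(measurements, survival_to) {
  measurements <- tibble::as_tibble(measurements)
  if (nrow(measurements)) {
    stopifnot(all(c("time", "y") %in% names(measurements)))
    if (survival_to < max(measurements$time)) {
      stop("`survival_to` must be at least the last measurement time",
           call. = FALSE)
    }
  }
  structure(list(measurements = measurements, survival_to = survival_to),
            class = "new_subject_data")
}

# Sample one random-effect vector per retained parameter draw for a new
# subject, conditional on their measurements AND survival to time s: the
# proposal is the exact Gaussian posterior given the measurements; the
# survivor factor exp(-H(s)) enters as an importance weight, and one of
# `k_imp` proposals is resampled per draw.
sample_new_effects <- function(th, new_subject, k_imp = 20) {
  nd <- nrow(th)
  meas <- new_subject$measurements
  s <- new_subject$survival_to
  if (nrow(meas) == 0) {
    warning("new subject has no measurements; prediction rests on the ",
            "survival information and the posterior alone", call. = FALSE)
  }
  n <- nrow(meas)
  St <- sum(meas$time); Stt <- sum(meas$time^2)
  Sy <- sum(meas$y); Syt <- sum(meas$y * meas$time)
  detS <- th$Sigma11 * th$Sigma22 - th$Sigma12^2
  i11 <- th$Sigma22 / detS; i22 <- th$Sigma11 / detS
  i12 <- -th$Sigma12 / detS
  sig2 <- th$sigma^2
  p11 <- n / sig2 + i11
  p12 <- St / sig2 + i12
  p22 <- Stt / sig2 + i22
  Se <- Sy - th$beta11 * n - th$beta12 * St
  Set <- Syt - th$beta11 * St - th$beta12 * Stt
  r1 <- Se / sig2; r2 <- Set / sig2
  detP <- p11 * p22 - p12^2
  m1 <- (p22 * r1 - p12 * r2) / detP
  m2 <- (p11 * r2 - p12 * r1) / detP
  # covariance chol of P^{-1}: sample U = m + A z with A A' = P^{-1}
  l11 <- sqrt(p11); l21 <- p12 / l11; l22 <- sqrt(p22 - l21^2)
  idx <- rep(seq_len(nd), each = k_imp)
  z1 <- stats::rnorm(nd * k_imp); z2 <- stats::rnorm(nd * k_imp)
  # solve L' x = z  (columns of A = L^{-T})
  x2 <- z2 / l22[idx]
  x1 <- (z1 - l21[idx] * x2) / l11[idx]
  u1 <- m1[idx] + x1
  u2 <- m2[idx] + x2
  a1 <- th$alpha1[idx]; a2 <- th$alpha2[idx]; a3 <- th$alpha3[idx]
  eh <- exp(th$log_lambda[idx] + a3 * (th$beta11[idx] - th$center[idx]) +
              (a1 + a3) * u1 + a2 * u2)
  Hs <- eh * g_funs(a3 * (th$beta12[idx] + u2), rep(s, nd * k_imp))$g
  logw <- -Hs
  pick <- vapply(seq_len(nd), function(j) {
    rows <- (j - 1L) * k_imp + seq_len(k_imp)
    w <- exp(logw[rows] - max(logw[rows]))
    rows[[sample.int(k_imp, 1, prob = w)]]
  }, numeric(1))
  list(u1 = u1[pick], u2 = u2[pick])
}

# pooled post-warmup parameter draws as a plain tibble with all alpha
# columns materialised and the centering constant attached
theta_table <- function(draws, n_use = 1000) {
  th <- draws$draws
  if (nrow(th) > n_use) {
    th <- th[round(seq(1, nrow(th), length.out = n_use)), ]
  }
  for (a in c("alpha1", "alpha2", "alpha3")) {
    if (!a %in% names(th)) th[[a]] <- 0
  }
  th$center <- draws$center
  th
}

#' Posterior-predictive distribution of future marker values
#'
#' For each retained posterior draw of the parameters, samples the new
#' subject's random effects from their conditional posterior given both
#' the observed measurements and survival to time s (via an exact-proposal
#' importance step weighting by the survivor factor), then draws a future
#' observation \eqn{y^* = m(t) + \varepsilon} at each horizon time.
#'
#' @param draws A [run_mcmc()] result (or [posterior_draws_from_csv()]).
#' @param new_subject A [new_subject_data()] object.
#' @param horizon_times Times (years) at which to predict; must exceed the
#'   last measurement time.
#' @param n_use Maximum number of posterior draws used.
#' @param k_imp Importance proposals per draw.
#' @return A tibble with class `"jm_prediction"`: `time`, `mean`, `lo95`,
#'   `hi95` (predictive mean and central 95% interval).
#' @export
predict_longitudinal <- function(draws, new_subject, horizon_times,
                                 n_use = 1000, k_imp = 20) {
  stopifnot(inherits(new_subject, "new_subject_data"))
  if (nrow(new_subject$measurements) &&
      any(horizon_times <= max(new_subject$measurements$time))) {
    stop("`horizon_times` must lie beyond the last measurement",
         call. = FALSE)
  }
  th <- theta_table(draws, n_use)
  u <- sample_new_effects(th, new_subject, k_imp)
  out <- purrr::map_dfr(horizon_times, function(t) {
    y <- (th$beta11 + u$u1) + (th$beta12 + u$u2) * t +
      stats::rnorm(nrow(th), 0, th$sigma)
    tibble::tibble(time = t, mean = mean(y),
                   lo95 = unname(stats::quantile(y, 0.025)),
                   hi95 = unname(stats::quantile(y, 0.975)))
  })
  class(out) <- c("jm_prediction", class(out))
  attr(out, "quantity") <- "longitudinal"
  out
}

#' Posterior-predictive conditional survival for a new subject
#'
#' For each retained posterior draw (with the new subject's random effects
#' sampled as in [predict_longitudinal()]), computes the conditional
#' survival probability \eqn{\exp\{-(H(t) - H(s))\}} of remaining
#' event-free to time t given survival to s, and summarises across draws.
#'
#' @inheritParams predict_longitudinal
#' @param t Prediction times (years), all `>= s`.
#' @return A tibble with class `"jm_prediction"`: `time`, `mean`, `lo95`,
#'   `hi95` for the survival probability, plus `cum_inc = 1 - mean`.
#' @export
predict_survival <- function(draws, new_subject, t, n_use = 1000,
                             k_imp = 20) {
  stopifnot(inherits(new_subject, "new_subject_data"))
  s <- new_subject$survival_to
  if (any(t < s)) {
    stop("prediction times must not precede the known survival time s",
         call. = FALSE)
  }
  th <- theta_table(draws, n_use)
  u <- sample_new_effects(th, new_subject, k_imp)
  eh <- exp(th$log_lambda + th$alpha3 * (th$beta11 - th$center) +
              (th$alpha1 + th$alpha3) * u$u1 + th$alpha2 * u$u2)
  b <- th$alpha3 * (th$beta12 + u$u2)
  Hs <- eh * g_funs(b, rep(s, nrow(th)))$g
  out <- purrr::map_dfr(t, function(tt) {
    p <- exp(-(eh * g_funs(b, rep(tt, nrow(th)))$g - Hs))
    tibble::tibble(time = tt, mean = mean(p),
                   lo95 = unname(stats::quantile(p, 0.025)),
                   hi95 = unname(stats::quantile(p, 0.975)),
                   cum_inc = 1 - mean(p))
  })
  class(out) <- c("jm_prediction", class(out))
  attr(out, "quantity") <- "survival"
  out
}

#' Persist posterior draws as CSV
#'
#' One row per retained draw, one column per parameter (plus `chain`,
#' `iteration` and the centering constant); [posterior_draws_from_csv()]
#' restores an object usable by the prediction functions.
#'
#' @param draws A [run_mcmc()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
posterior_draws_to_csv <- function(draws, path) {
  df <- draws$draws
  df$center <- draws$center
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname posterior_draws_to_csv
#' @param path Path of a CSV written by [posterior_draws_to_csv()].
#' @export
posterior_draws_from_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  center <- if ("center" %in% names(df)) df$center[1] else 47.15
  df$center <- NULL
  free_a <- intersect(c("alpha1", "alpha2", "alpha3"), names(df))
  structure(
    list(draws = df, u_draws = NULL, diagnostics = NULL, converged = NA,
         settings = NULL, priors = NULL,
         association = c(alpha1 = "intercept", alpha2 = "slope",
                         alpha3 = "current")[free_a],
         center = center, free_alphas = free_a),
    class = "posterior_draws"
  )
}

#' @rdname autoplot.jm_prediction
#' @export
plot_prediction <- function(prediction) {
  ggplot2::ggplot(prediction, ggplot2::aes(.data$time, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(
      x = "Years since first examination",
      y = if (identical(attr(prediction, "quantity"), "survival")) {
        "Conditional survival probability"
      } else {
        "Predicted marker value (mm)"
      }) +
    ggplot2::theme_minimal()
}

#' Plot a posterior-predictive curve
#'
#' Predictive mean with its central 95% band over time.
#'
#' @param object,prediction A `"jm_prediction"` tibble from
#'   [predict_longitudinal()] or [predict_survival()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot jm_prediction
#' @export
autoplot.jm_prediction <- function(object, ...) {
  plot_prediction(object)
}
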