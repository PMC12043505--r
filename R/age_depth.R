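# Non-monotonic Bayesian age-depth regression for sediment cores.
#
# theta_i = beta0 + beta1 * d_i + eps_i, eps_i ~ Normal(0, sigma_eps);
# the radiocarbon measurement enters through the standard calibration
# likelihood x_i ~ Normal(mu_c(theta_i), sqrt(sigma_i^2 + sigma_c^2)).
# Latent calendar ages are sampled explicitly, so calibration uncertainty
# propagates exactly; no ordering constraint is placed on theta_i — in
# high-energy depositional settings (storm redeposition, marine ingression)
# age reversals are real and a monotone model is over-precise.

#' Priors for the age-depth regression
#'
#' Defaults are vague on the calendar scale: intercept centred on the
#' middle of the curve support with sd 10,000 yr, slope Normal(0, 10,000
#' yr/m), residual scatter half-Normal(1,000 yr).
#'
#' @param beta0_mean,beta0_sd Intercept prior (cal BP at depth 0).
#' @param beta1_mean,beta1_sd Slope prior (cal yr per metre).
#' @param sigma_eps_scale Half-normal scale of the residual sd (cal yr).
#' @return An object of class `age_depth_priors`.
#' @export
age_depth_priors <- function(beta0_mean = NULL, beta0_sd = 10000,
                             beta1_mean = 0, beta1_sd = 10000,
                             sigma_eps_scale = 1000) {
  structure(list(beta0_mean = beta0_mean, beta0_sd = beta0_sd,
                 beta1_mean = beta1_mean, beta1_sd = beta1_sd,
                 sigma_eps_scale = sigma_eps_scale),
            class = "age_depth_priors")
}

age_depth_chain <- function(x, lab_sd, d, ip, pri, theta_lo, theta_hi,
                            ctl, chain_seed, theta_init) {
  set.seed(as.integer(chain_seed %% .Machine$integer.max))
  n <- length(x)
  theta <- pmin(pmax(theta_init + stats::rnorm(n, 0, 5), theta_lo + 1),
                theta_hi - 1)
  fit0 <- stats::lm.fit(cbind(1, d), theta)
  beta <- fit0$coefficients
  if (anyNA(beta)) beta <- c(mean(theta), 0)
  sigma_eps <- max(stats::sd(fit0$residuals), 10)

  meas_ll <- function(th) {
    mu <- ip$mu(th)
    out <- rep(-Inf, n)
    ok <- !is.na(mu)
    out[ok] <- stats::dnorm(x[ok], mu[ok],
                            sqrt(lab_sd[ok]^2 + ip$sigma(th[ok])^2),
                            log = TRUE)
    out
  }
  ll <- meas_ll(theta)

  prior_prec <- diag(c(1 / pri$beta0_sd^2, 1 / pri$beta1_sd^2))
  prior_mp <- c(pri$beta0_mean / pri$beta0_sd^2,
                pri$beta1_mean / pri$beta1_sd^2)
  X <- cbind(1, d)
  XtX <- crossprod(X)

  s_theta <- rep(40, n); s_ls <- 0.3
  acc_theta <- numeric(n); acc_ls <- 0
  batch <- 50L

  n_keep <- length(seq(ctl$burn_in + ctl$thin, ctl$iterations, by = ctl$thin))
  out_beta <- matrix(NA_real_, n_keep, 2L)
  out_sig <- numeric(n_keep)
  out_theta <- matrix(NA_real_, n_keep, n)
  krow <- 0L

  for (iter in seq_len(ctl$iterations)) {
    ## latent ages: componentwise random walk
    prop <- theta + stats::rnorm(n) * s_theta
    inside <- prop >= theta_lo & prop <= theta_hi
    prop_ll <- meas_ll(ifelse(inside, prop, theta))
    mu_line <- X %*% beta
    logr <- (prop_ll + stats::dnorm(prop, mu_line, sigma_eps, log = TRUE)) -
      (ll + stats::dnorm(theta, mu_line, sigma_eps, log = TRUE))
    logr[!inside] <- -Inf
    acc <- log(stats::runif(n)) < logr
    if (any(acc)) {
      theta[acc] <- prop[acc]
      ll[acc] <- prop_ll[acc]
      acc_theta[acc] <- acc_theta[acc] + 1
    }

    ## regression coefficients: conjugate Gibbs draw given theta, sigma_eps
    prec <- XtX / sigma_eps^2 + prior_prec
    mp <- crossprod(X, theta) / sigma_eps^2 + prior_mp
    ch <- chol(prec)
    mean_b <- backsolve(ch, forwardsolve(t(ch), mp))
    beta <- as.numeric(mean_b + backsolve(ch, stats::rnorm(2)))

    ## residual scatter: log random walk, half-normal prior
    prop_sig <- sigma_eps * exp(stats::rnorm(1) * s_ls)
    resid <- theta - X %*% beta
    logr <- sum(stats::dnorm(resid, 0, prop_sig, log = TRUE)) -
      sum(stats::dnorm(resid, 0, sigma_eps, log = TRUE)) +
      stats::dnorm(prop_sig, 0, pri$sigma_eps_scale, log = TRUE) -
      stats::dnorm(sigma_eps, 0, pri$sigma_eps_scale, log = TRUE) +
      log(prop_sig) - log(sigma_eps)
    if (is.finite(logr) && log(stats::runif(1)) < logr) {
      sigma_eps <- prop_sig
      acc_ls <- acc_ls + 1
    }

    if (iter <= ctl$burn_in && iter %% batch == 0L) {
      gain <- 0.6
      s_theta <- s_theta * exp(gain * (acc_theta / batch - 0.44))
      s_ls <- s_ls * exp(gain * (acc_ls / batch - 0.44))
      acc_theta[] <- 0; acc_ls <- 0
    }
    if (iter > ctl$burn_in && (iter - ctl$burn_in) %% ctl$thin == 0L) {
      krow <- krow + 1L
      out_beta[krow, ] <- beta
      out_sig[krow] <- sigma_eps
      out_theta[krow, ] <- theta
    }
  }
  list(beta = out_beta, sigma_eps = out_sig, theta = out_theta)
}

#' Fit the Bayesian age-depth regression
#'
#' @param core A data.frame (or [date_table]) with columns `lab_code`,
#'   `depth_m`, `c14_age`, `c14_sigma` (and optionally `material`,
#'   terrestrial assumed); at least 3 dated depths, not all equal.
#' @param curve A [cal_curve] covering the plausible calendar range.
#' @param priors An [age_depth_priors].
#' @param mcmc An [mcmc_control].
#' @return An object of class `age_depth_fit` with posterior draws of
#'   `beta0` (cal BP at depth 0), `beta1` (cal yr per metre), `sigma_eps`
#'   (cal yr) and the latent ages, plus diagnostics and a `converged` flag.
#' @export
#' @examples
#' curve <- sim_cal_curve(c(12000, 500), wiggle_amplitude = 0, noise_sd = 0,
#'                        sigma = 8, seed = 1)
#' core <- sim_core(core_sim_config(beta0 = 3000, beta1 = 1500,
#'   sigma_eps = 80, depths = seq(0.2, 3, by = 0.4), lab_sigma = 40,
#'   seed = 3), curve)
#' fit <- age_depth(core$core, curve,
#'   mcmc = mcmc_control(chains = 2, iterations = 1500, burn_in = 500,
#'                       thin = 5, seed = 1))
#' coef(fit)
age_depth <- function(core, curve, priors = age_depth_priors(),
                      mcmc = mcmc_control()) {
  core <- as.data.frame(core)
  req <- c("lab_code", "depth_m", "c14_age", "c14_sigma")
  if (!all(req %in% names(core))) {
    stop_bc(paste("core needs columns:", paste(req, collapse = ", ")),
            "baychron_validation_error")
  }
  if (nrow(core) < 3L) {
    stop_bc("age-depth regression needs at least 3 dated depths",
            "baychron_validation_error")
  }
  if (anyDuplicated(core$lab_code)) {
    stop_bc("duplicate lab_code in core", "baychron_validation_error")
  }
  if (length(unique(core$depth_m)) < 2L) {
    stop_bc("depths must not all be equal", "baychron_validation_error")
  }
  if (any(core$c14_sigma <= 0) || any(core$depth_m < 0)) {
    stop_bc("c14_sigma must be > 0 and depth_m >= 0", "baychron_validation_error")
  }
  stopifnot(inherits(curve, "cal_curve"))
  # canonical ordering: the posterior is exchangeable in the samples, and
  # sorting makes seeded runs identical regardless of input row order
  core <- core[order(core$depth_m, core$lab_code), , drop = FALSE]
  rownames(core) <- NULL
  ip <- curve_interpolator(curve)

  # initial ages from single-date calibration medians
  grid <- cal_grid(ip$hi, ip$lo, step_yr = 5)
  theta_init <- vapply(seq_len(nrow(core)), function(i) {
    det <- list(c14_age = core$c14_age[i], c14_sigma = core$c14_sigma[i],
                material = "terrestrial")
    point_summaries(calibrate_terrestrial(det, curve, grid))$median
  }, 0)
  if (is.null(priors$beta0_mean)) priors$beta0_mean <- mean(c(ip$lo, ip$hi))

  chains <- lapply(seq_len(mcmc$chains), function(cc) {
    age_depth_chain(core$c14_age, core$c14_sigma, core$depth_m, ip, priors,
                    ip$lo, ip$hi, mcmc, chain_seed = mcmc$seed + 1000L * cc,
                    theta_init)
  })
  beta0_mat <- sapply(chains, function(ch) ch$beta[, 1])
  beta1_mat <- sapply(chains, function(ch) ch$beta[, 2])
  sig_mat <- sapply(chains, `[[`, "sigma_eps")
  diag <- data.frame(
    parameter = c("beta0", "beta1", "sigma_eps"),
    rhat = c(split_rhat(beta0_mat), split_rhat(beta1_mat), split_rhat(sig_mat)),
    ess = c(ess_draws(beta0_mat), ess_draws(beta1_mat), ess_draws(sig_mat)))

  theta_samples <- do.call(rbind, lapply(chains, `[[`, "theta"))
  colnames(theta_samples) <- core$lab_code
  structure(list(core = core, curve_name = curve$name,
                 beta0_samples = as.numeric(beta0_mat),
                 beta1_samples = as.numeric(beta1_mat),
                 sigma_eps_samples = as.numeric(sig_mat),
                 theta_samples = theta_samples,
                 priors = priors, diagnostics = diag,
                 converged = all(diag$rhat <= 1.05, na.rm = TRUE),
                 seed = mcmc$seed),
            class = "age_depth_fit")
}

#' @export
print.age_depth_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian age-depth regression (%d dated depths)\n  beta0 %.0f cal BP, beta1 %.0f yr/m, sigma_eps %.0f yr%s\n",
    nrow(x$core), mean(x$beta0_samples), mean(x$beta1_samples),
    mean(x$sigma_eps_samples),
    if (!x$converged) "  [R-hat flag]" else ""))
  invisible(x)
}

#' @export
coef.age_depth_fit <- function(object, ...) {
  c(beta0 = mean(object$beta0_samples), beta1 = mean(object$beta1_samples),
    sigma_eps = mean(object$sigma_eps_samples))
}

#' @export
summary.age_depth_fit <- function(object, ...) {
  draws <- cbind(beta0 = object$beta0_samples, beta1 = object$beta1_samples,
                 sigma_eps = object$sigma_eps_samples)
  s <- data.frame(parameter = colnames(draws),
                  mean = colMeans(draws),
                  sd = apply(draws, 2, stats::sd),
                  t(apply(draws, 2, hpd_from_draws, level = 0.95)))
  names(s)[4:5] <- c("hpd95_lower", "hpd95_upper")
  rownames(s) <- NULL
  out <- list(estimates = s, diagnostics = object$diagnostics,
              converged = object$converged)
  class(out) <- "summary.age_depth_fit"
  out
}

#' @export
print.summary.age_depth_fit <- function(x, ...) {
  print(x$estimates, row.names = FALSE)
  cat("\nDiagnostics:\n"); print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' @export
plot.age_depth_fit <- function(x, ...) {
  d <- x$core$depth_m
  th <- colMeans(x$theta_samples)
  ds <- seq(min(d), max(d), length.out = 50)
  line <- x$beta0_samples + x$beta1_samples %o% ds
  qs <- apply(line, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  graphics::plot(th, d, ylim = rev(range(d)), xlab = "cal BP",
                 ylab = "depth (m)", ...)
  graphics::lines(qs[2, ], ds); graphics::lines(qs[1, ], ds, lty = 2)
  graphics::lines(qs[3, ], ds, lty = 2)
  invisible(x)
}

#' Posterior-predictive calendar ages at undated depths
#'
#' Bayesian imputation: for each requested depth d the predictive draw is
#' beta0 + beta1 * d + eps, eps ~ Normal(0, sigma_eps draw), over the
#' retained posterior draws.
#'
#' @param fit An `age_depth_fit`.
#' @param depths Depths in metres (non-empty).
#' @param force Proceed even if the fit is flagged non-converged.
#' @param level HPD level for the per-depth summary.
#' @return An object of class `age_depth_imputation`: `draws` (draws x
#'   depths), and `summary` (per-depth mean, sd, HPD).
#' @export
impute_depth_ages <- function(fit, depths, force = FALSE, level = 0.95) {
  stopifnot(inherits(fit, "age_depth_fit"))
  if (!length(depths)) stop_bc("empty depth list", "baychron_validation_error")
  if (!fit$converged && !force) {
    stop_bc("fit flagged as non-converged; pass force = TRUE to impute anyway",
            "baychron_convergence_error")
  }
  nd <- length(fit$beta0_samples)
  draws <- matrix(NA_real_, nd, length(depths))
  for (k in seq_along(depths)) {
    draws[, k] <- fit$beta0_samples + fit$beta1_samples * depths[k] +
      stats::rnorm(nd, 0, fit$sigma_eps_samples)
  }
  colnames(draws) <- sprintf("d%.3g", depths)
  hp <- apply(draws, 2, hpd_from_draws, level = level)
  structure(list(
    depths = depths, draws = draws,
    summary = data.frame(depth_m = depths, mean = colMeans(draws),
                         sd = apply(draws, 2, stats::sd),
                         hpd_lower = hp["lower", ], hpd_upper = hp["upper", ])),
    class = "age_depth_imputation")
}

#' @export
predict.age_depth_fit <- function(object, depths, ...) {
  impute_depth_ages(object, depths, ...)
}

#' @export
print.age_depth_imputation <- function(x, ...) {
  cat("Imputed calendar ages (cal BP):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Count age reversals in a core
#'
#' Sorts samples by depth and counts adjacent pairs whose single-date
#' calibrated posterior mean decreases with depth — the diagnostic for
#' sediment redeposition ("very old dates near the surface") that
#' motivates dropping the monotonicity assumption.
#'
#' @param core Core data.frame as in [age_depth] (>= 2 samples).
#' @param curve A [cal_curve].
#' @return Integer count of reversals.
#' @export
count_reversals <- function(core, curve) {
  core <- as.data.frame(core)
  if (nrow(core) < 2L) stop_bc("need >= 2 samples", "baychron_validation_error")
  ip <- curve_interpolator(curve)
  grid <- cal_grid(ip$hi, ip$lo, step_yr = 5)
  means <- vapply(seq_len(nrow(core)), function(i) {
    det <- list(c14_age = core$c14_age[i], c14_sigma = core$c14_sigma[i],
                material = "terrestrial")
    point_summaries(calibrate_terrestrial(det, curve, grid))$mean
  }, 0)
  ord <- order(core$depth_m)
  sum(diff(means[ord]) < 0)
}
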