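# Local marine reservoir offset (Delta-R) estimation from stratigraphically
# paired terrestrial (charcoal) and marine (shell) determinations.
#
# Hierarchical model: each context c has one latent event age theta_c shared
# by all of its samples; terrestrial likelihood Normal(x; mu_I(theta_c),
# sqrt(sigma^2 + sigma_I^2)), marine likelihood Normal(x; mu_M(theta_c) +
# Delta-R, sqrt(sigma^2 + sigma_M^2)); a single shared Delta-R with a wide
# uniform prior (+/- prior_halfwidth 14C yr).

#' Group a date table into paired stratigraphic contexts
#'
#' @param dates A [date_table] with a `context_id` column; every context
#'   must contain at least one terrestrial and one marine determination.
#' @return List of `paired_context` objects.
#' @export
paired_contexts <- function(dates) {
  dates <- date_table(dates)
  if (!"context_id" %in% names(dates) || all(is.na(dates$context_id))) {
    stop_bc("paired_contexts requires a context_id column", "baychron_validation_error")
  }
  split_df <- split(as.data.frame(dates), dates$context_id)
  lapply(split_df, function(d) {
    terr <- d[d$material == "terrestrial", , drop = FALSE]
    mar <- d[d$material == "marine", , drop = FALSE]
    if (!nrow(terr) || !nrow(mar)) {
      stop_bc(sprintf("context %s must contain both terrestrial and marine dates",
                      d$context_id[1]), "baychron_validation_error")
    }
    structure(list(context_id = d$context_id[1], terrestrial = terr,
                   marine = mar),
              class = "paired_context")
  })
}

delta_r_chain <- function(x, lab_sd, is_mar, ctx_of, ipT, ipM,
                          theta_lo, theta_hi, halfwidth, ctl, chain_seed,
                          theta_init) {
  set.seed(as.integer(chain_seed %% .Machine$integer.max))
  n_ctx <- length(theta_init)
  theta <- theta_init + stats::rnorm(n_ctx, 0, 5)
  theta <- pmin(pmax(theta, theta_lo + 1), theta_hi - 1)
  dr <- stats::runif(1, -halfwidth / 10, halfwidth / 10)

  ll_sample <- function(theta_c, dr_val) {
    # log-likelihood of every sample given its context age and Delta-R
    th <- theta_c[ctx_of]
    out <- rep(-Inf, length(x))
    ti <- which(!is_mar); mi <- which(is_mar)
    mu <- ipT$mu(th[ti]); s2 <- ipT$sigma(th[ti])^2
    ok <- !is.na(mu)
    out[ti[ok]] <- stats::dnorm(x[ti][ok], mu[ok],
                                sqrt(lab_sd[ti][ok]^2 + s2[ok]), log = TRUE)
    mu <- ipM$mu(th[mi]) + dr_val; s2 <- ipM$sigma(th[mi])^2
    ok <- !is.na(mu)
    out[mi[ok]] <- stats::dnorm(x[mi][ok], mu[ok],
                                sqrt(lab_sd[mi][ok]^2 + s2[ok]), log = TRUE)
    out
  }

  ll <- ll_sample(theta, dr)
  ll_ctx <- as.numeric(rowsum(ll, ctx_of))

  s_theta <- rep(40, n_ctx); s_dr <- 40
  acc_theta <- numeric(n_ctx); acc_dr <- 0
  batch <- 50L

  keep_iters <- seq(ctl$burn_in + ctl$thin, ctl$iterations, by = ctl$thin)
  out_dr <- numeric(length(keep_iters))
  out_theta <- matrix(NA_real_, length(keep_iters), n_ctx)
  krow <- 0L

  for (iter in seq_len(ctl$iterations)) {
    # context ages, componentwise
    prop <- theta + stats::rnorm(n_ctx) * s_theta
    prop[prop < theta_lo | prop > theta_hi] <- NA
    prop_full <- ifelse(is.na(prop), theta, prop)
    ll_new <- ll_sample(prop_full, dr)
    ll_ctx_new <- as.numeric(rowsum(ll_new, ctx_of))
    logr <- ll_ctx_new - ll_ctx
    logr[is.na(prop)] <- -Inf
    acc <- log(stats::runif(n_ctx)) < logr
    if (any(acc)) {
      theta[acc] <- prop_full[acc]
      ll_ctx[acc] <- ll_ctx_new[acc]
      acc_theta[acc] <- acc_theta[acc] + 1
      sel <- acc[ctx_of] # per-sample rows of the accepted contexts
      ll[sel] <- ll_new[sel]
    }
    # shared Delta-R
    dr_prop <- dr + stats::rnorm(1) * s_dr
    if (abs(dr_prop) <= halfwidth) {
      ll_new <- ll_sample(theta, dr_prop)
      logr <- sum(ll_new) - sum(ll)
      if (is.finite(logr) && log(stats::runif(1)) < logr) {
        dr <- dr_prop; ll <- ll_new
        ll_ctx <- as.numeric(rowsum(ll, ctx_of))
        acc_dr <- acc_dr + 1
      }
    }
    if (iter <= ctl$burn_in && iter %% batch == 0L) {
      gain <- 0.6
      s_theta <- s_theta * exp(gain * (acc_theta / batch - 0.44))
      s_dr <- s_dr * exp(gain * (acc_dr / batch - 0.44))
      acc_theta[] <- 0; acc_dr <- 0
    }
    if (iter > ctl$burn_in && (iter - ctl$burn_in) %% ctl$thin == 0L) {
      krow <- krow + 1L
      out_dr[krow] <- dr
      out_theta[krow, ] <- theta
    }
  }
  list(dr = out_dr, theta = out_theta)
}

#' Estimate the local marine reservoir offset Delta-R
#'
#' Fits the shared-Delta-R hierarchical model to paired contexts by MCMC,
#' then applies the agreement screening used for chronological models:
#' samples whose agreement index falls below `a_threshold` (default 60%)
#' are listed as excluded and the model is refitted once without them.
#'
#' @param pairs List of `paired_context` objects (see [paired_contexts]).
#' @param terrestrial_curve Terrestrial [cal_curve] (IntCal20-type).
#' @param marine_curve Marine [cal_curve] (Marine20-type).
#' @param prior_halfwidth Halfwidth of the uniform Delta-R prior, 14C yr
#'   ("wide restriction"); default 1000.
#' @param mcmc An [mcmc_control].
#' @param a_threshold Agreement-index screening threshold in percent.
#' @return An object of class `delta_r_fit`: `samples`, `mean`, `sd`,
#'   `hpd95`, `excluded` (lab codes dropped with their A-index),
#'   `diagnostics`, `seed`.
#' @export
estimate_delta_r <- function(pairs, terrestrial_curve, marine_curve,
                             prior_halfwidth = 1000, mcmc = mcmc_control(),
                             a_threshold = 60) {
  if (!length(pairs)) stop_bc("need at least one paired context",
                              "baychron_validation_error")
  if (prior_halfwidth <= 0) stop_bc("prior_halfwidth must be > 0",
                                    "baychron_validation_error")
  stopifnot(inherits(terrestrial_curve, "cal_curve"),
            inherits(marine_curve, "cal_curve"))

  flatten <- function(pairs) {
    rows <- do.call(rbind, lapply(pairs, function(p) {
      rbind(as.data.frame(p$terrestrial), as.data.frame(p$marine))
    }))
    rows$context_id <- rep(vapply(pairs, `[[`, "", "context_id"),
                           vapply(pairs, function(p)
                             nrow(p$terrestrial) + nrow(p$marine), 0L))
    rows
  }

  fit_once <- function(df) {
    ipT <- curve_interpolator(terrestrial_curve)
    ipM <- curve_interpolator(marine_curve)
    theta_lo <- max(ipT$lo, ipM$lo); theta_hi <- min(ipT$hi, ipM$hi)
    ctx_levels <- unique(df$context_id)
    ctx_of <- match(df$context_id, ctx_levels)
    is_mar <- df$material == "marine"

    # initial context ages and an overlap check: terrestrial 99.9% support
    # must intersect the marine support widened by the Delta-R prior
    grid <- cal_grid(theta_hi, theta_lo, step_yr = 5)
    theta_init <- numeric(length(ctx_levels))
    for (c in seq_along(ctx_levels)) {
      rows_c <- df[ctx_of == c, , drop = FALSE]
      terr <- rows_c[rows_c$material == "terrestrial", , drop = FALSE]
      mar <- rows_c[rows_c$material == "marine", , drop = FALSE]
      dt_dens <- calibrate_terrestrial(as.list(terr[1, ]), terrestrial_curve,
                                       grid)
      theta_init[c] <- point_summaries(dt_dens)$median
      ht <- hpd_intervals(dt_dens, 0.999)$intervals
      dm_dens <- calibrate_marine(as.list(mar[1, ]), marine_curve, 0,
                                  prior_halfwidth, grid)
      hm <- hpd_intervals(dm_dens, 0.999)$intervals
      if (min(hm$younger) > max(ht$older) || max(hm$older) < min(ht$younger)) {
        stop_bc(sprintf(
          "no overlap between terrestrial and marine supports in context %s within the Delta-R prior",
          ctx_levels[c]), "baychron_divergence_error")
      }
    }

    chains <- lapply(seq_len(mcmc$chains), function(cc) {
      delta_r_chain(df$c14_age, df$c14_sigma, is_mar, ctx_of, ipT, ipM,
                    theta_lo, theta_hi, prior_halfwidth, mcmc,
                    chain_seed = mcmc$seed + 1000L * cc, theta_init)
    })
    dr_mat <- sapply(chains, `[[`, "dr")
    theta_all <- do.call(rbind, lapply(chains, `[[`, "theta"))
    dr <- as.numeric(dr_mat)

    # per-sample agreement: unmodelled calibration vs modelled context age
    agreement <- numeric(nrow(df))
    dr_mean <- mean(dr); dr_sd <- stats::sd(dr)
    for (i in seq_len(nrow(df))) {
      d <- as.list(df[i, ])
      unmod <- if (is_mar[i]) {
        calibrate_marine(d, marine_curve, dr_mean, dr_sd, grid)
      } else {
        calibrate_terrestrial(d, terrestrial_curve, grid)
      }
      modelled <- density_from_draws(theta_all[, ctx_of[i]], grid)
      agreement[i] <- agreement_index(unmod, modelled)
    }
    list(dr = dr, dr_rhat = split_rhat(dr_mat),
         agreement = stats::setNames(agreement, df$lab_code))
  }

  df <- flatten(pairs)
  first <- fit_once(df)
  bad <- names(first$agreement)[first$agreement < a_threshold]
  excluded <- data.frame(lab_code = bad,
                         agreement = as.numeric(first$agreement[bad]))
  if (length(bad)) {
    df2 <- df[!df$lab_code %in% bad, , drop = FALSE]
    # screening must not empty a side of any context; drop contexts that lose one
    keep_ctx <- vapply(split(df2, df2$context_id), function(d) {
      any(d$material == "terrestrial") && any(d$material == "marine")
    }, TRUE)
    df2 <- df2[df2$context_id %in% names(keep_ctx)[keep_ctx], , drop = FALSE]
    if (!nrow(df2)) {
      stop_bc("agreement screening removed every context", "baychron_divergence_error")
    }
    final <- fit_once(df2)
  } else {
    final <- first
  }

  h <- hpd_from_draws(final$dr, 0.95)
  structure(list(samples = final$dr,
                 prior_halfwidth = prior_halfwidth,
                 mean = mean(final$dr), sd = stats::sd(final$dr),
                 hpd95 = c(lower = h[["lower"]], upper = h[["upper"]]),
                 excluded = excluded,
                 agreement = final$agreement,
                 diagnostics = data.frame(parameter = "delta_r",
                                          rhat = final$dr_rhat),
                 seed = mcmc$seed),
            class = "delta_r_fit")
}

#' @export
print.delta_r_fit <- function(x, ...) {
  cat(sprintf("Delta-R posterior: %.0f +/- %.0f 14C yr (95%% HPD %.0f to %.0f)\n",
              x$mean, x$sd, x$hpd95[["lower"]], x$hpd95[["upper"]]))
  if (nrow(x$excluded)) {
    cat(sprintf("Excluded by A < 60%%: %s\n",
                paste(x$excluded$lab_code, collapse = ", ")))
  }
  invisible(x)
}

#' @export
coef.delta_r_fit <- function(object, ...) {
  c(delta_r = object$mean)
}

#' Calibrate marine dates with an estimated Delta-R
#'
#' Applies the Delta-R posterior (its mean and sd) to every shell date and
#' reports the pooled oldest/youngest summary: the posterior means of the
#' extreme shells.
#'
#' @param shells A [date_table] of marine determinations.
#' @param marine_curve Marine [cal_curve].
#' @param dr A `delta_r_fit` (or a list with `mean` and `sd`).
#' @param grid A [cal_grid].
#' @return An object of class `delta_r_calibration`: `densities` (one
#'   `cal_density` per shell), `means`, and `pooled_range`
#'   `c(oldest, youngest)` cal BP.
#' @export
apply_delta_r <- function(shells, marine_curve, dr, grid) {
  shells <- date_table(shells)
  if (any(shells$material != "marine")) {
    stop_bc("apply_delta_r expects marine rows only", "baychron_material_error")
  }
  densities <- vector("list", nrow(shells))
  means <- numeric(nrow(shells))
  for (i in seq_len(nrow(shells))) {
    densities[[i]] <- calibrate_marine(as.list(shells[i, ]), marine_curve,
                                       dr$mean, dr$sd, grid)
    means[i] <- point_summaries(densities[[i]])$mean
  }
  names(densities) <- shells$lab_code
  structure(list(densities = densities,
                 means = stats::setNames(means, shells$lab_code),
                 pooled_range = c(oldest = max(means), youngest = min(means))),
            class = "delta_r_calibration")
}

#' @export
print.delta_r_calibration <- function(x, ...) {
  cat(sprintf("%d marine dates calibrated; pooled range %.1f to %.1f ka\n",
              length(x$densities), as_ka(x$pooled_range[["oldest"]]),
              as_ka(x$pooled_range[["youngest"]])))
  invisible(x)
}
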