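# Seeded simulators with known truth: calibration curves, phased sites,
# paired reservoir data sets, disturbed cores. Every generator is a pure
# function of (config, seed); the caller's RNG state is untouched.

#' Simulate a calibration curve
#'
#' mu_c(theta) = theta + amplitude * sin(2 pi theta / period) + smooth
#' seeded noise (a spline through Normal(0, noise_sd) offsets at 200-yr
#' anchor points), at 1-yr knots over the requested range with a constant
#' curve error. Amplitude 0 and noise 0 give the identity curve, handy for
#' closed-form checks.
#'
#' @param range_calbp `c(oldest, youngest)` cal BP, within (0, 60000).
#' @param wiggle_amplitude Sine amplitude, 14C yr.
#' @param wiggle_period Sine period, yr.
#' @param sigma Constant one-sigma curve error, 14C yr, > 0.
#' @param noise_sd Smooth-noise scale, 14C yr.
#' @param seed RNG seed.
#' @param kind `"terrestrial"` or `"marine"`.
#' @param name Curve label.
#' @return A [cal_curve] with `oldest - youngest + 1` knots.
#' @export
sim_cal_curve <- function(range_calbp, wiggle_amplitude = 20,
                          wiggle_period = 500, sigma = 10, noise_sd = 5,
                          seed = 1, kind = c("terrestrial", "marine"),
                          name = "simulated") {
  kind <- match.arg(kind)
  old <- max(range_calbp); young <- min(range_calbp)
  if (young <= 0 || old >= 60000) {
    stop_bc("range must lie within (0, 60000) cal BP", "baychron_validation_error")
  }
  if (sigma <= 0) stop_bc("sigma must be > 0", "baychron_validation_error")
  with_seed(seed, {
    theta <- seq(old, young, by = -1)
    mu <- theta + wiggle_amplitude * sin(2 * pi * theta / wiggle_period)
    if (noise_sd > 0) {
      anchors <- seq(old, young, length.out = max(4L, ceiling((old - young) / 200)))
      bumps <- stats::rnorm(length(anchors), 0, noise_sd)
      mu <- mu + stats::spline(anchors, bumps, xout = theta)$y
    }
    if (any(!is.finite(mu))) {
      stop_bc("simulated curve mean is non-finite; reduce amplitude/noise",
              "baychron_validation_error")
    }
    cal_curve(theta, mu, rep(sigma, length(theta)), name = name, kind = kind)
  })
}

#' Configuration for a simulated phased site
#'
#' @param phase_truths List of `c(start, end)` cal BP pairs (start > end),
#'   ordered older to younger.
#' @param dates_per_phase Dates drawn per phase (scalar or per-phase vector).
#' @param lab_sigma Lab error, 14C yr.
#' @param outlier_fraction Fraction of dates given a heavy-tailed calendar
#'   shift (Student-t(5) x `outlier_shift_scale` yr).
#' @param outlier_shift_scale Scale of outlier shifts, cal yr.
#' @param marine_fraction Fraction of dates that are marine shells.
#' @param true_delta_r True local reservoir offset, 14C yr.
#' @param seed RNG seed.
#' @return An object of class `site_sim_config`.
#' @export
site_sim_config <- function(phase_truths, dates_per_phase, lab_sigma = 40,
                            outlier_fraction = 0, outlier_shift_scale = 1000,
                            marine_fraction = 0, true_delta_r = 0, seed = 1) {
  for (p in phase_truths) {
    if (p[1] <= p[2]) stop_bc("phase start must be older than end",
                              "baychron_validation_error")
  }
  if (lab_sigma <= 0) stop_bc("lab_sigma must be > 0", "baychron_validation_error")
  for (f in c(outlier_fraction, marine_fraction)) {
    if (f < 0 || f > 1) stop_bc("fractions must be in [0, 1]",
                                "baychron_validation_error")
  }
  structure(list(phase_truths = phase_truths,
                 dates_per_phase = dates_per_phase, lab_sigma = lab_sigma,
                 outlier_fraction = outlier_fraction,
                 outlier_shift_scale = outlier_shift_scale,
                 marine_fraction = marine_fraction,
                 true_delta_r = true_delta_r, seed = seed),
            class = "site_sim_config")
}

#' Simulate a multi-phase occupation site
#'
#' True event ages are uniform within each phase; outlier dates get a
#' Student-t(5)-scaled calendar shift before mapping through the curve;
#' marine dates are offset by the true Delta-R on the marine curve. The
#' conventional radiocarbon age of each sample is
#' Normal(mu_curve(theta_eff) [+ Delta-R], sqrt(lab_sigma^2 + sigma_c^2)).
#' Shifted ages falling outside curve support are clipped (the clip is
#' recorded in the truth table); conventional ages are never clipped.
#'
#' @param cfg A [site_sim_config].
#' @param terrestrial_curve Terrestrial [cal_curve].
#' @param marine_curve Marine [cal_curve]; required when
#'   `marine_fraction > 0`.
#' @return List with `dates` (a [date_table] with `phase_id`) and `truth`
#'   (a data.frame holding every latent variable).
#' @export
sim_phased_site <- function(cfg, terrestrial_curve, marine_curve = NULL) {
  stopifnot(inherits(cfg, "site_sim_config"))
  K <- length(cfg$phase_truths)
  npp <- rep(cfg$dates_per_phase, length.out = K)
  ipT <- curve_interpolator(terrestrial_curve)
  ipM <- if (!is.null(marine_curve)) curve_interpolator(marine_curve)
  for (p in cfg$phase_truths) {
    if (p[1] > ipT$hi || p[2] < ipT$lo) {
      stop_bc("phase truth outside curve support", "baychron_range_error")
    }
  }
  with_seed(cfg$seed, {
    rows <- list(); truth <- list(); lab <- 0L
    for (j in seq_len(K)) {
      if (npp[j] == 0L) next
      p <- cfg$phase_truths[[j]]
      theta <- stats::runif(npp[j], p[2], p[1])
      is_out <- stats::runif(npp[j]) < cfg$outlier_fraction
      shift <- ifelse(is_out,
                      stats::rt(npp[j], df = 5) * cfg$outlier_shift_scale, 0)
      is_mar <- stats::runif(npp[j]) < cfg$marine_fraction
      if (any(is_mar) && is.null(ipM)) {
        stop_bc("marine_fraction > 0 requires a marine_curve",
                "baychron_validation_error")
      }
      theta_eff <- theta + shift
      clipped <- theta_eff < ipT$lo | theta_eff > ipT$hi
      theta_eff <- pmin(pmax(theta_eff, ipT$lo), ipT$hi)
      mu <- numeric(npp[j]); sc <- numeric(npp[j])
      ti <- which(!is_mar); mi <- which(is_mar)
      if (length(ti)) {
        mu[ti] <- ipT$mu(theta_eff[ti]); sc[ti] <- ipT$sigma(theta_eff[ti])
      }
      if (length(mi)) {
        th_m <- pmin(pmax(theta_eff[mi], ipM$lo), ipM$hi)
        mu[mi] <- ipM$mu(th_m) + cfg$true_delta_r
        sc[mi] <- ipM$sigma(th_m)
      }
      cra <- stats::rnorm(npp[j], mu, sqrt(cfg$lab_sigma^2 + sc^2))
      codes <- sprintf("SIM-%03d", lab + seq_len(npp[j])); lab <- lab + npp[j]
      rows[[j]] <- data.frame(
        lab_code = codes, c14_age = round(cra), c14_sigma = cfg$lab_sigma,
        material = ifelse(is_mar, "marine", "terrestrial"),
        phase_id = sprintf("P%d", j))
      truth[[j]] <- data.frame(
        lab_code = codes, phase = j, theta = theta, outlier = is_out,
        shift = shift, theta_eff = theta_eff, clipped = clipped,
        marine = is_mar)
    }
    if (!length(rows)) {
      empty <- data.frame(lab_code = character(), c14_age = numeric(),
                          c14_sigma = numeric(), material = character(),
                          phase_id = character())
      return(list(dates = date_table(empty), truth = empty))
    }
    list(dates = date_table(do.call(rbind, rows)),
         truth = do.call(rbind, truth))
  })
}

#' Simulate paired charcoal/shell contexts for Delta-R estimation
#'
#' One latent event age per context, shared by its terrestrial and marine
#' samples; shells are offset by the true Delta-R on the marine curve.
#'
#' @param n_contexts Number of stratigraphic contexts.
#' @param n_terrestrial,n_marine Samples per context of each material.
#' @param true_delta_r True offset, 14C yr.
#' @param terrestrial_curve,marine_curve [cal_curve]s.
#' @param age_range `c(oldest, youngest)` cal BP for the context ages.
#' @param lab_sigma Lab error, 14C yr.
#' @param seed RNG seed.
#' @return List with `pairs` (list of `paired_context`), `dates` (the flat
#'   [date_table]) and `truth` (context ages).
#' @export
sim_paired_reservoir <- function(n_contexts, n_terrestrial = 2, n_marine = 3,
                                 true_delta_r = 0, terrestrial_curve,
                                 marine_curve, age_range, lab_sigma = 35,
                                 seed = 1) {
  if (n_contexts == 0L) {
    return(list(pairs = list(), dates = NULL,
                truth = data.frame(context_id = character(), theta = numeric())))
  }
  ipT <- curve_interpolator(terrestrial_curve)
  ipM <- curve_interpolator(marine_curve)
  with_seed(seed, {
    theta_c <- stats::runif(n_contexts, min(age_range), max(age_range))
    rows <- list()
    for (c in seq_len(n_contexts)) {
      id <- sprintf("CTX-%02d", c)
      mt <- ipT$mu(theta_c[c]); st <- ipT$sigma(theta_c[c])
      mm <- ipM$mu(theta_c[c]) + true_delta_r; sm <- ipM$sigma(theta_c[c])
      rows[[c]] <- data.frame(
        lab_code = c(sprintf("%s-T%d", id, seq_len(n_terrestrial)),
                     sprintf("%s-M%d", id, seq_len(n_marine))),
        c14_age = round(c(
          stats::rnorm(n_terrestrial, mt, sqrt(lab_sigma^2 + st^2)),
          stats::rnorm(n_marine, mm, sqrt(lab_sigma^2 + sm^2)))),
        c14_sigma = lab_sigma,
        material = c(rep("terrestrial", n_terrestrial),
                     rep("marine", n_marine)),
        context_id = id)
    }
    dates <- date_table(do.call(rbind, rows))
    list(pairs = paired_contexts(dates), dates = dates,
         truth = data.frame(context_id = sprintf("CTX-%02d", seq_len(n_contexts)),
                            theta = theta_c))
  })
}

#' Configuration for a simulated sediment core
#'
#' @param beta0 True intercept, cal BP at depth 0.
#' @param beta1 True accumulation slope, cal yr per metre.
#' @param sigma_eps True residual scatter, cal yr.
#' @param depths Strictly increasing depths, metres.
#' @param redeposit_fraction Fraction of samples re-deposited (older
#'   material moved up-core).
#' @param redeposit_shift Calendar shift added to redeposited samples, yr
#'   (positive = older).
#' @param lab_sigma Lab error, 14C yr.
#' @param seed RNG seed.
#' @return An object of class `core_sim_config`.
#' @export
core_sim_config <- function(beta0, beta1, sigma_eps, depths,
                            redeposit_fraction = 0, redeposit_shift = 800,
                            lab_sigma = 40, seed = 1) {
  if (any(diff(depths) <= 0)) {
    stop_bc("depths must be strictly increasing", "baychron_validation_error")
  }
  if (lab_sigma <= 0 || sigma_eps < 0) {
    stop_bc("lab_sigma must be > 0 and sigma_eps >= 0", "baychron_validation_error")
  }
  structure(list(beta0 = beta0, beta1 = beta1, sigma_eps = sigma_eps,
                 depths = depths, redeposit_fraction = redeposit_fraction,
                 redeposit_shift = redeposit_shift, lab_sigma = lab_sigma,
                 seed = seed),
            class = "core_sim_config")
}

#' Simulate a (possibly disturbed) sediment core
#'
#' theta_i = beta0 + beta1 * d_i + Normal(0, sigma_eps); a
#' `redeposit_fraction` of samples receives `+redeposit_shift` calendar
#' years (older intrusions), emulating storm redeposition; conventional
#' ages map through the curve with lab error. Ages outside curve support
#' are clipped and the clip recorded.
#'
#' @param cfg A [core_sim_config].
#' @param curve A [cal_curve].
#' @return List with `core` (data.frame for [age_depth]) and `truth`.
#' @export
sim_core <- function(cfg, curve) {
  stopifnot(inherits(cfg, "core_sim_config"))
  ip <- curve_interpolator(curve)
  with_seed(cfg$seed, {
    n <- length(cfg$depths)
    theta <- cfg$beta0 + cfg$beta1 * cfg$depths +
      stats::rnorm(n, 0, cfg$sigma_eps)
    n_re <- round(cfg$redeposit_fraction * n)
    re_idx <- if (n_re > 0) sample.int(n, n_re) else integer()
    theta[re_idx] <- theta[re_idx] + cfg$redeposit_shift
    clipped <- theta < ip$lo | theta > ip$hi
    theta_eff <- pmin(pmax(theta, ip$lo), ip$hi)
    mu <- ip$mu(theta_eff); sc <- ip$sigma(theta_eff)
    cra <- round(stats::rnorm(n, mu, sqrt(cfg$lab_sigma^2 + sc^2)))
    core <- data.frame(lab_code = sprintf("CORE-%03d", seq_len(n)),
                       depth_m = cfg$depths, c14_age = cra,
                       c14_sigma = cfg$lab_sigma, material = "terrestrial")
    truth <- data.frame(lab_code = core$lab_code, depth_m = cfg$depths,
                        theta = theta_eff,
                        redeposited = seq_len(n) %in% re_idx,
                        clipped = clipped)
    list(core = core, truth = truth)
  })
}
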