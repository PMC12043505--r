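# Fixture builders and independent oracles used across the test files.
# Oracles are deliberately written as plain loops, independent of the
# package's vectorised implementations.

identity_curve <- function(old = 14000, young = 1000, sigma = 1,
                           kind = "terrestrial") {
  sim_cal_curve(c(old, young), wiggle_amplitude = 0, noise_sd = 0,
                sigma = sigma, seed = 1, kind = kind)
}

wiggly_curve <- function(old = 14000, young = 1000, seed = 2,
                         kind = "terrestrial") {
  sim_cal_curve(c(old, young), wiggle_amplitude = 30, wiggle_period = 400,
                sigma = 12, noise_sd = 8, seed = seed, kind = kind)
}

# brute-force two-point interpolation: linear scan for the bracket
oracle_interp <- function(curve, theta) {
  xs <- rev(curve$calbp); mu <- rev(curve$c14); sd <- rev(curve$sigma)
  out_mu <- numeric(length(theta)); out_sd <- numeric(length(theta))
  for (k in seq_along(theta)) {
    i <- 1L
    while (i < length(xs) - 1L && xs[i + 1L] < theta[k]) i <- i + 1L
    w <- (theta[k] - xs[i]) / (xs[i + 1L] - xs[i])
    out_mu[k] <- (1 - w) * mu[i] + w * mu[i + 1L]
    out_sd[k] <- (1 - w) * sd[i] + w * sd[i + 1L]
  }
  list(mu = out_mu, sigma = out_sd)
}

# brute-force Riemann calibration: per-cell loop, manual normal density
oracle_calibrate <- function(c14_age, c14_sigma, curve, ages,
                             dr_mean = 0, dr_var = 0) {
  lik <- numeric(length(ages))
  for (k in seq_along(ages)) {
    ip <- oracle_interp(curve, ages[k])
    v <- c14_sigma^2 + ip$sigma^2 + dr_var
    z <- (c14_age - (ip$mu + dr_mean))
    lik[k] <- exp(-0.5 * z * z / v) / sqrt(2 * pi * v)
  }
  lik / sum(lik)
}

# threshold-scan HPD oracle: try every density value as a cut level
oracle_hpd_cells <- function(mass, level) {
  best <- NULL
  for (thr in sort(unique(mass), decreasing = TRUE)) {
    sel <- which(mass >= thr)
    if (sum(mass[sel]) >= level - 1e-12) { best <- sel; break }
  }
  best
}

# monotone age-depth baseline: isotonic fit of calibrated means vs depth,
# prediction interval from the single-date calibration sd at each depth
monotone_baseline <- function(core, curve, level = 0.95) {
  ip <- baychron:::curve_interpolator(curve)
  grid <- cal_grid(ip$hi, ip$lo, step_yr = 5)
  n <- nrow(core)
  mean_i <- numeric(n); sd_i <- numeric(n)
  for (i in seq_len(n)) {
    det <- list(c14_age = core$c14_age[i], c14_sigma = core$c14_sigma[i],
                material = "terrestrial")
    dens <- calibrate_terrestrial(det, curve, grid)
    mean_i[i] <- point_summaries(dens)$mean
    sd_i[i] <- sqrt(sum(dens$mass * (dens$ages - mean_i[i])^2))
  }
  ord <- order(core$depth_m)
  iso <- stats::isoreg(core$depth_m[ord], mean_i[ord])
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(depth_m = core$depth_m[ord], fit = iso$yf,
             lower = iso$yf - z * sd_i[ord], upper = iso$yf + z * sd_i[ord])
}

quick_mcmc <- function(seed = 1, iterations = 1500, burn_in = 500, thin = 4,
                       chains = 2) {
  mcmc_control(chains = chains, iterations = iterations, burn_in = burn_in,
               thin = thin, seed = seed)
}
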