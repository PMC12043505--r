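# Single-date calibration: posterior over a calendar-age grid, HPD sets,
# point summaries, and the agreement index used for model screening.

#' Define a calendar-age grid
#'
#' The integration grid for calibrated densities. Ages are in cal BP, so
#' the grid runs from an older start down to a younger end. The default
#' 1-yr step matches single-date reporting resolution; a 5-yr step is
#' acceptable inside MCMC summaries for speed.
#'
#' @param start_calbp Older grid limit, cal BP.
#' @param end_calbp Younger grid limit, cal BP; must be < `start_calbp`.
#' @param step_yr Grid spacing in years, >= 1.
#' @return An object of class `cal_grid` with element `ages` (decreasing).
#' @export
cal_grid <- function(start_calbp, end_calbp, step_yr = 1) {
  if (!(start_calbp > end_calbp)) {
    stop_bc("grid start must be older (larger cal BP) than end",
            "baychron_validation_error")
  }
  if (step_yr < 1) stop_bc("step_yr must be >= 1", "baychron_validation_error")
  structure(list(start_calbp = start_calbp, end_calbp = end_calbp,
                 step_yr = step_yr,
                 ages = seq(start_calbp, end_calbp, by = -step_yr)),
            class = "cal_grid")
}

new_cal_density <- function(grid, mass) {
  structure(list(grid = grid, ages = grid$ages, mass = mass),
            class = "cal_density")
}

#' @export
print.cal_density <- function(x, ...) {
  s <- point_summaries(x)
  cat(sprintf(
    "<cal_density> %d cells (%.0f-%.0f cal BP, step %g); mean %.0f, median %.0f, mode %.0f cal BP\n",
    length(x$mass), x$grid$start_calbp, x$grid$end_calbp, x$grid$step_yr,
    s$mean, s$median, s$mode))
  invisible(x)
}

#' @export
plot.cal_density <- function(x, ...) {
  graphics::plot(x$ages, x$mass, type = "h", xlim = rev(range(x$ages)),
                 xlab = "cal BP", ylab = "probability mass", ...)
  invisible(x)
}

# Shared normalised-likelihood kernel.  extra_mu / extra_var fold in a
# reservoir offset (Delta-R mean and variance) for marine samples.
calibrate_kernel <- function(c14_age, c14_sigma, curve, grid,
                             extra_mu = 0, extra_var = 0) {
  stopifnot(inherits(curve, "cal_curve"), inherits(grid, "cal_grid"))
  rng <- curve_range(curve)
  if (grid$start_calbp > rng[["oldest"]] || grid$end_calbp < rng[["youngest"]]) {
    stop_bc("grid extends beyond curve support; clip the grid", "baychron_range_error")
  }
  ip <- curve_interpolator(curve)
  mu <- ip$mu(grid$ages) + extra_mu
  sd_tot <- sqrt(c14_sigma^2 + ip$sigma(grid$ages)^2 + extra_var)
  lik <- stats::dnorm(c14_age, mean = mu, sd = sd_tot)
  tot <- sum(lik)
  if (!is.finite(tot) || tot < 1e-300) {
    stop_bc("degenerate posterior: date has no likelihood mass on this grid",
            "baychron_degenerate_error")
  }
  new_cal_density(grid, lik / tot)
}

as_determination <- function(det) {
  det <- as.list(det)
  for (f in c("c14_age", "c14_sigma")) det[[f]] <- as.numeric(det[[f]])
  if (is.na(det$c14_sigma) || det$c14_sigma <= 0) {
    stop_bc("c14_sigma must be > 0", "baychron_validation_error")
  }
  det
}

#' Calibrate a terrestrial determination
#'
#' Computes the calendar-age posterior of one radiocarbon measurement
#' x +/- sigma on a grid: density(theta) proportional to
#' Normal(x; mu_c(theta), sqrt(sigma^2 + sigma_c(theta)^2)), normalised,
#' with a uniform prior over the grid.
#'
#' @param det A single determination: one row of a [date_table] or a list
#'   with `c14_age`, `c14_sigma`, `material`.
#' @param curve A terrestrial [cal_curve].
#' @param grid A [cal_grid] inside the curve support.
#' @return A `cal_density`.
#' @export
calibrate_terrestrial <- function(det, curve, grid) {
  det <- as_determination(det)
  if (!identical(det$material, "terrestrial")) {
    stop_bc(sprintf("material mismatch: expected terrestrial, got %s (%s)",
                    det$material, det$lab_code %||% "?"),
            "baychron_material_error")
  }
  if (curve$kind != "terrestrial") {
    stop_bc("curve kind must be terrestrial", "baychron_material_error")
  }
  calibrate_kernel(det$c14_age, det$c14_sigma, curve, grid)
}

#' Calibrate a marine determination with a reservoir offset
#'
#' Marine carbon appears old; Delta-R is the local offset from the global
#' marine curve, in 14C years. The likelihood becomes
#' Normal(x; mu_c(theta) + dr_mean, sqrt(sigma^2 + sigma_c^2 + dr_sigma^2)).
#'
#' @param det A single marine determination.
#' @param curve A marine [cal_curve] (Marine20-type).
#' @param delta_r_mean Delta-R mean, 14C yr.
#' @param delta_r_sigma Delta-R one-sigma, 14C yr, >= 0.
#' @param grid A [cal_grid].
#' @return A `cal_density`.
#' @export
calibrate_marine <- function(det, curve, delta_r_mean, delta_r_sigma, grid) {
  det <- as_determination(det)
  if (!identical(det$material, "marine")) {
    stop_bc(sprintf("material mismatch: expected marine, got %s (%s)",
                    det$material, det$lab_code %||% "?"),
            "baychron_material_error")
  }
  if (curve$kind != "marine") {
    stop_bc("curve kind must be marine", "baychron_material_error")
  }
  if (delta_r_sigma < 0) {
    stop_bc("delta_r_sigma must be >= 0", "baychron_validation_error")
  }
  calibrate_kernel(det$c14_age, det$c14_sigma, curve, grid,
                   extra_mu = delta_r_mean, extra_var = delta_r_sigma^2)
}

#' Highest posterior density set of a calibrated density
#'
#' Smallest set of grid cells, by descending density, whose total mass
#' reaches `level`, merged into contiguous calendar intervals. Calibrated
#' dates are often multimodal, so the set may contain several intervals.
#'
#' @param dens A `cal_density`.
#' @param level Coverage in (0, 1].
#' @return A list of class `hpd_set`: `level`, `attained`, and `intervals`,
#'   a data.frame with columns `older`, `younger` (cal BP) and `mass`.
#' @export
hpd_intervals <- function(dens, level) {
  stopifnot(inherits(dens, "cal_density"))
  if (!(level > 0 && level <= 1)) {
    stop_bc("level must be in (0, 1]", "baychron_validation_error")
  }
  ord <- order(dens$mass, decreasing = TRUE)
  cum <- cumsum(dens$mass[ord])
  k <- which(cum >= level - 1e-12)[1L]
  if (is.na(k)) k <- length(ord)
  if (level == 1) {
    sel <- which(dens$mass > 0)
  } else {
    # include cells tied with the cut density (symmetric multimodal dates
    # produce exact ties; dropping one of a tied pair would be arbitrary)
    cut <- dens$mass[ord[k]]
    sel <- which(dens$mass >= cut)
  }
  runs <- split(sel, cumsum(c(1, diff(sel) != 1)))
  intervals <- do.call(rbind, lapply(runs, function(ix) {
    data.frame(older = dens$ages[ix[1L]],
               younger = dens$ages[ix[length(ix)]],
               mass = sum(dens$mass[ix]))
  }))
  rownames(intervals) <- NULL
  structure(list(level = level, attained = sum(dens$mass[sel]),
                 intervals = intervals),
            class = "hpd_set")
}

#' @export
print.hpd_set <- function(x, ...) {
  cat(sprintf("<hpd_set> level %.3f (attained %.3f)\n", x$level, x$attained))
  for (i in seq_len(nrow(x$intervals))) {
    cat(sprintf("  [%.0f, %.0f] cal BP (%.3f)\n", x$intervals$older[i],
                x$intervals$younger[i], x$intervals$mass[i]))
  }
  invisible(x)
}

#' Point summaries of a calibrated density
#'
#' @param dens A `cal_density`.
#' @return List with `mean`, `median` (by cumulative mass) and `mode`
#'   (argmax; ties broken toward the older age), all in cal BP.
#' @export
point_summaries <- function(dens) {
  stopifnot(inherits(dens, "cal_density"))
  m <- sum(dens$ages * dens$mass)
  cum <- cumsum(dens$mass)
  med <- dens$ages[which(cum >= 0.5)[1L]]
  mx <- max(dens$mass)
  mode <- max(dens$ages[dens$mass == mx]) # oldest among ties
  list(mean = m, median = med, mode = mode)
}

#' Agreement index between an unmodelled and a modelled density
#'
#' The OxCal-style overlap statistic
#' A = 100 * sum(p_post * p_prior) / sum(p_prior * p_prior)
#' on a shared grid; A = 100 when the model leaves a date's calibration
#' unchanged, and values below 60 flag dates in conflict with the model.
#'
#' @param unmodelled The single-date calibration (`cal_density`).
#' @param modelled The same date's posterior under the model, on the same
#'   grid.
#' @return Agreement index in percent.
#' @export
agreement_index <- function(unmodelled, modelled) {
  stopifnot(inherits(unmodelled, "cal_density"), inherits(modelled, "cal_density"))
  if (length(unmodelled$ages) != length(modelled$ages) ||
      any(unmodelled$ages != modelled$ages)) {
    stop_bc("agreement_index requires both densities on the same grid",
            "baychron_grid_error")
  }
  100 * sum(modelled$mass * unmodelled$mass) / sum(unmodelled$mass^2)
}

#' Bin posterior draws onto a calendar grid
#'
#' Turns MCMC draws of a calendar age into a `cal_density` on `grid`
#' (used for agreement indices of modelled dates).
#'
#' @param draws Numeric vector of calendar-age draws, cal BP.
#' @param grid A [cal_grid].
#' @return A `cal_density`.
#' @export
density_from_draws <- function(draws, grid) {
  stopifnot(inherits(grid, "cal_grid"))
  step <- grid$step_yr
  # cells centred on grid ages (decreasing); assign by nearest cell
  idx <- round((grid$start_calbp - draws) / step) + 1L
  idx <- idx[idx >= 1L & idx <= length(grid$ages)]
  if (!length(idx)) {
    stop_bc("no draws fall inside the grid", "baychron_degenerate_error")
  }
  mass <- tabulate(idx, nbins = length(grid$ages))
  new_cal_density(grid, mass / sum(mass))
}

#' Export a calibrated density as two-column text
#'
#' @param dens A `cal_density`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cal_density <- function(dens, path) {
  stopifnot(inherits(dens, "cal_density"))
  utils::write.table(
    data.frame(calbp = dens$ages, mass = dens$mass),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
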