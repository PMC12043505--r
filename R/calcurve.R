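# Calibration curves: construction, .14c file I/O, linear interpolation.
# A curve maps calendar age theta (cal BP) to an expected radiocarbon age
# mu_c(theta) with a one-sigma curve error sigma_c(theta), both in 14C yr.

#' Construct a calibration curve
#'
#' A calibration curve is the empirical mapping from calendar age (years
#' cal BP, before AD 1950) to conventional radiocarbon age, with a
#' per-knot one-sigma error. IntCal20 (terrestrial) and Marine20 (marine)
#' are the reference datasets; any curve in the same layout can be used.
#'
#' @param calbp Calendar ages of the knots, years cal BP; strictly monotone.
#' @param c14 Radiocarbon ages at the knots, 14C yr BP.
#' @param sigma One-sigma curve error at the knots, 14C yr; all > 0.
#' @param name Curve label, e.g. `"IntCal20"`.
#' @param kind `"terrestrial"` or `"marine"`.
#' @return An object of class `cal_curve`. Knots are stored with cal BP
#'   strictly decreasing (oldest first).
#' @export
cal_curve <- function(calbp, c14, sigma, name = "curve",
                      kind = c("terrestrial", "marine")) {
  kind <- match.arg(kind)
  calbp <- as.numeric(calbp)
  c14 <- as.numeric(c14)
  sigma <- as.numeric(sigma)
  n <- length(calbp)
  if (n < 2L || length(c14) != n || length(sigma) != n) {
    stop_bc("calibration curve needs >= 2 knots with equal-length calbp, c14 and sigma",
            "baychron_validation_error")
  }
  if (anyNA(calbp) || anyNA(c14) || anyNA(sigma) || any(!is.finite(c14))) {
    stop_bc("calibration curve knots must be finite and non-missing",
            "baychron_validation_error")
  }
  d <- diff(calbp)
  if (all(d > 0)) {
    o <- rev(seq_len(n))
    calbp <- calbp[o]; c14 <- c14[o]; sigma <- sigma[o]
  } else if (!all(d < 0)) {
    stop_bc("calibration curve cal BP knots must be strictly monotone",
            "baychron_validation_error")
  }
  if (any(sigma <= 0)) {
    stop_bc("calibration curve sigma must be > 0 at every knot",
            "baychron_validation_error")
  }
  structure(list(name = name, calbp = calbp, c14 = c14, sigma = sigma,
                 kind = kind),
            class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve> %s (%s), %d knots, %.0f-%.0f cal BP\n",
              x$name, x$kind, length(x$calbp),
              max(x$calbp), min(x$calbp)))
  invisible(x)
}

#' Calendar-age range covered by a curve
#'
#' @param curve A [cal_curve].
#' @return `c(oldest, youngest)` in cal BP.
#' @export
curve_range <- function(curve) {
  stopifnot(inherits(curve, "cal_curve"))
  c(oldest = max(curve$calbp), youngest = min(curve$calbp))
}

#' Read a calibration curve from a .14c file
#'
#' The `intcal14c` dialect is the layout of the distributed IntCal20 and
#' Marine20 files: header lines starting with `#`, then delimited records
#' (comma or whitespace) whose first three numeric columns are calendar age
#' cal BP, 14C age BP and one-sigma error; any further columns (e.g.
#' Delta-14C) are ignored.
#'
#' @param path Path to the file.
#' @param dialect File dialect; only `"intcal14c"` is supported.
#' @param name Curve label; defaults to the file name.
#' @param kind `"terrestrial"` or `"marine"`.
#' @return A [cal_curve], knots normalised to strictly decreasing cal BP.
#' @export
read_cal_curve <- function(path, dialect = "intcal14c",
                           name = NULL, kind = c("terrestrial", "marine")) {
  kind <- match.arg(kind)
  dialect <- match.arg(dialect, "intcal14c")
  if (!file.exists(path)) {
    stop_bc(sprintf("calibration curve file not found: %s", path),
            "baychron_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) < 2L) {
    stop_bc("calibration curve file has fewer than 2 data records",
            "baychron_parse_error")
  }
  rec <- matrix(NA_real_, nrow = length(idx), ncol = 3L)
  for (k in seq_along(idx)) {
    fields <- strsplit(trimws(lines[idx[k]]), "[,[:space:]]+")[[1]]
    if (length(fields) < 3L) {
      stop_bc(sprintf("line %d: expected at least 3 numeric fields", idx[k]),
              "baychron_parse_error")
    }
    v <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(v)) {
      stop_bc(sprintf("line %d: malformed numeric field", idx[k]),
              "baychron_parse_error")
    }
    rec[k, ] <- v
  }
  cal_curve(rec[, 1], rec[, 2], rec[, 3],
            name = name %||% basename(path), kind = kind)
}

#' Write a calibration curve to a .14c file
#'
#' @param curve A [cal_curve].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cal_curve <- function(curve, path) {
  stopifnot(inherits(curve, "cal_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s (%s); columns: cal BP, 14C age BP, 1-sigma error",
                     curve$name, curve$kind), con)
  writeLines(sprintf("%.8g,%.8g,%.8g", curve$calbp, curve$c14, curve$sigma),
             con)
  invisible(path)
}

#' Interpolate a calibration curve at calendar ages
#'
#' Piecewise-linear interpolation of both the curve mean and its error,
#' exact at the knots. No extrapolation: ages outside the knot range raise
#' a range error (silent extrapolation corrupts posteriors downstream).
#'
#' @param curve A [cal_curve].
#' @param theta Calendar ages, cal BP (vectorised).
#' @return A list with numeric vectors `mu` and `sigma` (14C yr).
#' @export
interpolate_curve <- function(curve, theta) {
  stopifnot(inherits(curve, "cal_curve"))
  theta <- as.numeric(theta)
  lo <- min(curve$calbp); hi <- max(curve$calbp)
  if (anyNA(theta) || any(theta < lo | theta > hi)) {
    stop_bc(sprintf(
      "calendar age outside curve support [%.1f, %.1f] cal BP (no extrapolation)",
      lo, hi), "baychron_range_error")
  }
  ip <- curve_interpolator(curve)
  list(mu = ip$mu(theta), sigma = ip$sigma(theta))
}

# Fast internal interpolator: precomputes ascending knot arrays once and
# returns closures used inside the samplers.  Ages outside support give NA.
# Regularly spaced knots (all simulated curves; segments of the reference
# curves) get an arithmetic bracket lookup, avoiding findInterval's O(m)
# sortedness re-check on every call.
curve_interpolator <- function(curve) {
  asc <- rev(curve$calbp)
  mu_asc <- rev(curve$c14)
  sd_asc <- rev(curve$sigma)
  n <- length(asc)
  h <- diff(asc)
  regular <- (max(h) - min(h)) < 1e-9 * max(h)
  x0 <- asc[1L]; h1 <- h[1L]
  locate <- if (regular) {
    function(xi) {
      i <- floor((xi - x0) / h1) + 1
      i[i < 1] <- 1
      i[i > n - 1L] <- n - 1L
      as.integer(i)
    }
  } else {
    function(xi) findInterval(xi, asc, all.inside = TRUE)
  }
  interp <- function(values) {
    force(values)
    function(x) {
      out <- rep(NA_real_, length(x))
      ok <- which(!is.na(x) & x >= asc[1L] & x <= asc[n])
      if (length(ok)) {
        xi <- x[ok]
        i <- locate(xi)
        w <- (xi - asc[i]) / (asc[i + 1L] - asc[i])
        out[ok] <- (1 - w) * values[i] + w * values[i + 1L]
      }
      out
    }
  }
  list(mu = interp(mu_asc), sigma = interp(sd_asc),
       lo = asc[1L], hi = asc[n])
}
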