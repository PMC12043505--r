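# Bayesian multi-phase chronological model.
#
# Dated events theta_i are grouped into ordered depositional phases (older
# to younger) delimited by start/end boundary parameters. Two boundary
# treatments are supported:
#   "uniform": events strictly inside [end, start]; the joint prior carries
#     the span correction p(theta, start, end) ~ prod U(theta; end, start)
#     x (R - span)^-1 over the overall range of width R, which makes the
#     prior on the phase span exactly Uniform(0, R) for any member count.
#   "sigma": a plateau on [end, start] with Gaussian tails of scale tau
#     outside, tau ~ half-Normal(tau_scale); event tails of abutting phases
#     may overlap, reflecting sedimentary fuzziness at physical boundaries.
# A general outlier model gives each date a prior probability of a
# heavy-tailed calendar-scale shift: shift_i = phi_i * t_i * 10^u_i with
# phi_i ~ Bernoulli(prior_prob), t_i ~ Student-t(t_df), u_i ~ U(range).
# Posterior sampling is Metropolis-within-Gibbs with a Gibbs flip for the
# outlier indicators and burn-in-only step adaptation.

#' Specify one depositional phase
#'
#' @param phase_id Phase label (e.g. `"V"`).
#' @param members Character vector of `lab_code`s of the determinations
#'   assigned to the phase; non-empty.
#' @param boundary_type `"sigma"` (plateau with Gaussian tails; overlap
#'   between abutting phases allowed) or `"uniform"` (hard boundaries).
#' @return An object of class `phase_spec`.
#' @export
phase_spec <- function(phase_id, members,
                       boundary_type = c("sigma", "uniform")) {
  boundary_type <- match.arg(boundary_type)
  members <- as.character(members)
  if (!length(members)) {
    stop_bc(sprintf("phase %s has no members", phase_id),
            "baychron_validation_error")
  }
  structure(list(phase_id = as.character(phase_id), members = members,
                 boundary_type = boundary_type),
            class = "phase_spec")
}

#' Specify the general outlier model
#'
#' Each date carries a prior probability of being an outlier; outliers are
#' shifted on the calendar scale by t * 10^u years with t Student-t
#' distributed and u uniform over an exponent range, so shifts from single
#' years to ten thousand years are entertained.
#'
#' @param prior_prob Prior outlier probability, default 0.05.
#' @param t_df Student-t degrees of freedom for the shift kernel, default 5.
#' @param log10_scale_range Exponent range for the shift scale, default
#'   `c(0, 4)`.
#' @return An object of class `outlier_spec`.
#' @export
outlier_spec <- function(prior_prob = 0.05, t_df = 5,
                         log10_scale_range = c(0, 4)) {
  if (!(prior_prob >= 0 && prior_prob < 1)) {
    stop_bc("prior_prob must be in [0, 1)", "baychron_validation_error")
  }
  if (t_df <= 0) stop_bc("t_df must be > 0", "baychron_validation_error")
  if (diff(log10_scale_range) <= 0) {
    stop_bc("log10_scale_range must be ordered", "baychron_validation_error")
  }
  structure(list(prior_prob = prior_prob, t_df = t_df,
                 log10_scale_range = log10_scale_range),
            class = "outlier_spec")
}

#' MCMC control settings
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iterations Total iterations per chain.
#' @param burn_in Iterations discarded (and used for step adaptation).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed RNG seed; chain c runs under seed + 1000 * c.
#' @return An object of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, iterations = 20000,
                         burn_in = floor(iterations / 2), thin = 10,
                         seed = 1) {
  if (iterations <= burn_in) {
    stop_bc("iterations must exceed burn_in", "baychron_validation_error")
  }
  if (chains < 2) stop_bc("chains must be >= 2", "baychron_validation_error")
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Build a validated phase-model specification
#'
#' Checks phase membership, attaches curves and the outlier model, and
#' fixes the overall calendar range (default: the union of the 99.9%
#' single-date calibrated supports, padded by 500 yr and clipped to curve
#' support).
#'
#' @param dates A [date_table].
#' @param phases List of [phase_spec], ordered older to younger.
#' @param curve Terrestrial [cal_curve] for terrestrial dates.
#' @param marine_curve Marine [cal_curve]; required if any member is marine.
#' @param delta_r Length-2 numeric `c(mean, sigma)` reservoir offset for
#'   marine members; required if any member is marine.
#' @param outlier An [outlier_spec], or `NULL` to disable outlier handling.
#' @param contiguous If `TRUE`, abutting phases share one boundary (K
#'   phases have K + 1 boundaries).
#' @param overall_range Optional `c(oldest, youngest)` cal BP.
#' @param tau_scale Half-normal scale (yr) of the sigma-boundary tails.
#' @return An object of class `phase_model_spec`.
#' @export
build_phase_model <- function(dates, phases, curve, marine_curve = NULL,
                              delta_r = NULL, outlier = outlier_spec(),
                              contiguous = TRUE, overall_range = NULL,
                              tau_scale = 100) {
  dates <- date_table(dates)
  if (!length(phases)) stop_bc("empty phase list", "baychron_validation_error")
  phases <- lapply(phases, function(p) {
    if (!inherits(p, "phase_spec")) stop_bc("phases must be phase_spec objects",
                                            "baychron_validation_error")
    p
  })
  all_members <- unlist(lapply(phases, `[[`, "members"))
  unknown <- setdiff(all_members, dates$lab_code)
  if (length(unknown)) {
    stop_bc(sprintf("unknown lab_code in phases: %s",
                    paste(unknown, collapse = ", ")),
            "baychron_validation_error")
  }
  if (anyDuplicated(all_members)) {
    stop_bc(sprintf("determination assigned to more than one phase: %s",
                    paste(unique(all_members[duplicated(all_members)]),
                          collapse = ", ")),
            "baychron_validation_error")
  }
  used <- dates[match(all_members, dates$lab_code), , drop = FALSE]
  is_marine <- used$material == "marine"
  if (any(is_marine)) {
    if (is.null(marine_curve) || is.null(delta_r)) {
      stop_bc("marine members require a marine_curve and a delta_r = c(mean, sigma)",
              "baychron_validation_error")
    }
    stopifnot(inherits(marine_curve, "cal_curve"))
    if (marine_curve$kind != "marine") {
      stop_bc("marine_curve must have kind marine", "baychron_material_error")
    }
  }
  stopifnot(inherits(curve, "cal_curve"))
  if (curve$kind != "terrestrial") {
    stop_bc("curve must have kind terrestrial", "baychron_material_error")
  }

  n <- nrow(used)
  phase_of <- integer(n)
  off <- 0L
  for (j in seq_along(phases)) {
    phase_of[off + seq_along(phases[[j]]$members)] <- j
    off <- off + length(phases[[j]]$members)
  }

  # curve support shared by all members
  supp <- curve_range(curve)
  if (any(is_marine)) {
    ms <- curve_range(marine_curve)
    supp <- c(oldest = min(supp[1], ms[1]), youngest = max(supp[2], ms[2]))
  }

  # single-date calibrations at 5-yr step over curve support: medians for
  # initialisation, 99.9% supports for the default overall range
  scan <- cal_grid(supp[["oldest"]], supp[["youngest"]], step_yr = 5)
  med <- numeric(n)
  lo99 <- numeric(n); hi99 <- numeric(n)
  cal_mass <- matrix(0, length(scan$ages), n)
  for (i in seq_len(n)) {
    d <- as.list(used[i, ])
    dens <- if (is_marine[i]) {
      calibrate_marine(d, marine_curve, delta_r[1], delta_r[2], scan)
    } else {
      calibrate_terrestrial(d, curve, scan)
    }
    med[i] <- point_summaries(dens)$median
    cal_mass[, i] <- dens$mass
    h <- hpd_intervals(dens, 0.999)
    hi99[i] <- max(h$intervals$older)
    lo99[i] <- min(h$intervals$younger)
  }
  if (is.null(overall_range)) {
    overall_range <- c(min(max(hi99) + 500, supp[["oldest"]]),
                       max(min(lo99) - 500, supp[["youngest"]]))
  }
  if (!(overall_range[1] > overall_range[2])) {
    stop_bc("overall_range must be c(oldest, youngest) with oldest > youngest",
            "baychron_validation_error")
  }
  if (overall_range[1] > supp[["oldest"]] || overall_range[2] < supp[["youngest"]]) {
    stop_bc("overall_range extends beyond curve support", "baychron_range_error")
  }

  structure(list(
    dates = used, phases = phases, phase_of = phase_of,
    curve = curve, marine_curve = marine_curve,
    delta_r = delta_r, outlier = outlier, contiguous = isTRUE(contiguous),
    overall_range = as.numeric(overall_range), tau_scale = tau_scale,
    init_theta = med, is_marine = is_marine,
    # single-date calibrations on the scan grid: initialisation, and the
    # independence proposal that lets event ages hop between calibration
    # modes (multimodal calibrated dates are the norm on wiggly curves)
    cal_scan = list(start = scan$start_calbp, step = scan$step_yr,
                    mass = cal_mass, cum = apply(cal_mass, 2, cumsum))
  ), class = "phase_model_spec")
}

#' @export
print.phase_model_spec <- function(x, ...) {
  cat(sprintf("<phase_model_spec> %d phases, %d dates, range %.0f-%.0f cal BP%s\n",
              length(x$phases), nrow(x$dates), x$overall_range[1],
              x$overall_range[2],
              if (x$contiguous) ", contiguous" else ""))
  invisible(x)
}

# ---- internal model workspace --------------------------------------------

phase_workspace <- function(spec) {
  n <- nrow(spec$dates)
  K <- length(spec$phases)
  ipT <- curve_interpolator(spec$curve)
  ipM <- if (!is.null(spec$marine_curve)) curve_interpolator(spec$marine_curve)
  ti <- which(!spec$is_marine)
  mi <- which(spec$is_marine)
  x <- spec$dates$c14_age
  lab_var <- spec$dates$c14_sigma^2
  dr_mean <- ifelse(spec$is_marine, spec$delta_r[1] %||% 0, 0)
  dr_var <- ifelse(spec$is_marine, (spec$delta_r[2] %||% 0)^2, 0)
  types <- vapply(spec$phases, `[[`, "", "boundary_type")
  members <- lapply(spec$phases, function(p) match(p$members, spec$dates$lab_code))
  n_mem <- lengths(members)
  R <- spec$overall_range[1] - spec$overall_range[2]

  meas_ll <- function(age_eff) {
    out <- rep(-Inf, n)
    if (length(ti)) {
      mu <- ipT$mu(age_eff[ti])
      s2 <- ipT$sigma(age_eff[ti])^2
      ok <- !is.na(mu)
      out[ti[ok]] <- stats::dnorm(x[ti][ok], mu[ok],
                                  sqrt(lab_var[ti][ok] + s2[ok]), log = TRUE)
    }
    if (length(mi)) {
      mu <- ipM$mu(age_eff[mi]) + dr_mean[mi]
      s2 <- ipM$sigma(age_eff[mi])^2 + dr_var[mi]
      ok <- !is.na(mu)
      out[mi[ok]] <- stats::dnorm(x[mi][ok], mu[ok],
                                  sqrt(lab_var[mi][ok] + s2[ok]), log = TRUE)
    }
    out
  }

  # per-event phase prior, given boundary vectors a, e and tail scales tau
  event_lp <- function(theta, a, e, tau) {
    out <- numeric(n)
    for (j in seq_len(K)) {
      th <- theta[members[[j]]]
      if (types[j] == "uniform") {
        lp <- rep.int(-log(a[j] - e[j]), length(th))
        lp[th > a[j] | th < e[j]] <- -Inf
      } else {
        norm <- -log((a[j] - e[j]) + sqrt(2 * pi) * tau[j])
        excess <- pmax(th - a[j], 0) + pmax(e[j] - th, 0)
        lp <- norm - excess^2 / (2 * tau[j]^2)
      }
      out[members[[j]]] <- lp
    }
    out
  }

  # boundary-level prior: range/order constraints, the uniform-span
  # correction, and the half-normal tau prior for sigma phases
  boundary_lp <- function(a, e, tau) {
    old <- spec$overall_range[1]; young <- spec$overall_range[2]
    if (any(a > old) || any(e < young)) return(-Inf)
    lp <- 0
    for (j in seq_len(K)) {
      span <- a[j] - e[j]
      if (types[j] == "uniform") {
        if (span <= 0 || span >= R) return(-Inf)
        lp <- lp - log(R - span)
      } else {
        if (span < 0) return(-Inf)
        if (is.na(tau[j]) || tau[j] <= 0) return(-Inf)
        lp <- lp + stats::dnorm(tau[j], 0, spec$tau_scale, log = TRUE) + log(2)
      }
    }
    if (K > 1L) {
      for (j in seq_len(K - 1L)) {
        if (a[j] < a[j + 1L] || e[j] < e[j + 1L]) return(-Inf)
        overlap_ok <- types[j] == "sigma" && types[j + 1L] == "sigma"
        if (spec$contiguous) {
          if (e[j] != a[j + 1L]) return(-Inf)
        } else if (!overlap_ok && e[j] < a[j + 1L]) {
          return(-Inf)
        }
      }
    }
    lp
  }

  outlier_lp <- function(phi, t, u) {
    o <- spec$outlier
    if (is.null(o)) return(0)
    lo <- o$log10_scale_range[1]; hi <- o$log10_scale_range[2]
    if (any(u < lo | u > hi)) return(-Inf)
    sum(ifelse(phi == 1, log(o$prior_prob), log1p(-o$prior_prob))) +
      sum(stats::dt(t, df = o$t_df, log = TRUE)) -
      length(u) * log(hi - lo)
  }

  list(n = n, K = K, x = x, types = types, members = members, n_mem = n_mem,
       R = R, meas_ll = meas_ll, event_lp = event_lp,
       boundary_lp = boundary_lp, outlier_lp = outlier_lp)
}

#' Log posterior density of a phase-model state
#'
#' Returns `-Inf` (never an error) for states outside the support. The
#' state is a list with elements `theta` (event ages, in date order of the
#' spec), `start` and `end` (per-phase boundaries, cal BP; for contiguous
#' models `end[j]` must equal `start[j+1]`), `tau` (tail scales, `NA` for
#' uniform phases), and — when the outlier model is enabled — `phi`
#' (0/1 indicators), `t` and `u` (shift components).
#'
#' @param state State list as described above.
#' @param spec A [build_phase_model] result.
#' @return Log posterior density (unnormalised).
#' @export
phase_log_posterior <- function(state, spec) {
  stopifnot(inherits(spec, "phase_model_spec"))
  ws <- phase_workspace(spec)
  n <- ws$n; K <- ws$K
  theta <- as.numeric(state$theta)
  a <- as.numeric(state$start); e <- as.numeric(state$end)
  tau <- as.numeric(state$tau %||% rep(NA_real_, K))
  stopifnot(length(theta) == n, length(a) == K, length(e) == K)
  if (!is.null(spec$outlier)) {
    phi <- as.numeric(state$phi %||% rep(0, n))
    t <- as.numeric(state$t %||% rep(0, n))
    u <- as.numeric(state$u %||% rep(spec$outlier$log10_scale_range[1], n))
    shift <- phi * t * 10^u
  } else {
    phi <- rep(0, n); t <- rep(0, n); u <- rep(0, n); shift <- rep(0, n)
  }
  blp <- ws$boundary_lp(a, e, tau)
  if (!is.finite(blp)) return(-Inf)
  total <- blp + sum(ws$meas_ll(theta + shift)) +
    sum(ws$event_lp(theta, a, e, tau))
  if (!is.null(spec$outlier)) total <- total + ws$outlier_lp(phi, t, u)
  if (is.nan(total)) -Inf else total
}

# ---- sampler --------------------------------------------------------------

# One chain of Metropolis-within-Gibbs. Returns retained draws.
phase_chain <- function(spec, ws, ctl, chain_seed, prior_only = FALSE,
                        fixed = NULL) {
  set.seed(as.integer(chain_seed %% .Machine$integer.max))
  n <- ws$n; K <- ws$K
  old <- spec$overall_range[1]; young <- spec$overall_range[2]
  o <- spec$outlier
  use_outlier <- !is.null(o) && !prior_only

  meas_of <- if (prior_only) function(age_eff) numeric(n) else ws$meas_ll
  event_lp <- ws$event_lp
  if (!is.null(o)) {
    lpo <- log(o$prior_prob) - log1p(-o$prior_prob)
    u_lo <- o$log10_scale_range[1]; u_hi <- o$log10_scale_range[2]
    t_df <- o$t_df
  }

  # --- initialisation: single-date medians, boundaries at member extremes
  init_state <- function(attempt) {
    theta <- pmin(pmax(spec$init_theta, young + 1), old - 1)
    if (attempt > 1L) theta <- theta + stats::rnorm(n, 0, 20 * attempt)
    theta <- pmin(pmax(theta, young + 1), old - 1)
    a <- numeric(K); e <- numeric(K)
    for (j in seq_len(K)) {
      th <- theta[ws$members[[j]]]
      a[j] <- min(max(th) + 50, old)
      e[j] <- max(min(th) - 50, young)
    }
    if (spec$contiguous && K > 1L) {
      b <- c(a[1], (a[-1] + e[-K]) / 2, e[K])
      b <- sort(b, decreasing = TRUE)
      a <- b[seq_len(K)]; e <- b[seq_len(K) + 1L]
    }
    if (!is.null(fixed)) {
      if (spec$contiguous) {
        b <- c(a, e[K])
        b[fixed$idx] <- fixed$val
        a <- b[seq_len(K)]; e <- b[seq_len(K) + 1L]
      } else {
        b <- as.numeric(rbind(a, e))
        b[fixed$idx] <- fixed$val
        m <- matrix(b, nrow = 2L)
        a <- m[1, ]; e <- m[2, ]
      }
      # pinned boundaries may no longer bracket the init ages: clip inside
      for (j in seq_len(K)) {
        mem <- ws$members[[j]]
        theta[mem] <- pmin(pmax(theta[mem], e[j] + 1), a[j] - 1)
      }
    }
    tau <- ifelse(ws$types == "sigma", spec$tau_scale / 2, NA_real_)
    list(theta = theta, a = a, e = e, tau = tau)
  }

  st <- NULL
  for (attempt in seq_len(1000L)) {
    cand <- init_state(attempt)
    blp <- ws$boundary_lp(cand$a, cand$e, cand$tau)
    elp <- ws$event_lp(cand$theta, cand$a, cand$e, cand$tau)
    mll <- meas_of(cand$theta)
    if (is.finite(blp) && all(is.finite(elp)) && all(is.finite(mll))) {
      st <- cand; break
    }
  }
  if (is.null(st)) {
    stop_bc("could not find a finite initial state after 1000 attempts",
            "baychron_init_error")
  }
  theta <- st$theta; a <- st$a; e <- st$e; tau <- st$tau
  phi <- rep(0, n); tshift <- rep(0, n)
  p1_cur <- rep(if (!is.null(o)) o$prior_prob else 0, n)
  if (use_outlier) {
    t_par <- stats::rt(n, df = t_df)
    u_par <- stats::runif(n, u_lo, u_hi)
  } else {
    t_par <- rep(0, n); u_par <- rep(0, n)
  }

  ll_meas <- meas_of(theta + tshift)
  lp_event <- ws$event_lp(theta, a, e, tau)
  lp_bound <- ws$boundary_lp(a, e, tau)

  # boundary parameter vector: contiguous -> K+1 shared values,
  # otherwise interleaved (a1, e1, a2, e2, ...)
  nb <- if (spec$contiguous) K + 1L else 2L * K
  get_bvec <- function() if (spec$contiguous) c(a, e[K]) else
    as.numeric(rbind(a, e))
  set_bvec <- function(b) {
    if (spec$contiguous) {
      list(a = b[seq_len(K)], e = b[seq_len(K) + 1L])
    } else {
      m <- matrix(b, nrow = 2L)
      list(a = m[1, ], e = m[2, ])
    }
  }

  # metadata for the independence proposals: boundaries that are the
  # exclusive edge of a single uniform phase (shared contiguous interior
  # boundaries keep the random walk: their conditional mixes two phases)
  binfo <- vector("list", nb)
  if (spec$contiguous) {
    if (ws$types[1L] == "uniform") binfo[[1L]] <- list(phase = 1L, role = "start")
    if (ws$types[K] == "uniform") binfo[[K + 1L]] <- list(phase = K, role = "end")
  } else {
    for (j in seq_len(K)) {
      if (ws$types[j] == "uniform") {
        binfo[[2L * j - 1L]] <- list(phase = j, role = "start")
        binfo[[2L * j]] <- list(phase = j, role = "end")
      }
    }
  }

  # adaptive step scales, frozen at end of burn-in
  s_theta <- rep(50, n); s_b <- rep(50, nb)
  s_tau <- rep(0.4, K); s_t <- rep(0.8, n); s_u <- rep(0.4, n)
  acc_theta <- numeric(n); acc_b <- numeric(nb); try_b <- numeric(nb)
  acc_tau <- numeric(K); acc_tu <- numeric(n)
  batch <- 50L

  keep_iters <- seq(ctl$burn_in + ctl$thin, ctl$iterations, by = ctl$thin)
  n_keep <- length(keep_iters)
  out_b <- matrix(NA_real_, n_keep, nb)
  out_theta <- matrix(NA_real_, n_keep, n)
  out_phi <- matrix(0, n_keep, n)
  out_tau <- matrix(NA_real_, n_keep, K)
  krow <- 0L

  # independence-proposal machinery: sample from / evaluate the stored
  # single-date calibrations (piecewise-constant over the scan grid)
  cs <- spec$cal_scan
  ng <- nrow(cs$mass)
  cal_logq <- function(th) {
    cell <- floor((cs$start - th) / cs$step) + 1
    out <- rep(-Inf, n)
    ok <- which(cell >= 1 & cell <= ng)
    if (length(ok)) {
      m <- cs$mass[cbind(cell[ok], ok)]
      vals <- rep(-Inf, length(ok))
      vals[m > 0] <- log(m[m > 0])
      out[ok] <- vals
    }
    out
  }
  cal_draw <- function() {
    u <- stats::runif(n)
    cells <- vapply(seq_len(n), function(i) {
      findInterval(u[i], cs$cum[, i]) + 1L
    }, 0L)
    cells <- pmin(cells, ng)
    cs$start - (cells - 1L) * cs$step + stats::runif(n, -cs$step / 2,
                                                     cs$step / 2)
  }

  for (iter in seq_len(ctl$iterations)) {
    ## 1. event ages: random walk, with periodic independence proposals
    ## from the single-date calibrations (mode-hopping; MH-corrected)
    indep_theta <- !prior_only && iter %% 5L == 0L
    if (indep_theta) {
      prop <- cal_draw()
      prop_meas <- meas_of(prop + tshift)
      prop_event <- event_lp(prop, a, e, tau)
      logr <- (prop_meas + prop_event) - (ll_meas + lp_event) +
        cal_logq(theta) - cal_logq(prop)
    } else {
      prop <- theta + stats::rnorm(n) * s_theta
      prop_meas <- meas_of(prop + tshift)
      prop_event <- event_lp(prop, a, e, tau)
      logr <- (prop_meas + prop_event) - (ll_meas + lp_event)
    }
    logr[is.nan(logr)] <- -Inf
    acc <- log(stats::runif(n)) < logr
    if (any(acc)) {
      theta[acc] <- prop[acc]
      ll_meas[acc] <- prop_meas[acc]
      lp_event[acc] <- prop_event[acc]
      if (!indep_theta) acc_theta[acc] <- acc_theta[acc] + 1
    }

    ## 2. boundaries (one at a time). Uniform-phase edges alternate a
    ## random walk with an independence draw from the power-law shape of
    ## their full conditional (q(s) propto s^-n): a random walk alone
    ## cannot track the rapid span collapse when an outlier flag switches
    ## on, which traps chains in a widened-phase mode.
    bvec <- get_bvec()
    for (k in seq_len(nb)) {
      if (!is.null(fixed) && k %in% fixed$idx) next
      cand <- bvec
      qcorr <- 0
      info <- binfo[[k]]
      indep <- !is.null(info) && stats::runif(1) < 0.5
      if (indep) {
        j <- info$phase
        th_j <- theta[ws$members[[j]]]
        nj <- ws$n_mem[j]
        if (info$role == "start") {
          lower <- max(th_j)
          upper <- old
          if (!spec$contiguous && j > 1L) {
            upper <- min(upper, a[j - 1L])
            if (!(ws$types[j - 1L] == "sigma" && ws$types[j] == "sigma")) {
              upper <- min(upper, e[j - 1L])
            }
          }
          s_min <- lower - e[j]; s_max <- upper - e[j]
          if (s_max > s_min && s_min > 0) {
            s_new <- draw_powerlaw_span(nj, s_min, s_max)
            cand[k] <- e[j] + s_new
            qcorr <- nj * (log(s_new) - log(a[j] - e[j]))
          } else indep <- FALSE
        } else {
          upper <- min(th_j)
          lower <- young
          if (!spec$contiguous && j < K) {
            lower <- max(lower, e[j + 1L])
            if (!(ws$types[j] == "sigma" && ws$types[j + 1L] == "sigma")) {
              lower <- max(lower, a[j + 1L])
            }
          }
          s_min <- a[j] - upper; s_max <- a[j] - lower
          if (s_max > s_min && s_min > 0) {
            s_new <- draw_powerlaw_span(nj, s_min, s_max)
            cand[k] <- a[j] - s_new
            qcorr <- nj * (log(s_new) - log(a[j] - e[j]))
          } else indep <- FALSE
        }
      }
      if (!indep) {
        step <- if (stats::runif(1) < 0.1) 8 * s_b[k] else s_b[k]
        cand[k] <- bvec[k] + stats::rnorm(1) * step
        qcorr <- 0
        try_b[k] <- try_b[k] + 1
      }
      be <- set_bvec(cand)
      new_bound <- ws$boundary_lp(be$a, be$e, tau)
      if (is.finite(new_bound)) {
        new_event <- ws$event_lp(theta, be$a, be$e, tau)
        logr <- new_bound + sum(new_event) - (lp_bound + sum(lp_event)) + qcorr
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          bvec <- cand; a <- be$a; e <- be$e
          lp_bound <- new_bound; lp_event <- new_event
          if (!indep) acc_b[k] <- acc_b[k] + 1
        }
      }
    }

    ## 3. sigma-phase tail scales (log random walk)
    for (j in which(ws$types == "sigma")) {
      cand_tau <- tau
      cand_tau[j] <- tau[j] * exp(stats::rnorm(1) * s_tau[j])
      new_bound <- ws$boundary_lp(a, e, cand_tau)
      if (is.finite(new_bound)) {
        new_event <- ws$event_lp(theta, a, e, cand_tau)
        logr <- new_bound + sum(new_event) - (lp_bound + sum(lp_event)) +
          log(cand_tau[j]) - log(tau[j])
        if (is.finite(logr) && log(stats::runif(1)) < logr) {
          tau <- cand_tau; lp_bound <- new_bound; lp_event <- new_event
          acc_tau[j] <- acc_tau[j] + 1
        }
      }
    }

    ## 4. outlier machinery
    if (use_outlier) {
      idx0 <- which(phi == 0); idx1 <- which(phi == 1)
      # shift components of non-outliers: direct prior refresh
      if (length(idx0)) {
        t_par[idx0] <- stats::rt(length(idx0), df = t_df)
        u_par[idx0] <- stats::runif(length(idx0), u_lo, u_hi)
      }
      # shift components of current outliers: joint (t, u) random walk
      if (length(idx1)) {
        tp <- t_par; up <- u_par
        tp[idx1] <- t_par[idx1] + stats::rnorm(length(idx1)) * s_t[idx1]
        up[idx1] <- u_par[idx1] + stats::rnorm(length(idx1)) * s_u[idx1]
        ok <- up[idx1] >= u_lo & up[idx1] <= u_hi
        prop_shift <- tshift
        prop_shift[idx1] <- tp[idx1] * 10^up[idx1]
        prop_meas <- meas_of(theta + prop_shift)
        logr <- (prop_meas[idx1] - ll_meas[idx1]) +
          stats::dt(tp[idx1], df = t_df, log = TRUE) -
          stats::dt(t_par[idx1], df = t_df, log = TRUE)
        logr[!ok] <- -Inf
        accp <- log(stats::runif(length(idx1))) < logr
        w <- idx1[accp]
        if (length(w)) {
          t_par[w] <- tp[w]; u_par[w] <- up[w]
          tshift[w] <- prop_shift[w]; ll_meas[w] <- prop_meas[w]
          acc_tu[w] <- acc_tu[w] + 1
        }
      }
      # Gibbs flip of the indicators from the full conditional; the
      # current-state term is already cached, so one evaluation suffices
      shift_on <- t_par * 10^u_par
      l_other <- meas_of(theta + (1 - phi) * shift_on)
      on1 <- phi == 1
      l_on <- l_other; l_on[on1] <- ll_meas[on1]
      l_off <- ll_meas; l_off[on1] <- l_other[on1]
      log_odds <- lpo + l_on - l_off
      log_odds[is.nan(log_odds)] <- 0
      p1 <- 1 / (1 + exp(-log_odds))
      p1[l_on == -Inf & l_off == -Inf] <- o$prior_prob
      p1_cur <- p1 # Rao-Blackwellised outlier probability for recording
      phi <- as.numeric(stats::runif(n) < p1)
      tshift <- phi * shift_on
      on1 <- phi == 1
      ll_meas <- l_off; ll_meas[on1] <- l_on[on1]

      # measurement-preserving switch: flip phi while translating theta by
      # the shift, so theta + shift (and the measurement term) is invariant.
      # Without it the chain cannot leave the mode where a phase has
      # widened to absorb a shifted date at face value.  Acceptance ratio
      # reduces to the prior odds times the phase-prior ratio at the
      # translated event age.  Repeated a few times per sweep: the move is
      # likelihood-free and the productive shift draws are rare.
      for (rep_sw in 1:3) {
      t_new <- stats::rt(n, df = t_df)
      u_new <- stats::runif(n, u_lo, u_hi)
      s_new <- t_new * 10^u_new
      # phi = 0: translate by the proposed shift; phi = 1: undo the shift
      theta_sw <- theta - (1 - phi) * s_new + tshift
      lp_sw <- event_lp(theta_sw, a, e, tau)
      logr <- (1 - 2 * phi) * lpo + lp_sw - lp_event
      acc_sw <- log(stats::runif(n)) < logr
      if (any(acc_sw)) {
        w <- which(acc_sw)
        theta[w] <- theta_sw[w]
        lp_event[w] <- lp_sw[w]
        phi[w] <- 1 - phi[w]
        # refresh (t, u) from the prior in both directions (required for
        # detailed balance: the proposal densities then cancel exactly)
        t_par[w] <- t_new[w]
        u_par[w] <- u_new[w]
        tshift[w] <- phi[w] * t_par[w] * 10^u_par[w]
        # measurement term unchanged by construction
      }
      }
    }

    ## adaptation during burn-in only
    if (iter <= ctl$burn_in && iter %% batch == 0L) {
      gain <- 0.6
      rw_batch <- if (prior_only) batch else batch - batch %/% 5L
      s_theta <- s_theta * exp(gain * (acc_theta / rw_batch - 0.44))
      s_b <- s_b * exp(gain * (acc_b / pmax(try_b, 1) - 0.44))
      s_tau <- s_tau * exp(gain * (acc_tau / batch - 0.44))
      s_t <- s_t * exp(gain * (acc_tu / batch - 0.44))
      s_u <- s_u * exp(gain * (acc_tu / batch - 0.44))
      acc_theta[] <- 0; acc_b[] <- 0; try_b[] <- 0; acc_tau[] <- 0
      acc_tu[] <- 0
    }

    if (iter > ctl$burn_in && (iter - ctl$burn_in) %% ctl$thin == 0L) {
      krow <- krow + 1L
      out_b[krow, ] <- get_bvec()
      out_theta[krow, ] <- theta
      # record the Gibbs full-conditional probability rather than the 0/1
      # indicator: same expectation under stationarity, far less variance
      out_phi[krow, ] <- if (use_outlier) p1_cur else phi
      out_tau[krow, ] <- tau
    }
  }

  list(boundaries = out_b, theta = out_theta, phi = out_phi, tau = out_tau)
}

# Draw a span s from q(s) propto s^(-n) on [s_min, s_max] by inverse CDF,
# computed in log space (s_min^(1-n) overflows for tight spans and large n).
# This is the exact shape of a uniform phase's boundary full conditional up
# to the (R - s)^-1 factor, which the MH step corrects.
draw_powerlaw_span <- function(n, s_min, s_max) {
  u <- stats::runif(1)
  if (n == 1) {
    return(exp(log(s_min) + u * (log(s_max) - log(s_min))))
  }
  p <- 1 - n # negative for n > 1
  t1 <- p * log(s_min); t2 <- p * log(s_max) # t1 > t2
  logv <- t1 + log(u + (1 - u) * exp(t2 - t1))
  exp(logv / p)
}

boundary_names <- function(spec) {
  ids <- vapply(spec$phases, `[[`, "", "phase_id")
  K <- length(ids)
  if (spec$contiguous) {
    c(paste0("start_", ids), paste0("end_", ids[K]))
  } else {
    as.character(rbind(paste0("start_", ids), paste0("end_", ids)))
  }
}

#' Sample the phase-model posterior
#'
#' Metropolis-within-Gibbs: random-walk updates for event ages, boundaries
#' and tail scales; prior refresh plus random-walk for outlier shifts; a
#' Gibbs flip for outlier indicators. Step scales adapt during burn-in
#' only, so a fixed seed yields bit-identical draws. Split R-hat and
#' effective sample size are recorded for every boundary; R-hat above 1.05
#' flags the result (no exception).
#'
#' @param spec A [build_phase_model] result.
#' @param mcmc An [mcmc_control].
#' @param fixed_boundaries Optional named numeric vector pinning boundaries
#'   at known values (names as in the boundary summaries, e.g.
#'   `c(start_A = 9000)`); pinned boundaries are held fixed during
#'   sampling — useful for terminus constraints and for checking that a
#'   single wide pinned phase leaves single-date calibrations untouched.
#' @return An object of class `phase_model_fit` with elements
#'   `boundary_samples` (draws x boundaries), `event_samples`,
#'   `outlier_prob`, `agreement`, `diagnostics`, `flagged`, `seed`.
#' @export
sample_posterior <- function(spec, mcmc = mcmc_control(),
                             fixed_boundaries = NULL) {
  stopifnot(inherits(spec, "phase_model_spec"), inherits(mcmc, "mcmc_control"))
  ws <- phase_workspace(spec)
  fixed <- NULL
  if (!is.null(fixed_boundaries)) {
    bn_all <- boundary_names(spec)
    idx <- match(names(fixed_boundaries), bn_all)
    if (anyNA(idx)) {
      stop_bc(sprintf("unknown boundary name(s): %s",
                      paste(names(fixed_boundaries)[is.na(idx)],
                            collapse = ", ")),
              "baychron_validation_error")
    }
    fixed <- list(idx = idx, val = as.numeric(fixed_boundaries))
  }
  chains <- lapply(seq_len(mcmc$chains), function(c) {
    phase_chain(spec, ws, mcmc, chain_seed = mcmc$seed + 1000L * c,
                fixed = fixed)
  })
  bn <- boundary_names(spec)
  nb <- ncol(chains[[1]]$boundaries)
  n_keep <- nrow(chains[[1]]$boundaries)

  boundary_samples <- do.call(rbind, lapply(chains, `[[`, "boundaries"))
  colnames(boundary_samples) <- bn
  event_samples <- do.call(rbind, lapply(chains, `[[`, "theta"))
  colnames(event_samples) <- spec$dates$lab_code
  phi_all <- do.call(rbind, lapply(chains, `[[`, "phi"))

  diag <- data.frame(
    boundary = bn,
    rhat = vapply(seq_len(nb), function(k) {
      split_rhat(sapply(chains, function(ch) ch$boundaries[, k]))
    }, 0),
    ess = vapply(seq_len(nb), function(k) {
      ess_draws(sapply(chains, function(ch) ch$boundaries[, k]))
    }, 0))

  # agreement indices: unmodelled single-date calibration vs binned
  # modelled event posterior, shared 5-yr grid over the overall range
  grid <- cal_grid(spec$overall_range[1], spec$overall_range[2], step_yr = 5)
  agreement <- numeric(ws$n)
  for (i in seq_len(ws$n)) {
    d <- as.list(spec$dates[i, ])
    unmod <- if (spec$is_marine[i]) {
      calibrate_marine(d, spec$marine_curve, spec$delta_r[1], spec$delta_r[2],
                       grid)
    } else {
      calibrate_terrestrial(d, spec$curve, grid)
    }
    modelled <- density_from_draws(event_samples[, i], grid)
    agreement[i] <- agreement_index(unmod, modelled)
  }

  structure(list(
    spec = spec,
    boundary_samples = boundary_samples,
    event_samples = event_samples,
    outlier_prob = if (!is.null(spec$outlier))
      stats::setNames(colMeans(phi_all), spec$dates$lab_code),
    agreement = stats::setNames(agreement, spec$dates$lab_code),
    diagnostics = diag,
    flagged = any(diag$rhat > 1.05, na.rm = TRUE),
    n_draws = nrow(boundary_samples),
    chains = mcmc$chains,
    seed = mcmc$seed
  ), class = "phase_model_fit")
}

#' Fit a Bayesian phase model
#'
#' One-call interface: builds the model specification
#' ([build_phase_model]) and samples its posterior ([sample_posterior]).
#'
#' @inheritParams build_phase_model
#' @param mcmc An [mcmc_control].
#' @return A `phase_model_fit`.
#' @export
#' @examples
#' curve <- sim_cal_curve(c(12000, 1000), wiggle_amplitude = 0,
#'                        noise_sd = 0, sigma = 8, seed = 1)
#' site <- sim_phased_site(site_sim_config(
#'   phase_truths = list(c(8500, 7500)), dates_per_phase = 8,
#'   lab_sigma = 40, seed = 7), curve)
#' fit <- phase_model(site$dates,
#'   list(phase_spec("A", site$dates$lab_code, "uniform")),
#'   curve, outlier = NULL,
#'   mcmc = mcmc_control(chains = 2, iterations = 1200, burn_in = 400,
#'                       thin = 4, seed = 1))
#' coef(fit)
phase_model <- function(dates, phases, curve, marine_curve = NULL,
                        delta_r = NULL, outlier = outlier_spec(),
                        contiguous = TRUE, overall_range = NULL,
                        tau_scale = 100, mcmc = mcmc_control()) {
  spec <- build_phase_model(dates, phases, curve, marine_curve, delta_r,
                            outlier, contiguous, overall_range, tau_scale)
  sample_posterior(spec, mcmc)
}

#' @export
print.phase_model_fit <- function(x, ...) {
  cat(sprintf("Bayesian phase model: %d phases, %d dates, %d draws (%d chains)\n",
              length(x$spec$phases), nrow(x$spec$dates), x$n_draws, x$chains))
  est <- boundary_estimates(x)
  cat("Boundaries (cal BP):\n")
  print(est[, c("boundary", "mean", "median", "ka")], row.names = FALSE)
  if (x$flagged) cat("WARNING: R-hat > 1.05 on at least one boundary\n")
  invisible(x)
}

#' @export
summary.phase_model_fit <- function(object, levels = c(0.68, 0.95), ...) {
  out <- list(boundaries = boundary_estimates(object, levels),
              diagnostics = object$diagnostics,
              outliers = if (!is.null(object$spec$outlier))
                outlier_report(object),
              flagged = object$flagged)
  class(out) <- "summary.phase_model_fit"
  out
}

#' @export
print.summary.phase_model_fit <- function(x, ...) {
  cat("Boundary estimates:\n"); print(x$boundaries, row.names = FALSE)
  cat("\nDiagnostics:\n"); print(x$diagnostics, row.names = FALSE)
  if (!is.null(x$outliers)) {
    cat("\nOutlier report:\n"); print(x$outliers, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.phase_model_fit <- function(object, ...) {
  colMeans(object$boundary_samples)
}

#' @export
plot.phase_model_fit <- function(x, ...) {
  bs <- x$boundary_samples
  dens <- apply(bs, 2, stats::density)
  xr <- rev(range(bs)); yr <- c(0, max(vapply(dens, function(d) max(d$y), 0)))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = "cal BP",
                 ylab = "posterior density", ...)
  for (k in seq_along(dens)) graphics::lines(dens[[k]], col = k)
  graphics::legend("topright", colnames(bs), col = seq_along(dens), lty = 1,
                   cex = 0.7)
  invisible(x)
}

#' Posterior summaries of phase boundaries
#'
#' @param result A `phase_model_fit`.
#' @param levels HPD coverage levels.
#' @return Data frame with one row per boundary: mean, median, `ka`
#'   (display rounding to 0.1 ka) and HPD limits per level (cal BP).
#' @export
boundary_estimates <- function(result, levels = c(0.68, 0.95)) {
  stopifnot(inherits(result, "phase_model_fit"))
  bs <- result$boundary_samples
  if (!nrow(bs)) stop_bc("no posterior samples", "baychron_validation_error")
  out <- data.frame(boundary = colnames(bs),
                    mean = colMeans(bs),
                    median = apply(bs, 2, stats::median))
  out$ka <- as_ka(out$mean)
  for (lv in levels) {
    h <- apply(bs, 2, hpd_from_draws, level = lv)
    out[[sprintf("hpd%d_older", round(lv * 100))]] <- h["upper", ]
    out[[sprintf("hpd%d_younger", round(lv * 100))]] <- h["lower", ]
  }
  rownames(out) <- NULL
  out
}

#' Per-sample outlier probabilities and agreement indices
#'
#' @param result A `phase_model_fit` fitted with the outlier model enabled.
#' @return Data frame: `lab_code`, `p_outlier` (posterior mean of the
#'   indicator), `agreement` (A-index, percent).
#' @export
outlier_report <- function(result) {
  stopifnot(inherits(result, "phase_model_fit"))
  if (is.null(result$spec$outlier)) {
    stop_bc("outlier model was disabled in this fit", "baychron_unsupported_error")
  }
  data.frame(lab_code = result$spec$dates$lab_code,
             p_outlier = as.numeric(result$outlier_prob),
             agreement = as.numeric(result$agreement))
}

#' Prior-predictive spans of uniform phases
#'
#' Samples boundaries and events from the prior alone (measurement terms
#' switched off) with the same Metropolis-within-Gibbs machinery, and
#' returns the sampled span (start - end) per phase. Under the span
#' correction used here the span prior is Uniform(0, R) for every phase
#' regardless of member count.
#'
#' @param spec A [build_phase_model] result with uniform boundaries.
#' @param draws Number of retained draws.
#' @param seed RNG seed.
#' @return Matrix (draws x phases) of spans in years.
#' @export
prior_predictive_span <- function(spec, draws = 10000, seed = 1) {
  stopifnot(inherits(spec, "phase_model_spec"))
  if (!all(vapply(spec$phases, `[[`, "", "boundary_type") == "uniform")) {
    stop_bc("prior_predictive_span requires uniform boundaries",
            "baychron_unsupported_error")
  }
  ws <- phase_workspace(spec)
  thin <- 20L
  burn <- 2000L
  ctl <- mcmc_control(chains = 2, iterations = burn + draws * thin,
                      burn_in = burn, thin = thin, seed = seed)
  ch <- phase_chain(spec, ws, ctl, chain_seed = seed, prior_only = TRUE)
  K <- ws$K
  if (spec$contiguous) {
    a <- ch$boundaries[, seq_len(K), drop = FALSE]
    e <- ch$boundaries[, seq_len(K) + 1L, drop = FALSE]
  } else {
    a <- ch$boundaries[, 2L * seq_len(K) - 1L, drop = FALSE]
    e <- ch$boundaries[, 2L * seq_len(K), drop = FALSE]
  }
  span <- a - e
  colnames(span) <- vapply(spec$phases, `[[`, "", "phase_id")
  span
}
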