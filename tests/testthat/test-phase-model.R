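# Phase-model construction, log posterior, sampler contracts.

site_fixture <- function(n = 12, span = c(8500, 7500), seed = 11,
                         curve = identity_curve()) {
  sim_phased_site(site_sim_config(list(span), n, lab_sigma = 40, seed = seed),
                  curve)
}

test_that("model building validates membership and counts boundaries", {
  curve <- identity_curve()
  df <- data.frame(lab_code = sprintf("L%02d", 1:33),
                   c14_age = round(seq(7700, 7000, length.out = 33)),
                   c14_sigma = 30, material = "terrestrial")
  phases <- list(phase_spec("V", df$lab_code[1:11]),
                 phase_spec("IV", df$lab_code[12:22]),
                 phase_spec("III", df$lab_code[23:33]))
  spec <- build_phase_model(date_table(df), phases, curve, outlier = NULL,
                            contiguous = TRUE)
  # 3 contiguous phases share interior boundaries: 4 in total
  expect_length(baychron:::boundary_names(spec), 4L)

  dup <- list(phase_spec("V", df$lab_code[1:11]),
              phase_spec("IV", df$lab_code[11:22]))
  expect_error(build_phase_model(date_table(df), dup, curve),
               "more than one phase", class = "baychron_validation_error")
  expect_error(build_phase_model(date_table(df), list(), curve),
               class = "baychron_validation_error")
  expect_error(phase_spec("X", character()), class = "baychron_validation_error")
  expect_error(build_phase_model(
    date_table(df), list(phase_spec("V", c("L01", "NOPE"))), curve),
    "NOPE", class = "baychron_validation_error")

  mar <- df; mar$material[1] <- "marine"
  expect_error(build_phase_model(date_table(mar),
                                 list(phase_spec("V", df$lab_code[1:11])),
                                 curve),
               "delta_r", class = "baychron_validation_error")
})

test_that("log posterior matches single-date calibration up to a constant", {
  curve <- wiggly_curve(9200, 6800, seed = 4)
  df <- data.frame(lab_code = "L1", c14_age = 7900, c14_sigma = 45,
                   material = "terrestrial")
  spec <- build_phase_model(date_table(df),
                            list(phase_spec("A", "L1", "uniform")), curve,
                            outlier = NULL,
                            overall_range = c(9100, 6900))
  grid <- cal_grid(8500, 7300, 10)
  dens <- calibrate_terrestrial(as.list(df[1, ]), curve, grid)
  lp <- vapply(seq_along(grid$ages), function(k) {
    phase_log_posterior(list(theta = grid$ages[k],
                             start = 9000, end = 7000,
                             tau = NA_real_),
                        spec)
  }, 0)
  want <- log(dens$mass[match(grid$ages, dens$ages)])
  expect_lt(max(abs((lp - lp[1]) - (want - want[1]))), 1e-9)
})

test_that("states outside the support give -Inf, never an error", {
  curve <- identity_curve()
  df <- data.frame(lab_code = "L1", c14_age = 8000, c14_sigma = 40,
                   material = "terrestrial")
  spec <- build_phase_model(date_table(df),
                            list(phase_spec("A", "L1", "uniform")), curve,
                            outlier = NULL, overall_range = c(9000, 7000))
  # event outside the uniform phase
  expect_identical(phase_log_posterior(
    list(theta = 8600, start = 8500, end = 7500, tau = NA_real_), spec), -Inf)
  # boundaries out of order
  expect_identical(phase_log_posterior(
    list(theta = 8000, start = 7500, end = 8500, tau = NA_real_), spec), -Inf)
  # boundary beyond the overall range
  expect_identical(phase_log_posterior(
    list(theta = 8000, start = 9500, end = 7500, tau = NA_real_), spec), -Inf)
})

test_that("widening a uniform span at fixed events lowers the density", {
  curve <- identity_curve()
  df <- data.frame(lab_code = sprintf("L%d", 1:5),
                   c14_age = seq(8200, 7800, length.out = 5),
                   c14_sigma = 40, material = "terrestrial")
  spec <- build_phase_model(date_table(df),
                            list(phase_spec("A", df$lab_code, "uniform")),
                            curve, outlier = NULL,
                            overall_range = c(10000, 6000))
  # spans well inside the overall range: density must fall monotonically
  spans <- seq(600, 1800, by = 300)
  lp <- vapply(spans, function(s) {
    phase_log_posterior(list(theta = df$c14_age,
                             start = 8000 + s / 2, end = 8000 - s / 2,
                             tau = NA_real_), spec)
  }, 0)
  expect_true(all(diff(lp) < 0))
})

test_that("a fixed seed reproduces boundary draws bit-identically", {
  curve <- identity_curve()
  site <- site_fixture(10)
  phases <- list(phase_spec("A", site$dates$lab_code, "uniform"))
  f1 <- phase_model(site$dates, phases, curve, outlier = NULL,
                    mcmc = quick_mcmc(seed = 99))
  f2 <- phase_model(site$dates, phases, curve, outlier = NULL,
                    mcmc = quick_mcmc(seed = 99))
  expect_identical(f1$boundary_samples, f2$boundary_samples)
  expect_identical(f1$event_samples, f2$event_samples)
  f3 <- phase_model(site$dates, phases, curve, outlier = NULL,
                    mcmc = quick_mcmc(seed = 100))
  expect_false(identical(f1$boundary_samples, f3$boundary_samples))
})

test_that("uniform-boundary draws respect the ordering invariant everywhere", {
  curve <- identity_curve()
  site <- site_fixture(15, seed = 21)
  fit <- phase_model(site$dates,
                     list(phase_spec("A", site$dates$lab_code, "uniform")),
                     curve, outlier = NULL, mcmc = quick_mcmc(seed = 3))
  start <- fit$boundary_samples[, "start_A"]
  end <- fit$boundary_samples[, "end_A"]
  ev_max <- apply(fit$event_samples, 1, max)
  ev_min <- apply(fit$event_samples, 1, min)
  expect_true(all(start >= ev_max))
  expect_true(all(ev_min >= end))
})

test_that("a single wide phase leaves each date's marginal at its calibration", {
  # with the outlier model off and one phase PINNED to the whole range,
  # each event's posterior must equal its single-date calibration (with
  # free boundaries the span prior contracts the phase onto the data and
  # shrinks edge events inward — the phase model working as intended)
  curve <- wiggly_curve(11000, 5000, seed = 6)
  site <- site_fixture(6, seed = 31, curve = curve)
  spec <- build_phase_model(site$dates,
                            list(phase_spec("A", site$dates$lab_code,
                                            "uniform")),
                            curve, outlier = NULL,
                            overall_range = c(10600, 5400))
  fit <- sample_posterior(spec, mcmc_control(chains = 2, iterations = 42000,
                                             burn_in = 2000, thin = 4,
                                             seed = 5),
                          fixed_boundaries = c(start_A = 10500,
                                               end_A = 5500))
  # total variation over a shared 50-yr partition: the reference is the
  # 1-yr calibration integrated over each bin (point-evaluating it at bin
  # centres leaves a pure discretisation artifact larger than the bound)
  fine <- cal_grid(10500, 5500, 1)
  breaks <- seq(5500, 10500, by = 50)
  tv <- vapply(seq_len(nrow(site$dates)), function(i) {
    calf <- calibrate_terrestrial(as.list(site$dates[i, ]), curve, fine)
    ref <- numeric(length(breaks) - 1L)
    agg <- tapply(calf$mass,
                  findInterval(calf$ages, breaks, rightmost.closed = TRUE),
                  sum)
    ref[as.integer(names(agg))] <- agg
    emp <- tabulate(findInterval(fit$event_samples[, i], breaks,
                                 rightmost.closed = TRUE),
                    nbins = length(breaks) - 1L)
    0.5 * sum(abs(ref / sum(ref) - emp / sum(emp)))
  }, 0)
  expect_lt(max(tv), 0.02)
})

test_that("boundary summaries re-derive from the raw draws", {
  curve <- identity_curve()
  site <- site_fixture(10, seed = 41)
  fit <- phase_model(site$dates,
                     list(phase_spec("A", site$dates$lab_code, "uniform")),
                     curve, outlier = NULL, mcmc = quick_mcmc(seed = 7))
  est <- boundary_estimates(fit, levels = 0.95)
  expect_equal(nrow(est), 2L)
  expect_equal(est$mean, unname(colMeans(fit$boundary_samples)))
  expect_equal(est$median,
               unname(apply(fit$boundary_samples, 2, stats::median)))
  expect_equal(est$ka, round(est$mean / 1000, 1))

  # degenerate draws: mean = median, zero-width HPD
  fit$boundary_samples[, "start_A"] <- 8400
  est2 <- boundary_estimates(fit, levels = 0.95)
  expect_equal(est2$mean[1], est2$median[1])
  expect_equal(est2$hpd95_older[1], est2$hpd95_younger[1])
})

test_that("outlier report needs the outlier model", {
  curve <- identity_curve()
  site <- site_fixture(8, seed = 51)
  fit <- phase_model(site$dates,
                     list(phase_spec("A", site$dates$lab_code, "uniform")),
                     curve, outlier = NULL, mcmc = quick_mcmc(seed = 9))
  expect_error(outlier_report(fit), class = "baychron_unsupported_error")
})

test_that("an injected 1000-yr shift attains the top outlier probability", {
  curve <- identity_curve()
  ip <- baychron:::curve_interpolator(curve)
  site <- site_fixture(20, seed = 61)
  dates <- site$dates
  # inject into the date nearest mid-phase, where a +1000-yr shift is
  # unambiguous (a shift on a date already near the phase start merely
  # looks like a slightly older in-phase event)
  k <- which.min(abs(site$truth$theta - 8000))
  set.seed(61)
  dates$c14_age[k] <- round(rnorm(1, ip$mu(site$truth$theta[k] + 1000), 40))
  fit <- phase_model(dates, list(phase_spec("A", dates$lab_code, "uniform")),
                     curve,
                     mcmc = mcmc_control(chains = 2, iterations = 5000,
                                         burn_in = 1500, thin = 2, seed = 13))
  rep <- outlier_report(fit)
  expect_equal(which.max(rep$p_outlier), k)
  expect_gt(max(rep$p_outlier), 0.5)
  # the conflicting date also shows depressed agreement
  expect_lt(rep$agreement[k], 60)
})

test_that("sigma boundaries fit and report tail overlap sensibly", {
  curve <- identity_curve()
  site <- sim_phased_site(site_sim_config(
    list(c(8500, 8100), c(8100, 7700)), 8, lab_sigma = 40, seed = 71), curve)
  phases <- list(phase_spec("older", site$dates$lab_code[1:8], "sigma"),
                 phase_spec("younger", site$dates$lab_code[9:16], "sigma"))
  fit <- phase_model(site$dates, phases, curve, outlier = NULL,
                     contiguous = TRUE, mcmc = quick_mcmc(seed = 17))
  expect_length(colnames(fit$boundary_samples), 3L)
  est <- boundary_estimates(fit)
  expect_true(est$mean[1] > est$mean[2])
  expect_true(est$mean[2] > est$mean[3])
  expect_true(all(is.finite(fit$diagnostics$rhat)))
})

test_that("prior-predictive spans are uniform and seed-deterministic", {
  curve <- identity_curve()
  df <- data.frame(lab_code = sprintf("L%d", 1:5),
                   c14_age = seq(8300, 7700, length.out = 5),
                   c14_sigma = 40, material = "terrestrial")
  spec <- build_phase_model(date_table(df),
                            list(phase_spec("A", df$lab_code, "uniform")),
                            curve, outlier = NULL,
                            overall_range = c(9000, 7000))
  span <- prior_predictive_span(spec, draws = 10000, seed = 1)
  R <- 2000
  ks <- suppressWarnings(stats::ks.test(span[, 1], "punif", 0, R))
  expect_gt(ks$p.value, 0.01)

  # a single-member phase behaves identically: the correction is n-free
  df1 <- df[1, , drop = FALSE]
  spec1 <- build_phase_model(date_table(df1),
                             list(phase_spec("A", "L1", "uniform")), curve,
                             outlier = NULL, overall_range = c(9000, 7000))
  span1 <- prior_predictive_span(spec1, draws = 10000, seed = 2)
  ks1 <- suppressWarnings(stats::ks.test(span1[, 1], "punif", 0, R))
  expect_gt(ks1$p.value, 0.01)

  expect_identical(prior_predictive_span(spec1, draws = 500, seed = 5),
                   prior_predictive_span(spec1, draws = 500, seed = 5))
})
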