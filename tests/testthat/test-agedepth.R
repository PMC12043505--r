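# Age-depth regression, imputation, reversal diagnostics.

line_core <- function(beta0 = 3000, beta1 = 1500, sigma_eps = 0,
                      depths = seq(0.25, 3, by = 0.25), lab = 5, seed = 3,
                      curve = identity_curve()) {
  sim_core(core_sim_config(beta0, beta1, sigma_eps, depths,
                           lab_sigma = lab, seed = seed), curve)
}

test_that("an exact line is recovered within posterior uncertainty", {
  curve <- identity_curve()
  core <- line_core(beta0 = 2000, beta1 = 500, lab = 5,
                    depths = seq(0.5, 6, by = 0.5))
  fit <- age_depth(core$core, curve, mcmc = quick_mcmc(seed = 1,
                                                       iterations = 2000,
                                                       burn_in = 800))
  b0 <- fit$beta0_samples; b1 <- fit$beta1_samples
  expect_lt(abs(mean(b0) - 2000), 2 * sd(b0))
  expect_lt(abs(mean(b1) - 500), 2 * sd(b1))
  expect_true(all(fit$sigma_eps_samples > 0))
})

test_that("input row order does not change the seeded posterior", {
  curve <- identity_curve()
  core <- line_core(sigma_eps = 100, lab = 40)$core
  ctl <- quick_mcmc(seed = 8, iterations = 1200, burn_in = 500)
  f1 <- age_depth(core, curve, mcmc = ctl)
  set.seed(99); perm <- sample(nrow(core))
  f2 <- age_depth(core[perm, ], curve, mcmc = ctl)
  expect_identical(f1$beta1_samples, f2$beta1_samples)
  expect_identical(f1$theta_samples, f2$theta_samples)
})

test_that("validation rejects degenerate cores", {
  curve <- identity_curve()
  core <- line_core()$core
  expect_error(age_depth(core[1:2, ], curve),
               class = "baychron_validation_error")
  flat <- core[1:3, ]; flat$depth_m <- 1
  expect_error(age_depth(flat, curve), class = "baychron_validation_error")
})

test_that("imputation adds residual variance and interpolates the line", {
  curve <- identity_curve()
  core <- line_core(beta0 = 3000, beta1 = 1500, sigma_eps = 0, lab = 5)
  fit <- age_depth(core$core, curve, mcmc = quick_mcmc(seed = 2,
                                                       iterations = 2000,
                                                       burn_in = 800))
  depths <- c(0.375, 1.125, 2.625)
  set.seed(1)
  imp <- impute_depth_ages(fit, depths, force = TRUE)
  line_draws <- sapply(depths, function(d) {
    fit$beta0_samples + fit$beta1_samples * d
  })
  for (k in seq_along(depths)) {
    # predictive variance >= regression-line variance (law of total variance)
    expect_gte(var(imp$draws[, k]), var(line_draws[, k]))
    # midpoint of two dated depths sits at the neighbour average
    want <- 3000 + 1500 * depths[k]
    mc_se <- sd(imp$draws[, k]) / sqrt(nrow(imp$draws) / 10)
    expect_lt(abs(mean(imp$draws[, k]) - want), 3 * mc_se + 5)
  }
  expect_error(impute_depth_ages(fit, numeric()),
               class = "baychron_validation_error")
})

test_that("the posterior is invariant to depth-unit rescaling", {
  curve <- identity_curve()
  core <- line_core(sigma_eps = 100, lab = 40, seed = 5)$core
  ctl <- quick_mcmc(seed = 11, iterations = 1200, burn_in = 500)
  pri_m <- age_depth_priors(beta0_mean = 7000, beta0_sd = 10000,
                            beta1_mean = 0, beta1_sd = 10000,
                            sigma_eps_scale = 1000)
  fit_m <- age_depth(core, curve, pri_m, ctl)
  core_cm <- core; core_cm$depth_m <- core$depth_m * 100
  pri_cm <- age_depth_priors(beta0_mean = 7000, beta0_sd = 10000,
                             beta1_mean = 0, beta1_sd = 100,
                             sigma_eps_scale = 1000)
  fit_cm <- age_depth(core_cm, curve, pri_cm, ctl)
  expect_equal(fit_cm$beta1_samples, fit_m$beta1_samples / 100,
               tolerance = 1e-8)
  expect_equal(fit_cm$beta0_samples, fit_m$beta0_samples, tolerance = 1e-8)
})

test_that("inflating lab errors widens every latent-age marginal", {
  # larger measurement errors flatten each date's likelihood, so the
  # latent calendar-age posteriors must widen at every dated depth.
  # (The line + epsilon imputation interval does NOT necessarily widen:
  # the observed scatter is reallocated from sigma_eps to the stated
  # measurement error, and the sigma_eps posterior shrinks — see the
  # methods vignette.)
  curve <- identity_curve()
  core <- line_core(sigma_eps = 80, lab = 30, seed = 7)$core
  ctl <- quick_mcmc(seed = 21, iterations = 1500, burn_in = 600)
  fit1 <- age_depth(core, curve, mcmc = ctl)
  core4 <- core; core4$c14_sigma <- core$c14_sigma * 4
  fit4 <- age_depth(core4, curve, mcmc = ctl)
  sd1 <- apply(fit1$theta_samples, 2, sd)
  sd4 <- apply(fit4$theta_samples, 2, sd)
  expect_true(all(sd4 > sd1))
})

test_that("tighter residual priors shrink imputed intervals on line data", {
  # on exact-line data, pushing the half-normal scale of sigma_eps toward
  # zero must pull the imputed interval onto the regression line; the
  # scales span the likelihood-dominated down to the prior-pinned regime
  curve <- identity_curve()
  core <- line_core(sigma_eps = 0, lab = 5, seed = 9)$core
  widths <- vapply(c(200, 2, 0.2), function(scale) {
    fit <- age_depth(core, curve,
                     age_depth_priors(sigma_eps_scale = scale),
                     quick_mcmc(seed = 31, iterations = 3000, burn_in = 1000,
                                thin = 2))
    set.seed(3)
    imp <- impute_depth_ages(fit, 1.6, force = TRUE)
    imp$summary$hpd_upper - imp$summary$hpd_lower
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("reversal counting matches the brute-force pairwise scan", {
  curve <- identity_curve()
  mono <- line_core(sigma_eps = 0, lab = 1, seed = 13)$core
  expect_equal(count_reversals(mono, curve), 0L)

  swapped <- data.frame(lab_code = c("a", "b", "c", "d"),
                        depth_m = 1:4,
                        c14_age = c(5000, 5600, 5400, 6000),
                        c14_sigma = 10, material = "terrestrial")
  expect_equal(count_reversals(swapped, curve), 1L)

  for (seed in 1:5) {
    core <- sim_core(core_sim_config(3000, 1200, 300, seq(0.2, 2.4, 0.2),
                                     redeposit_fraction = 0.25,
                                     redeposit_shift = 900, lab_sigma = 30,
                                     seed = seed), curve)$core
    got <- count_reversals(core, curve)
    # oracle: direct scan of adjacent calibrated means by depth
    ip <- baychron:::curve_interpolator(curve)
    grid <- cal_grid(ip$hi, ip$lo, 5)
    means <- vapply(seq_len(nrow(core)), function(i) {
      point_summaries(calibrate_terrestrial(
        list(c14_age = core$c14_age[i], c14_sigma = core$c14_sigma[i],
             material = "terrestrial"), curve, grid))$mean
    }, 0)
    ord <- order(core$depth_m)
    want <- 0L
    for (k in seq_len(length(ord) - 1L)) {
      if (means[ord[k + 1L]] < means[ord[k]]) want <- want + 1L
    }
    expect_equal(got, want)
  }

  expect_error(count_reversals(mono[1, ], curve),
               class = "baychron_validation_error")
})
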