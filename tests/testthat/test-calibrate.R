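# Single-date calibration, HPD sets, summaries, agreement index.

test_that("on a linear curve the posterior is the closed-form Gaussian", {
  cv <- identity_curve(sigma = 1e-9)
  det <- list(c14_age = 8000, c14_sigma = 50, material = "terrestrial")
  grid <- cal_grid(9000, 7000, 1)
  dens <- calibrate_terrestrial(det, cv, grid)
  want <- dnorm(grid$ages, 8000, 50)
  want <- want / sum(want)
  expect_lt(max(abs(dens$mass - want)), 1e-12)
  expect_equal(sum(dens$mass), 1, tolerance = 1e-9)
})

test_that("calibration equals the brute-force Riemann oracle on wiggly curves", {
  # trimmed grids keep the oracle loop affordable; several curves and dates
  for (seed in 1:3) {
    cv <- wiggly_curve(8600, 7400, seed = seed)
    x <- 7600 + 150 * seed
    det <- list(c14_age = x, c14_sigma = 45, material = "terrestrial")
    grid <- cal_grid(8500, 7500, 5)
    dens <- calibrate_terrestrial(det, cv, grid)
    want <- oracle_calibrate(x, 45, cv, grid$ages)
    expect_lt(max(abs(dens$mass - want)), 1e-12)
  }
})

test_that("marine calibration applies the reservoir offset correctly", {
  cvm <- identity_curve(sigma = 1e-9, kind = "marine")
  grid <- cal_grid(9000, 7000, 1)
  det <- list(c14_age = 8000, c14_sigma = 50, material = "marine")

  # Delta-R = 0 +/- 0 reduces exactly to the terrestrial kernel
  d0 <- calibrate_marine(det, cvm, 0, 0, grid)
  det_t <- det; det_t$material <- "terrestrial"
  cvt <- identity_curve(sigma = 1e-9, kind = "terrestrial")
  dt <- calibrate_terrestrial(det_t, cvt, grid)
  expect_equal(d0$mass, dt$mass)

  # +100 14C yr offset shifts the calendar posterior 100 yr younger
  d100 <- calibrate_marine(det, cvm, 100, 0, grid)
  m0 <- point_summaries(d0)$mean
  m100 <- point_summaries(d100)$mean
  expect_equal(m100 - m0, -100, tolerance = 0.01)

  # oracle equality including the Delta-R variance term
  cvw <- wiggly_curve(8600, 7400, seed = 5, kind = "marine")
  gridw <- cal_grid(8500, 7500, 5)
  dw <- calibrate_marine(det, cvw, 120, 35, gridw)
  want <- oracle_calibrate(8000, 50, cvw, gridw$ages, dr_mean = 120,
                           dr_var = 35^2)
  expect_lt(max(abs(dw$mass - want)), 1e-12)
})

test_that("material and kind mismatches are rejected for every shell", {
  cvt <- identity_curve()
  grid <- cal_grid(9000, 7000, 5)
  shells <- date_table(data.frame(
    lab_code = sprintf("SH-%02d", 1:49),
    c14_age = round(seq(8100, 7200, length.out = 49)),
    c14_sigma = 40, material = "marine"))
  for (i in seq_len(nrow(shells))) {
    expect_error(calibrate_terrestrial(as.list(shells[i, ]), cvt, grid),
                 class = "baychron_material_error")
  }
})

test_that("degenerate posteriors raise rather than returning garbage", {
  cv <- identity_curve(sigma = 1e-9)
  det <- list(c14_age = 100000, c14_sigma = 10, material = "terrestrial")
  expect_error(calibrate_terrestrial(det, cv, cal_grid(9000, 7000, 1)),
               class = "baychron_degenerate_error")
  expect_error(calibrate_terrestrial(
    list(c14_age = 8000, c14_sigma = 50, material = "terrestrial"),
    cv, cal_grid(20000, 7000, 1)), class = "baychron_range_error")
})

test_that("HPD sets match expectations on unimodal and bimodal densities", {
  cv <- identity_curve(sigma = 1e-9)
  det <- list(c14_age = 8000, c14_sigma = 50, material = "terrestrial")
  dens <- calibrate_terrestrial(det, cv, cal_grid(9000, 7000, 1))
  h <- hpd_intervals(dens, 0.954)
  expect_equal(nrow(h$intervals), 1L)
  expect_equal(h$intervals$older, 8100, tolerance = 2)
  expect_equal(h$intervals$younger, 7900, tolerance = 2)
  expect_gte(h$attained, 0.954)

  # symmetric bimodal: two disjoint intervals, equal to the threshold oracle
  grid <- cal_grid(9000, 7000, 1)
  mass <- dnorm(grid$ages, 8400, 40) + dnorm(grid$ages, 7600, 40)
  bim <- baychron:::new_cal_density(grid, mass / sum(mass))
  h2 <- hpd_intervals(bim, 0.9)
  expect_equal(nrow(h2$intervals), 2L)
  want_cells <- oracle_hpd_cells(bim$mass, 0.9)
  got_cells <- unlist(lapply(seq_len(nrow(h2$intervals)), function(i) {
    which(bim$ages <= h2$intervals$older[i] &
            bim$ages >= h2$intervals$younger[i])
  }))
  expect_setequal(got_cells, want_cells)

  # level 1 returns the support of all non-zero cells
  h3 <- hpd_intervals(bim, 1)
  expect_equal(h3$attained, 1)
  expect_equal(sum(bim$mass > 0),
               sum(vapply(seq_len(nrow(h3$intervals)), function(i) {
                 sum(bim$ages <= h3$intervals$older[i] &
                       bim$ages >= h3$intervals$younger[i] & bim$mass > 0)
               }, 0L)))
})

test_that("point summaries: symmetric equality, hand case, oracle sums", {
  cv <- identity_curve(sigma = 1e-9)
  det <- list(c14_age = 8000, c14_sigma = 50, material = "terrestrial")
  dens <- calibrate_terrestrial(det, cv, cal_grid(9000, 7000, 1))
  s <- point_summaries(dens)
  expect_equal(s$mean, 8000, tolerance = 0.5)
  expect_equal(s$median, 8000, tolerance = 1)
  expect_equal(s$mode, 8000, tolerance = 1)

  g3 <- cal_grid(3000, 2998, 1)
  d3 <- baychron:::new_cal_density(g3, c(0.3, 0.5, 0.2))
  s3 <- point_summaries(d3)
  expect_equal(s3$mean, 2999.1) # 3000*.3 + 2999*.5 + 2998*.2 by hand
  expect_equal(s3$median, 2999)
  expect_equal(s3$mode, 2999)

  wig <- wiggly_curve(8600, 7400, seed = 9)
  dw <- calibrate_terrestrial(list(c14_age = 7900, c14_sigma = 45,
                                   material = "terrestrial"),
                              wig, cal_grid(8500, 7500, 5))
  expect_equal(point_summaries(dw)$mean, sum(dw$ages * dw$mass))
})

test_that("agreement index behaves as an overlap statistic", {
  grid <- cal_grid(9000, 7000, 1)
  g1 <- dnorm(grid$ages, 8000, 60); g1 <- g1 / sum(g1)
  d1 <- baychron:::new_cal_density(grid, g1)
  expect_equal(agreement_index(d1, d1), 100)

  far <- dnorm(grid$ages, 7200, 60); far <- far / sum(far)
  expect_lt(agreement_index(d1, baychron:::new_cal_density(grid, far)), 1e-6)

  half <- dnorm(grid$ages, 8060, 60); half <- half / sum(half)
  d2 <- baychron:::new_cal_density(grid, half)
  want <- 100 * sum(half * g1) / sum(g1 * g1)
  expect_equal(agreement_index(d1, d2), want, tolerance = 1e-9)

  other <- cal_grid(9000, 7000, 5)
  expect_error(agreement_index(d1, baychron:::new_cal_density(
    other, rep(1 / length(other$ages), length(other$ages)))),
    class = "baychron_grid_error")
})

test_that("grid refinement changes point summaries by under 5 yr", {
  cv <- wiggly_curve(9200, 6800, seed = 3)
  det <- list(c14_age = 7900, c14_sigma = 45, material = "terrestrial")
  s5 <- point_summaries(calibrate_terrestrial(det, cv, cal_grid(9000, 7000, 5)))
  s1 <- point_summaries(calibrate_terrestrial(det, cv, cal_grid(9000, 7000, 1)))
  expect_lt(abs(s5$mean - s1$mean), 5)
  expect_lt(abs(s5$median - s1$median), 5)
})

test_that("agreement index is stable under grid-step refinement", {
  # same support, steps 5 and 1: relative change under 1e-6 requires the
  # index to be a density overlap, not a cell-count artefact
  for (step in c(5, 1)) {
    grid <- cal_grid(9000, 7000, step)
    p <- dnorm(grid$ages, 8000, 80); p <- p / sum(p)
    q <- dnorm(grid$ages, 8050, 80); q <- q / sum(q)
    a <- agreement_index(baychron:::new_cal_density(grid, p),
                         baychron:::new_cal_density(grid, q))
    if (step == 5) a5 <- a else a1 <- a
  }
  expect_equal(a5, a1, tolerance = 1e-6)
})

test_that("densities export as two-column text and draws bin onto grids", {
  cv <- identity_curve(sigma = 1e-9)
  dens <- calibrate_terrestrial(list(c14_age = 8000, c14_sigma = 50,
                                     material = "terrestrial"),
                                cv, cal_grid(9000, 7000, 1))
  path <- withr::local_tempfile()
  write_cal_density(dens, path)
  back <- utils::read.csv(path)
  expect_equal(back$calbp, dens$ages)
  expect_equal(back$mass, dens$mass)

  set.seed(1)
  draws <- rnorm(20000, 8000, 50)
  binned <- density_from_draws(draws, cal_grid(9000, 7000, 5))
  expect_equal(sum(binned$mass), 1)
  expect_equal(point_summaries(binned)$mean, 8000, tolerance = 2)
})
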