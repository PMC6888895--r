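test_that("per-volume closure matches hand algebra", {
  comp <- flux_components(90, 36, 5)
  p <- solve_pnet(comp, cfg = balance_config("stratified"))
  expect_equal(p$value, (90 - 36 - 5) / 0.7)          # 70 nmol/l/d
  expect_equal(p$unit, "nmol l-1 d-1")
  zero <- solve_pnet(flux_components(0, 0, 0),
                     cfg = balance_config("stratified"))
  expect_equal(zero$value, 0)
})

test_that("enclosure areal closure gives the per-area balance", {
  comp <- flux_components(0.43, 0, 0.007, unit = "mmol m-2 d-1")
  p <- solve_pnet(comp, geometry = 6, cfg = balance_config("stratified"))
  expect_equal(p$value, (0.43 - 0.007) / (0.7 * 6) * 1e3)   # 100.71
  expect_equal(round(p$value), 101)
})

test_that("balance residual is zero to machine precision for random
           component sets", {
  set.seed(99)
  for (i in 1:1000) {
    fs <- runif(1, -50, 300); fl <- runif(1, 0, 150)
    fz <- runif(1, -20, 50); a <- runif(1, 0, 0.9)
    cfg <- balance_config("stratified", alpha = a)
    p <- solve_pnet(flux_components(fs, fl, fz), cfg = cfg)$value
    residual <- fs - fl - fz - (1 - a) * p            # Eq. form at P_net
    scale <- max(abs(c(fs, fl, fz, p)), 1)
    expect_lt(abs(residual) / scale, 1e-10)
  }
})

test_that("areal whole-basin closure matches the explicit area-weighted
           budget", {
  g <- derive_geometry(stechlin_hypsometry("south"), 6)
  cfg <- balance_config("stratified")
  comp <- flux_components(0.71, 1.4, 0.05, unit = "mmol m-2 d-1")
  p <- solve_pnet(comp, g, cfg)$value                  # nmol l-1 d-1
  lhs <- 0.71 * g$A_tot                                # mmol d-1 out
  rhs <- 1.4 * g$A_sed + 0.05 * g$A_th +
    (1 - cfg$alpha) * p * 1e-3 * g$volume_sml          # mmol d-1 in
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("Monte Carlo closure matches its closed-form Gaussian limits", {
  comp <- flux_components(c(90, 52), c(36, 6), c(5, 5))
  cfg <- balance_config("stratified")
  mc <- monte_carlo_pnet(comp, cfg = cfg, n = 9999, seed = 17)
  mu <- (90 - 36 - 5) / 0.7
  sigma <- sqrt(52^2 + 6^2 + 5^2) / 0.7
  expect_lt(abs(mc$mean - mu), 3 * sigma / sqrt(9999))
  expect_lt(abs(mc$sd - sigma) / sigma, 0.03)
  expect_lt(abs(mc$p_positive - pnorm(mu / sigma)), 0.015)
  # the law-of-large-numbers limit tightens at n = 1e6
  big <- monte_carlo_pnet(comp, cfg = cfg, n = 1e6, seed = 18)
  expect_lt(abs(big$mean - mu), 3 * sigma / sqrt(1e6))
})

test_that("Monte Carlo is seed-reproducible and degenerate at zero sd", {
  comp <- flux_components(c(90, 52), c(36, 6), c(5, 5))
  a <- monte_carlo_pnet(comp, cfg = balance_config(), n = 2000, seed = 7)
  b <- monte_carlo_pnet(comp, cfg = balance_config(), n = 2000, seed = 7)
  expect_identical(a$draws, b$draws)
  c_ <- monte_carlo_pnet(comp, cfg = balance_config(), n = 2000, seed = 8)
  expect_false(identical(a$draws, c_$draws))

  det <- monte_carlo_pnet(flux_components(90, 36, 5),
                          cfg = balance_config(), n = 500, seed = 1)
  expect_equal(det$sd, 0)
  expect_equal(det$mean,
               solve_pnet(flux_components(90, 36, 5),
                          cfg = balance_config())$value)
})

test_that("negative draws are retained in the positive-probability
           statistic", {
  comp <- flux_components(c(10, 50), c(0, 0), c(0, 0))
  mc <- monte_carlo_pnet(comp, cfg = balance_config(), n = 9999, seed = 2)
  expect_gt(sum(mc$draws < 0), 0)
  expect_lt(mc$p_positive, 1)
})

test_that("ignoring oxidation shifts production toward the raw deficit", {
  # with positive net emission, alpha = 0 lowers the inferred production
  comp <- flux_components(148, 79, 8)
  p03 <- solve_pnet(comp, cfg = balance_config("stratified"))$value
  p00 <- solve_pnet(comp, cfg = balance_config("stratified",
                                               alpha = 0))$value
  expect_lt(p00, p03)
  expect_equal(sign(p03 - p00), sign(148 - 79 - 8))
})

test_that("enclosure comparison derives the printed lateral input", {
  g <- derive_geometry(stechlin_hypsometry("south"), 6)
  lat <- solve_lateral(0.77, 0.024, 101, g)
  expect_equal(round(lat$lateral_volumetric), 77)     # ~76 printed
  expect_lt(abs(lat$lateral_volumetric - 76), 2)
  expect_lt(abs(lat$f_l_areal - 1.4), 0.05)
  # open water identical to the enclosure: no lateral input
  same <- solve_lateral(0.43, 0.007, (0.43 - 0.007) / (0.7 * 6) * 1e3, g)
  expect_equal(same$lateral_volumetric, 0, tolerance = 1e-10)
  expect_warning(solve_lateral(0.1, 0.007, 101, g), "negative")
})

test_that("seasonal parameterisation follows the stratification calendar", {
  onset <- "2016-05-01"; full <- "2016-06-01"
  expect_equal(seasonal_config("2016-03-15", onset, full)$season,
               "non_stratified")
  expect_equal(seasonal_config("2016-03-15", onset, full)$alpha, 0)
  cfg_jun <- seasonal_config("2016-06-20", onset, full)
  expect_equal(cfg_jun$season, "stratified")
  expect_equal(cfg_jun$alpha, 0.3)
  # transitional month splits at mid-month
  expect_equal(seasonal_config("2016-05-10", onset, full)$season,
               "non_stratified")
  expect_equal(seasonal_config("2016-05-20", onset, full)$season,
               "stratified")
})

test_that("configuration guards reject singular or invalid closures", {
  expect_error(balance_config("stratified", alpha = 1), "singular")
  expect_error(balance_config("stratified", alpha = -0.1), "alpha")
  expect_warning(balance_config("non_stratified", alpha = 0.3),
                 "forces alpha = 0")
  expect_error(flux_components(c(90, -1), 0, 0), "sd must be")
  expect_error(monte_carlo_pnet(flux_components(90, 36, 5),
                                cfg = balance_config()),
               "seed")
})

test_that("component CSV round trips with unit checking", {
  tab <- generate_component_table(
    means = c(f_s = 90, f_l = 36, f_z = 5),
    sds = c(f_s = 52, f_l = 6, f_z = 5),
    site = "ne", season = "stratified")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  comp <- read_components(path, site = "ne", season = "stratified")
  expect_equal(comp$f_s, c(mean = 90, sd = 52))
  expect_equal(comp$unit, "nmol l-1 d-1")
  bad <- tab; bad$unit <- "furlong fortnight-1"
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_components(path, site = "ne"), "unknown unit")
})
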