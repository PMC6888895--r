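test_that("chamber flux is the amount slope per footprint area", {
  # exact line adding 0.1 mmol over 0.1 d on a 1 m^2 footprint
  times <- c(0, 72, 144)                      # minutes; 144 min = 0.1 d
  dep <- chamber_deployment(times, ch4_mmol = 0.1 * times / 144,
                            footprint_area_m2 = 1)
  expect_equal(chamber_flux(dep), 1.0)
  # constant chamber content: no flux
  flat <- chamber_deployment(times, ch4_mmol = rep(0.05, 3),
                             footprint_area_m2 = 1)
  expect_equal(chamber_flux(flat), 0)
})

test_that("chamber flux is invariant to uniform time shifts", {
  times <- seq(0, 40, 10)
  mmol <- 0.002 * times + 0.01
  f1 <- chamber_flux(chamber_deployment(times, ch4_mmol = mmol))
  f2 <- chamber_flux(chamber_deployment(times + 37, ch4_mmol = mmol))
  expect_equal(f1, f2)
})

test_that("chamber deployment validation rejects degenerate series", {
  expect_error(chamber_deployment(c(0, 10), ch4_mmol = c(0, 1)),
               "3 time points")
  expect_error(chamber_deployment(c(0, 10, 5), ch4_mmol = c(0, 1, 2)),
               "increasing")
  expect_error(chamber_deployment(c(0, 10, 20), ch4_mmol = c(0, -1, 2)),
               "non-negative")
})

test_that("noisy ppm deployments recover the generating flux within 10%", {
  true_flux <- 0.47                           # mmol m-2 d-1
  times <- seq(0, 40, 5)
  footprint <- 0.07; temp <- 20
  mmol <- true_flux * footprint * times / 1440
  ppm <- (mmol / 1000) * 8.31446 * (temp + 273.15) /
    (101325 * 15e-3) * 1e6 + 1.9
  set.seed(31)
  recovered <- replicate(25, {
    noisy <- ppm * (1 + rnorm(length(ppm), 0, 0.05))
    chamber_flux(chamber_deployment(times, ch4_ppm = noisy,
                                    footprint_area_m2 = footprint,
                                    water_temp_c = temp))
  })
  expect_lt(abs(mean(recovered) - true_flux) / true_flux, 0.10)
})

test_that("the CH4 Schmidt number polynomial evaluates as published", {
  # direct evaluation of the Wanninkhof (1992) freshwater polynomial
  t <- 20
  expect_equal(schmidt_ch4(t),
               1897.8 - 114.28 * t + 3.2902 * t^2 - 0.039061 * t^3)
  expect_equal(schmidt_ch4(20), 615.792, tolerance = 1e-9)
  expect_equal(schmidt_ch4(20), 600, tolerance = 0.05)  # near 600 by design
})

test_that("k600 inversion undoes the forward flux law", {
  k600_true <- 6.0; temp <- 18; c_sfc <- 500; atm <- 1.9
  k_ch4 <- k600_true * (schmidt_ch4(temp) / 600)^(-0.5) * 24 / 100
  flux <- k_ch4 * (c_sfc - ch4_equilibrium(temp, atm)) * 1e-3
  expect_equal(k600_from_flux(flux, c_sfc, temp, atm), k600_true,
               tolerance = 1e-6)
  # the 2/3 exponent variant round trips too
  k_23 <- k600_true * (schmidt_ch4(temp) / 600)^(-2 / 3) * 24 / 100
  flux23 <- k_23 * (c_sfc - ch4_equilibrium(temp, atm)) * 1e-3
  expect_equal(k600_from_flux(flux23, c_sfc, temp, atm,
                              sc_exponent = 2 / 3),
               k600_true, tolerance = 1e-6)
})

test_that("vanishing air-water gradient is flagged, not zeroed", {
  temp <- 15
  c_eq <- ch4_equilibrium(temp)
  expect_warning(k <- k600_from_flux(0, c_eq, temp), "indeterminate")
  expect_true(is.na(k))
  expect_error(k600_from_flux(0.5, c_eq, temp), "zero air-water gradient")
})

test_that("k600-wind fit recovers exact coefficients and flags degeneracy", {
  u10 <- seq(0.5, 8, length.out = 12)
  k600 <- 1.98 * u10 + 0.94
  m <- suppressWarnings(fit_k600_wind(u10, k600))
  expect_equal(m$slope, 1.98, tolerance = 1e-10)
  expect_equal(m$intercept, 0.94, tolerance = 1e-10)

  flat <- fit_k600_wind(u10, rep(3, 12))
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_equal(flat$r_squared, 0)

  expect_warning(two <- fit_k600_wind(c(1, 4), c(2.92, 8.86)), "2 pairs")
  expect_equal(two$slope, 1.98, tolerance = 1e-10)
  expect_error(fit_k600_wind(rep(2, 5), 1:5), "all equal")
})

test_that("wind-based emission respects limits and monotonicity", {
  m <- k600_wind_model(1.98, 0.94)
  # calm wind: the intercept alone sets k600
  expect_equal(predict_k600(m, rep(0, 4)), rep(0.94, 4))
  # no gradient, no emission regardless of wind
  temp <- 20
  e0 <- estimate_emission(m, c(0, 3, 9), ch4_equilibrium(temp), temp)
  expect_equal(e0$flux, rep(0, 3))
  # monotone non-decreasing in U10 for an oversaturated surface
  e <- estimate_emission(m, c(0, 1, 3, 6, 10), 600, temp)
  expect_true(all(diff(e$flux) > 0))
  expect_error(estimate_emission(m, numeric(0), 600, temp), "empty")
  expect_error(predict_k600(m, -1), "non-negative")
})

test_that("wind-based emission recovers the campaign's generating mean", {
  spec <- synthetic_lake_spec("stechlin_s", seed = 5)
  camp <- generate_campaign(spec)
  m <- k600_wind_model(spec$true_k600[1], spec$true_k600[2])
  est <- estimate_emission(m, camp$wind$u10, camp$truth$surface_conc,
                           camp$truth$surface_temp_c)
  expect_lt(abs(est$mean - camp$truth$f_s) / camp$truth$f_s, 0.05)
})
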