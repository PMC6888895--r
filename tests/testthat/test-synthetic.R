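test_that("campaign generation is seed-reproducible", {
  s1 <- generate_campaign(synthetic_lake_spec("stechlin_ne", seed = 21))
  s2 <- generate_campaign(synthetic_lake_spec("stechlin_ne", seed = 21))
  s1$spec <- s2$spec <- NULL                    # closures differ by env
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$ch4$values, s2$ch4$values)
  expect_identical(s1$wind, s2$wind)
  s3 <- generate_campaign(synthetic_lake_spec("stechlin_ne", seed = 22))
  expect_false(identical(s1$wind, s3$wind))
  expect_error(synthetic_lake_spec("stechlin_ne"), "seed")
})

test_that("generated bundles satisfy the steady-state budget identity", {
  for (p in c("stechlin_ne", "stechlin_s", "enclosure")) {
    camp <- generate_campaign(synthetic_lake_spec(p, seed = 9))
    g <- camp$geometry; tr <- camp$truth
    f_s_implied <- ((1 - tr$alpha) * tr$pnet * 1e-3 * g$volume_sml +
                      tr$f_l * g$A_sed + tr$f_z * g$A_th) / g$A_tot
    expect_equal(tr$f_s, f_s_implied, tolerance = 1e-8)
    # the surface concentration was calibrated to reproduce that emission
    m <- k600_wind_model(tr$k600[1], tr$k600[2])
    # noise-free wind is not stored; recompute with the observed series
    est <- estimate_emission(m, camp$wind$u10, tr$surface_conc,
                             tr$surface_temp_c, tr$atm_ppm)
    expect_lt(abs(est$mean - tr$f_s) / tr$f_s, 0.05)
  }
})

test_that("generated fields look like a stratified field season", {
  camp <- generate_campaign(synthetic_lake_spec("stechlin_s", seed = 14))
  ch4 <- rowMeans(camp$ch4$values)
  d <- camp$truth$sml_thickness
  peak_depth <- camp$ch4$depths[which.max(ch4)]
  expect_gt(peak_depth, d - 1)                  # peak at/below the SML base
  expect_lt(peak_depth, d + 4)
  expect_gt(max(ch4), 1000)                     # pronounced thermocline peak
  expect_true(all(ch4 >= 0))
  sml_temp <- camp$temperature$values[1, ncol(camp$temperature$values)]
  expect_gt(sml_temp, 18)                       # warmed surface layer
  expect_true(all(camp$wind$u10 >= 0))
  expect_gt(camp$truth$surface_conc, 200)       # oversaturated SML
  expect_lt(camp$truth$surface_conc, 1200)
})

test_that("noise-free campaigns close the budget end to end", {
  spec <- synthetic_lake_spec("stechlin_s", seed = 7,
                              noise = list(conc = 0, wind = 0,
                                           chamber = 0))
  camp <- generate_campaign(spec)
  res <- suppressWarnings(run_pipeline(camp, seed = 11,
                                       n_iterations = 999))
  expect_lt(abs(res$pnet_point$value - camp$truth$pnet) /
              camp$truth$pnet, 0.01)
  # the campaign OMC sits within 5 points of the analytic preset OMC
  g <- camp$geometry; tr <- camp$truth
  omc_true <- omc(tr$pnet * 1e-6 * g$volume_sml,
                  tr$f_l * 1e-3 * g$A_sed, tr$f_z * 1e-3 * g$A_th)
  expect_lt(abs(res$omc - omc_true), 5)
})

test_that("enclosure campaigns yield no lateral input on comparison", {
  spec <- synthetic_lake_spec("enclosure", seed = 13,
                              noise = list(conc = 0, wind = 0,
                                           chamber = 0))
  camp <- generate_campaign(spec)
  res <- suppressWarnings(run_pipeline(camp, seed = 3,
                                       n_iterations = 499))
  # comparing the enclosure against itself: zero lateral input
  g_open <- derive_geometry(stechlin_hypsometry("south"), 6)
  lat <- solve_lateral(res$f_s[["mean"]], res$f_z[["mean"]],
                       res$pnet_point$value, g_open)
  expect_lt(abs(lat$lateral_volumetric), 1)
})

test_that("component-table fixtures drive the Monte Carlo as specified", {
  tab <- generate_component_table(
    means = c(f_s = 2503, f_l = 1198, f_z = 139),
    sds = c(f_s = 1160, f_l = 185, f_z = 170), unit = "mol d-1")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  comp <- read_components(path, site = "synthetic")
  mc <- monte_carlo_pnet(comp, cfg = balance_config(), n = 9999,
                         seed = 101)
  expect_equal(mc$unit, "mol d-1")
  expect_lt(abs(mc$mean - 1653) / 1653, 0.03)   # whole-lake production
  # zero-sd preset is fully deterministic downstream
  det <- generate_component_table(means = c(f_s = 90, f_l = 36, f_z = 5))
  comp0 <- flux_components(det$mean[1], det$mean[2], det$mean[3])
  mc0 <- monte_carlo_pnet(comp0, cfg = balance_config(), n = 100,
                          seed = 1)
  expect_equal(mc0$sd, 0)
  expect_error(generate_component_table(means = c(f_s = 1, f_l = 1,
                                                  f_z = 1),
                                        sds = c(f_s = -1, f_l = 0,
                                                f_z = 0)),
               ">= 0")
})

test_that("campaign bundles round trip through the CSV writers", {
  camp <- generate_campaign(synthetic_lake_spec("stechlin_s", seed = 6))
  dir <- withr::local_tempdir()
  write_campaign(camp, dir)
  expect_true(all(file.exists(file.path(dir,
    c("hypsometry.csv", "temperature.csv", "ch4.csv", "wind.csv",
      "components.csv", "truth.json")))))
  hyp <- read_hypsometry(file.path(dir, "hypsometry.csv"))
  expect_equal(hyp$area_m2, camp$hypsometry$area_m2)
  temp <- read_profile_series(file.path(dir, "temperature.csv"),
                              "temperature")
  expect_equal(temp$values, unname(camp$temperature$values),
               ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$pnet, camp$truth$pnet)
})
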