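# Synthetic lakes and field campaigns with known ground truth ------------

#' Calibrated two-basin study hypsometries
#'
#' Piecewise-linear depth-area tables for the two study basins of a
#' Stechlin-like dimictic lake, calibrated so that a 6-m SML yields the
#' basin geometry used throughout: Northeast 2.0067 km^2 surface,
#' 11.2e6 m^3 SML volume, 0.28 km^2 littoral sediment; South 1.1228 km^2,
#' 5.7e6 m^3, 0.31 km^2. Synthetic reconstructions, not survey bathymetry.
#'
#' @param basin `"northeast"` or `"south"`.
#' @return hypsometry data frame (`depth_m`, `area_m2`) on a 1-m grid.
#' @export
stechlin_hypsometry <- function(basin = c("northeast", "south")) {
  basin <- match.arg(basin)
  if (basin == "northeast") {
    a0 <- 2006700; zmax <- 69.5
    a6 <- a0 - 6 * (6 * a0 - 11.2e6) / 18      # linear 0-6 m
    z <- c(0:69, zmax)
    a <- ifelse(z <= 6, a0 + (a6 - a0) * z / 6,
                a6 * (zmax - z) / (zmax - 6))
  } else {
    a0 <- 1122775; zmax <- 20.5
    a6 <- a0 - 310000
    a1 <- (5.7e6 - 0.5 * a0 - 2.5 * a6) / 3    # knot making V(6 m) = 5.7e6
    z <- c(0:20, zmax)
    a <- ifelse(z <= 1, a0 + (a1 - a0) * z,
         ifelse(z <= 6, a1 + (a6 - a1) * (z - 1) / 5,
                a6 * (zmax - z) / (zmax - 6)))
  }
  data.frame(depth_m = z, area_m2 = pmax(a, 0))
}

#' Specify a synthetic lake and field campaign
#'
#' Bundles the ground truths from which [generate_campaign()] synthesises a
#' self-consistent set of field observations: a steady-state SML methane
#' budget (production, lateral input, thermocline diffusion), a linear
#' k600-wind relation driving surface emission, and a stratified
#' temperature field evolving under a prescribed diffusivity profile.
#'
#' @param preset one of `"stechlin_ne"`, `"stechlin_s"`, `"enclosure"`,
#'   `"central_reservoir"`, or `NULL` for a fully custom spec.
#' @param seed mandatory RNG seed.
#' @param true_pnet net internal production, nmol l-1 d-1.
#' @param true_f_l lateral littoral flux, mmol m-2 d-1 (0 for enclosed
#'   columns).
#' @param true_k600 `c(slope, intercept)` of the k600-wind relation
#'   (cm h-1 per m s-1, cm h-1).
#' @param sml_thickness m.
#' @param hypsometry depth-area table; presets supply calibrated tables.
#' @param kz_profile function(depth) giving true K_z (m2 s-1).
#' @param alpha oxidised fraction of internal production.
#' @param noise list with `conc` (relative, CH4 profiles), `wind`
#'   (relative), `chamber` (lognormal sd of the chamber slope factor).
#'   All zero gives exact, noise-free observations.
#' @param n_days campaign length (days of hourly wind; profiles weekly).
#' @param n_chambers number of chamber deployments.
#' @return object of class `lake_campaign_spec`.
#' @export
synthetic_lake_spec <- function(preset = NULL, seed,
                                true_pnet = 80, true_f_l = 1.4,
                                true_k600 = c(1.98, 0.94),
                                sml_thickness = 6,
                                hypsometry = NULL,
                                kz_profile = NULL,
                                alpha = 0.3,
                                noise = list(conc = 0.05, wind = 0.05,
                                             chamber = 0.05),
                                n_days = 28, n_chambers = 7) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  name <- if (is.null(preset)) "custom" else preset
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("stechlin_ne", "stechlin_s", "enclosure",
                                  "central_reservoir"))
    if (preset == "stechlin_ne") {
      hypsometry <- stechlin_hypsometry("northeast")
      true_pnet <- 72
    } else if (preset == "stechlin_s") {
      hypsometry <- stechlin_hypsometry("south")
      true_pnet <- 88
    } else if (preset == "enclosure") {
      # 9-m-diameter column reaching the sediment; no littoral input
      r <- 4.5; zmax <- 20
      hypsometry <- data.frame(depth_m = 0:zmax,
                               area_m2 = rep(pi * r^2, zmax + 1))
      true_pnet <- 101; true_f_l <- 0
    } else {
      r <- 15; zmax <- 18
      hypsometry <- data.frame(depth_m = 0:zmax,
                               area_m2 = rep(pi * r^2, zmax + 1))
      true_pnet <- 2; true_f_l <- 0
    }
  }
  if (is.null(hypsometry))
    stop("custom spec needs a hypsometry", call. = FALSE)
  if (is.null(kz_profile)) {
    d <- sml_thickness
    kz_profile <- function(z) {
      # vigorous mixing near the surface, a broad quiet band reaching
      # ~1.2e-6 m2 s-1 well above the SML base, and the 1e-6
      # thermocline-top minimum at the base itself
      ifelse(z <= d - 6.5, 2e-5,
      ifelse(z <= d - 5,
             2e-5 * (1.2e-6 / 2e-5)^((z - (d - 6.5)) / 1.5),
      ifelse(z <= d, 1.2e-6 - 0.2e-6 * (z - (d - 5)) / 5,
             1.5e-6)))
    }
  }
  stopifnot(all(unlist(noise) >= 0), is.finite(true_pnet),
            is.finite(true_f_l))
  structure(list(name = name, seed = as.integer(seed),
                 true_pnet = true_pnet, true_f_l = true_f_l,
                 true_k600 = true_k600, sml_thickness = sml_thickness,
                 hypsometry = hypsometry, kz_profile = kz_profile,
                 alpha = alpha, noise = noise,
                 n_days = n_days, n_chambers = n_chambers),
            class = "lake_campaign_spec")
}

#' Forward finite-difference vertical diffusion of heat
#'
#' Conservative explicit scheme for the basin-averaged temperature field
#' dT/dt = (1/A) d/dz (K A dT/dz) on a uniform grid, with an optional
#' surface heat input applied to the top cell and an insulated bottom.
#' Used by the campaign generator and as the forward counterpart of the
#' heat-budget diffusivity inversion.
#'
#' @param temp0 initial temperature profile on `depths`.
#' @param depths uniform depth grid, m.
#' @param area planar area at each depth, m^2.
#' @param kz diffusivity, m2 s-1: scalar or per-depth vector.
#' @param days simulated duration.
#' @param dt_s time step, s (default 3600; must satisfy the explicit
#'   stability limit dt < dz^2 / (2 max K)).
#' @param surface_heat_c_d warming rate applied to the top cell, degrees C
#'   per day.
#' @param snapshot_days days at which to record profiles (default start and
#'   end).
#' @return matrix `length(depths) x length(snapshot_days)`.
#' @export
simulate_diffusion <- function(temp0, depths, area, kz, days,
                               dt_s = 3600, surface_heat_c_d = 0,
                               snapshot_days = c(0, days)) {
  nz <- length(depths)
  dz <- diff(depths)
  if (any(abs(dz - dz[1]) > 1e-9))
    stop("simulate_diffusion needs a uniform grid", call. = FALSE)
  dz <- dz[1]
  kz <- rep_len(kz, nz)
  if (dt_s >= dz^2 / (2 * max(kz)))
    stop("time step violates the explicit stability limit", call. = FALSE)
  k_face <- (kz[-nz] + kz[-1]) / 2
  a_face <- (area[-nz] + area[-1]) / 2
  n_steps <- ceiling(days * 86400 / dt_s)
  snap_step <- round(snapshot_days * 86400 / dt_s)
  out <- matrix(NA_real_, nz, length(snapshot_days))
  temp <- temp0
  for (s in 0:n_steps) {
    hit <- which(snap_step == s)
    if (length(hit)) out[, hit] <- temp
    if (s == n_steps) break
    flux <- -k_face * a_face * diff(temp) / dz        # downward heat flux
    div <- c(-flux[1], flux[-(nz - 1)] - flux[-1], flux[nz - 1])
    temp <- temp + dt_s * div / (area * dz)
    temp[1] <- temp[1] + surface_heat_c_d * dt_s / 86400
  }
  out
}

#' Generate a synthetic field campaign with ground-truth manifest
#'
#' Synthesises the full observation bundle a field season would produce,
#' self-consistently with the spec's truths under the steady-state SML
#' budget: the areal surface emission implied by the truths,
#' F_S = ((1-alpha) P_net V + F_L A_sed + F_z A_th) / A_tot, drives both
#' the chamber deployments (through the true k600-wind relation) and the
#' calibrated surface concentration, so that the wind-based emission
#' estimate recovers it.
#'
#' @param spec a [synthetic_lake_spec()].
#' @return list of class `lake_campaign`: `geometry`, `hypsometry`,
#'   `temperature` and `ch4` [profile_series()], `wind` (data frame),
#'   `chambers` (list of [chamber_deployment()] with deployment wind),
#'   `components` (Table-shaped data frame), and `truth` (manifest of every
#'   generating value).
#' @export
generate_campaign <- function(spec) {
  stopifnot(inherits(spec, "lake_campaign_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(spec$seed)

  geom <- derive_geometry(spec$hypsometry, spec$sml_thickness)
  d <- spec$sml_thickness
  zmax <- floor(max(spec$hypsometry$depth_m))
  depths <- 0:min(zmax, 20)
  area_at <- hypsometric_area_fun(spec$hypsometry)
  area <- pmax(area_at(depths), 1e-6)
  kz_true <- spec$kz_profile(depths)

  # temperature: warm SML over a logistic thermocline, evolved by diffusion
  temp0 <- 10 + 10 / (1 + exp(0.7 * (depths - d)))
  n_profiles <- max(2L, floor(spec$n_days / 7) + 1L)
  prof_days <- seq(0, spec$n_days, length.out = n_profiles)
  temp_mat <- simulate_diffusion(temp0, depths, area, kz_true,
                                 days = spec$n_days, dt_s = 1800,
                                 surface_heat_c_d = 0.08,
                                 snapshot_days = prof_days)
  dates <- as.Date("2016-06-01") + round(prof_days)
  temp_series <- profile_series(depths, dates, temp_mat, "temperature")

  # thermocline flux truth: the conservative window rule on the true K_z
  in_win <- depths >= d - 3 & depths <= d
  k_base <- max(kz_true[in_win])
  # SML plateau, thermocline peak, low deep water (Gaussian peak over a
  # logistic step down to hypolimnion background)
  peak_depth <- d + 2
  amp <- 800
  base <- 150 + 200 / (1 + exp(1.5 * (depths - peak_depth - 2)))
  ch4_prof <- base + amp * exp(-(depths - peak_depth)^2 / 2)
  grad_base <- ch4_prof[match(d + 1, depths)] - ch4_prof[match(d, depths)]
  true_f_z <- k_base * grad_base * 1e-3 * 86400       # mmol m-2 d-1

  ch4_mat <- sapply(seq_len(n_profiles), function(j) {
    pmax(ch4_prof * (1 + stats::rnorm(length(depths), 0,
                                      spec$noise$conc)), 0)
  })
  ch4_series <- profile_series(depths, dates, ch4_mat, "ch4")

  # steady-state emission implied by the truths (Eq. of the SML budget)
  true_f_s <- ((1 - spec$alpha) * spec$true_pnet * 1e-3 * geom$volume_sml +
                 spec$true_f_l * geom$A_sed + true_f_z * geom$A_th) /
    geom$A_tot

  # hourly wind and the surface concentration that reproduces true_f_s
  n_wind <- spec$n_days * 24
  u10_true <- pmax(3 + 1.2 * sin(seq_len(n_wind) * 2 * pi / 24) +
                     stats::rnorm(n_wind, 0, 0.8), 0)
  u10_obs <- pmax(u10_true * (1 + stats::rnorm(n_wind, 0,
                                               spec$noise$wind)), 0)
  temp_sfc <- 20
  atm_ppm <- 1.9
  sc <- schmidt_ch4(temp_sfc)
  k600_true <- spec$true_k600[1] * u10_true + spec$true_k600[2]
  k_ch4_m_d <- k600_true * (sc / 600)^(-0.5) * 24 / 100
  c_eq <- ch4_equilibrium(temp_sfc, atm_ppm)
  surface_conc <- c_eq + true_f_s / (mean(k_ch4_m_d) * 1e-3)  # nmol l-1

  # chamber deployments at random hours, fluxes from the true k600 chain
  dep_idx <- sort(sample.int(n_wind, spec$n_chambers))
  chambers <- lapply(dep_idx, function(i) {
    flux_i <- k_ch4_m_d[i] * (surface_conc - c_eq) * 1e-3  # mmol m-2 d-1
    if (spec$noise$chamber > 0)
      flux_i <- flux_i * stats::rlnorm(1, -spec$noise$chamber^2 / 2,
                                       spec$noise$chamber)
    times <- seq(0, 40, by = 10)
    footprint <- 0.07
    mmol <- flux_i * footprint * times / 1440
    t_k <- temp_sfc + 273.15
    ppm <- (mmol / 1000) * 8.31446 * t_k / (101325 * 15e-3) * 1e6 + atm_ppm
    list(deployment = chamber_deployment(times, ch4_ppm = ppm,
                                         chamber_volume_l = 15,
                                         footprint_area_m2 = footprint,
                                         water_temp_c = temp_sfc),
         u10 = u10_true[i])
  })

  components <- generate_component_table(
    means = c(f_s = true_f_s, f_l = spec$true_f_l, f_z = true_f_z),
    sds = c(f_s = true_f_s * 0.3, f_l = spec$true_f_l * 0.15,
            f_z = true_f_z * 0.5),
    unit = "mmol m-2 d-1", site = spec$name, season = "stratified")

  truth <- list(pnet = spec$true_pnet, f_l = spec$true_f_l,
                f_z = true_f_z, f_s = true_f_s,
                k600 = spec$true_k600, kz = kz_true, depths = depths,
                surface_conc = surface_conc, surface_temp_c = temp_sfc,
                atm_ppm = atm_ppm, alpha = spec$alpha,
                sml_thickness = d, seed = spec$seed)

  structure(list(spec = spec, geometry = geom,
                 hypsometry = spec$hypsometry,
                 temperature = temp_series, ch4 = ch4_series,
                 wind = data.frame(hour = seq_len(n_wind), u10 = u10_obs),
                 chambers = chambers, components = components,
                 truth = truth),
            class = "lake_campaign")
}

#' Emit a component table fixture
#'
#' Produces the `site, season, term, mean, sd, unit` data frame consumed by
#' [read_components()] and the mass-balance solvers.
#'
#' @param means named vector with `f_s`, `f_l`, `f_z`.
#' @param sds named vector, same names (default all zero).
#' @param unit component unit.
#' @param site,season metadata columns.
#' @return data frame in the component-CSV shape.
#' @export
generate_component_table <- function(means, sds = NULL,
                                     unit = "nmol l-1 d-1",
                                     site = "synthetic",
                                     season = "stratified") {
  terms <- c("f_s", "f_l", "f_z")
  if (!all(terms %in% names(means)))
    stop("means must name f_s, f_l, f_z", call. = FALSE)
  if (is.null(sds)) sds <- stats::setNames(rep(0, 3), terms)
  if (any(sds < 0)) stop("sds must be >= 0", call. = FALSE)
  data.frame(site = site, season = season, term = terms,
             mean = as.numeric(means[terms]),
             sd = as.numeric(sds[terms]), unit = unit)
}

#' Write a campaign bundle to disk
#'
#' Writes the CSV bundle (`hypsometry.csv`, `temperature.csv`, `ch4.csv`,
#' `wind.csv`, `chamber_<i>.csv`, `components.csv`) and the ground-truth
#' manifest `truth.json` into a directory. All writes are atomic
#' (temporary file + rename).
#'
#' @param campaign a [generate_campaign()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "lake_campaign"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- function(ps) {
    data.frame(date = rep(as.character(ps$dates),
                          each = length(ps$depths)),
               depth_m = rep(ps$depths, ncol(ps$values)),
               value = as.vector(ps$values))
  }
  atomic_write_csv(campaign$hypsometry, file.path(dir, "hypsometry.csv"))
  atomic_write_csv(long(campaign$temperature),
                   file.path(dir, "temperature.csv"))
  atomic_write_csv(long(campaign$ch4), file.path(dir, "ch4.csv"))
  atomic_write_csv(campaign$wind, file.path(dir, "wind.csv"))
  atomic_write_csv(campaign$components, file.path(dir, "components.csv"))
  for (i in seq_along(campaign$chambers)) {
    ch <- campaign$chambers[[i]]
    atomic_write_csv(
      data.frame(minutes = ch$deployment$times_min,
                 ch4_ppm = ch$deployment$ch4_ppm, u10 = ch$u10),
      file.path(dir, sprintf("chamber_%02d.csv", i)))
  }
  truth <- campaign$truth
  truth$kz <- NULL; truth$depths <- NULL   # profile stored in CSVs
  atomic_write_json(truth, file.path(dir, "truth.json"))
  invisible(dir)
}
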