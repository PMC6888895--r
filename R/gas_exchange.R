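# Air-water gas exchange: chamber fluxes and k600 wind models ------------

#' Schmidt number of methane in fresh water
#'
#' Wanninkhof (1992) freshwater polynomial,
#' Sc = 1897.8 - 114.28 T + 3.2902 T^2 - 0.039061 T^3 (T in degrees C).
#'
#' @param temp_c water temperature, degrees Celsius (valid ca. 0-30).
#' @return dimensionless Schmidt number.
#' @export
schmidt_ch4 <- function(temp_c) {
  1897.8 - 114.28 * temp_c + 3.2902 * temp_c^2 - 0.039061 * temp_c^3
}

#' Atmospheric-equilibrium methane concentration in fresh water
#'
#' Henry's-law solubility with a van 't Hoff temperature correction
#' (K_H = 1.4e-3 mol l-1 atm-1 at 25 degrees C, d ln K_H / d(1/T) = 1750 K;
#' Sander compilation values for CH4).
#'
#' @param temp_c water temperature, degrees Celsius.
#' @param atm_ppm atmospheric CH4 mixing ratio, ppm (default 1.9).
#' @return equilibrium concentration, nmol l-1.
#' @export
ch4_equilibrium <- function(temp_c, atm_ppm = 1.9) {
  t_k <- temp_c + 273.15
  kh <- 1.4e-3 * exp(1750 * (1 / t_k - 1 / 298.15))   # mol l-1 atm-1
  kh * atm_ppm * 1e-6 * 1e9                           # nmol l-1
}

#' Describe a floating-chamber deployment
#'
#' @param times_min sampling times, minutes since deployment (>= 3, strictly
#'   increasing).
#' @param ch4_ppm chamber headspace CH4 mixing ratio at each time (ppm).
#'   Either this or `ch4_mmol` must be given.
#' @param ch4_mmol trapped CH4 amount at each time (mmol), as an alternative
#'   to the mixing-ratio series.
#' @param chamber_volume_l chamber headspace volume, litres (15 as deployed).
#' @param footprint_area_m2 water surface area covered by the chamber, m^2.
#' @param water_temp_c surface water temperature, degrees C.
#' @return object of class `chamber_deployment`.
#' @export
chamber_deployment <- function(times_min, ch4_ppm = NULL, ch4_mmol = NULL,
                               chamber_volume_l = 15,
                               footprint_area_m2 = 0.07,
                               water_temp_c = 20) {
  if (length(times_min) < 3L)
    stop("chamber deployment needs at least 3 time points", call. = FALSE)
  if (any(diff(times_min) <= 0))
    stop("chamber times must be strictly increasing", call. = FALSE)
  if (is.null(ch4_ppm) == is.null(ch4_mmol))
    stop("give exactly one of `ch4_ppm` or `ch4_mmol`", call. = FALSE)
  conc <- if (is.null(ch4_ppm)) ch4_mmol else ch4_ppm
  if (length(conc) != length(times_min))
    stop("time and concentration series differ in length", call. = FALSE)
  if (any(conc < 0))
    stop("chamber concentrations must be non-negative", call. = FALSE)
  if (chamber_volume_l <= 0 || footprint_area_m2 <= 0)
    stop("chamber volume and footprint area must be positive", call. = FALSE)
  structure(list(times_min = as.numeric(times_min),
                 ch4_ppm = ch4_ppm, ch4_mmol = ch4_mmol,
                 chamber_volume_l = chamber_volume_l,
                 footprint_area_m2 = footprint_area_m2,
                 water_temp_c = water_temp_c),
            class = "chamber_deployment")
}

#' Areal methane flux from a floating-chamber deployment
#'
#' Fits a straight line to the trapped CH4 amount versus time; the slope per
#' unit footprint area is the air-water flux. Mixing-ratio series are turned
#' into amounts with the ideal gas law at 1 atm and the deployment's water
#' temperature. Negative fluxes (influx) are allowed.
#'
#' @param dep a [chamber_deployment()].
#' @return areal flux, mmol m-2 d-1.
#' @export
chamber_flux <- function(dep) {
  stopifnot(inherits(dep, "chamber_deployment"))
  mmol <- if (is.null(dep$ch4_mmol)) {
    t_k <- dep$water_temp_c + 273.15
    v_m3 <- dep$chamber_volume_l / 1000
    # ppm -> mol via n = x * P V / (R T), then mol -> mmol
    dep$ch4_ppm * 1e-6 * 101325 * v_m3 / (8.31446 * t_k) * 1000
  } else dep$ch4_mmol
  slope <- unname(stats::coef(stats::lm(mmol ~ dep$times_min))[2]) # mmol/min
  slope * 1440 / dep$footprint_area_m2
}

#' Gas transfer velocity k600 from a measured flux
#'
#' Inverts the bulk flux law k = F / (C_surface - C_eq) and normalises the
#' CH4 transfer velocity to a Schmidt number of 600:
#' k600 = k_CH4 * (Sc_CH4 / 600)^n.
#'
#' @param flux areal flux, mmol m-2 d-1.
#' @param surface_conc dissolved CH4 at the surface, nmol l-1.
#' @param temp_c surface water temperature, degrees C.
#' @param atm_ppm atmospheric mixing ratio, ppm.
#' @param sc_exponent Schmidt-number exponent n; 1/2 for a wavy free
#'   surface (default), 2/3 for a smooth surface.
#' @return k600 in cm h-1; `NA` (with a warning) when the air-water gradient
#'   vanishes together with the flux.
#' @export
k600_from_flux <- function(flux, surface_conc, temp_c, atm_ppm = 1.9,
                           sc_exponent = 0.5) {
  c_eq <- ch4_equilibrium(temp_c, atm_ppm)
  grad <- (surface_conc - c_eq) * 1e-3     # nmol l-1 -> mmol m-3
  if (abs(grad) < .Machine$double.eps * 1e3) {
    if (abs(flux) > 0)
      stop("nonzero flux with zero air-water gradient: k undefined",
           call. = FALSE)
    warning("zero flux and zero gradient: k600 indeterminate, returning NA")
    return(NA_real_)
  }
  k_ch4_m_d <- flux / grad
  k_ch4_cm_h <- k_ch4_m_d * 100 / 24
  k_ch4_cm_h * (schmidt_ch4(temp_c) / 600)^sc_exponent
}

#' Fit a linear k600 ~ wind-speed model
#'
#' Ordinary least squares of k600 (cm h-1) on 10-m wind speed U10 (m s-1),
#' the conventional parameterisation for low-wind lakes.
#'
#' @param u10 wind speeds, m s-1.
#' @param k600 gas transfer velocities, cm h-1.
#' @return object of class `k600_wind_model` with fields `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
fit_k600_wind <- function(u10, k600) {
  if (length(u10) != length(k600))
    stop("u10 and k600 differ in length", call. = FALSE)
  if (length(u10) < 2L)
    stop("need at least 2 (u10, k600) pairs", call. = FALSE)
  if (diff(range(u10)) == 0)
    stop("wind speeds are all equal: slope not identifiable", call. = FALSE)
  if (length(u10) == 2L)
    warning("only 2 pairs: exact interpolation, fit statistics meaningless")
  fit <- stats::lm(k600 ~ u10)
  sm <- suppressWarnings(summary(fit))   # noise-free input is legitimate
  ss_tot <- sum((k600 - mean(k600))^2)
  r2 <- if (ss_tot == 0) 0 else sm$r.squared
  pv <- if (nrow(sm$coefficients) > 1 && ncol(sm$coefficients) >= 4)
    sm$coefficients[2, 4] else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, p_value = pv, n = length(u10)),
            class = "k600_wind_model")
}

#' Create a k600 wind model from known coefficients
#'
#' Useful for applying published parameterisations (e.g. alternative
#' emission models) without refitting.
#'
#' @param slope cm h-1 per (m s-1).
#' @param intercept cm h-1.
#' @return `k600_wind_model`.
#' @export
k600_wind_model <- function(slope, intercept) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = NA_real_, p_value = NA_real_, n = NA_integer_),
            class = "k600_wind_model")
}

#' @export
print.k600_wind_model <- function(x, ...) {
  cat(sprintf("k600 [cm h-1] = %.3f * U10 [m s-1] + %.3f\n",
              x$slope, x$intercept))
  if (is.finite(x$r_squared))
    cat(sprintf("  R^2 = %.3f, p = %.3g, n = %d\n",
                x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Evaluate a k600 wind model
#'
#' @param model a `k600_wind_model`.
#' @param u10 wind speeds, m s-1 (>= 0).
#' @return k600 in cm h-1.
#' @export
predict_k600 <- function(model, u10) {
  stopifnot(inherits(model, "k600_wind_model"))
  if (any(u10 < 0)) stop("wind speed must be non-negative", call. = FALSE)
  model$slope * u10 + model$intercept
}

#' Wind-based surface methane emission estimate
#'
#' Applies a k600 wind model to a wind-speed series: per time step,
#' k600(U10) is rescaled to the CH4 transfer velocity via the Schmidt
#' number and multiplied by the air-water concentration gradient.
#'
#' @param model a `k600_wind_model`.
#' @param u10 wind-speed series, m s-1.
#' @param surface_conc dissolved surface CH4, nmol l-1 (scalar or series).
#' @param temp_c water temperature, degrees C (scalar or series).
#' @param atm_ppm atmospheric mixing ratio, ppm.
#' @param sc_exponent Schmidt-number exponent (see [k600_from_flux()]).
#' @return list with `mean`, `sd` (mmol m-2 d-1), and the per-step `flux`
#'   series.
#' @export
estimate_emission <- function(model, u10, surface_conc, temp_c,
                              atm_ppm = 1.9, sc_exponent = 0.5) {
  if (length(u10) == 0)
    stop("empty wind series", call. = FALSE)
  k600 <- predict_k600(model, u10)
  k_ch4_m_d <- k600 * (schmidt_ch4(temp_c) / 600)^(-sc_exponent) * 24 / 100
  grad <- (surface_conc - ch4_equilibrium(temp_c, atm_ppm)) * 1e-3
  flux <- k_ch4_m_d * grad
  list(mean = mean(flux),
       sd = if (length(flux) > 1) stats::sd(flux) else 0,
       flux = flux)
}
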