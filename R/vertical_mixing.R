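# Stratification, heat-budget diffusivity, thermocline CH4 flux ----------

#' Freshwater density from temperature
#'
#' UNESCO/Millero zero-salinity polynomial (kg m-3).
#'
#' @param temp_c temperature, degrees C.
#' @return density, kg m-3.
#' @export
water_density <- function(temp_c) {
  999.842594 + 6.793952e-2 * temp_c - 9.095290e-3 * temp_c^2 +
    1.001685e-4 * temp_c^3 - 1.120083e-6 * temp_c^4 + 6.536332e-9 * temp_c^5
}

#' Depth-by-date profile series
#'
#' Rectangular grid of one observed variable (temperature or dissolved CH4)
#' on a fixed depth grid over a set of sampling dates.
#'
#' @param depths depth grid, m, strictly increasing (1-m resolution in the
#'   field protocol this mirrors).
#' @param dates sampling dates (`Date` or numeric days).
#' @param values matrix `length(depths) x length(dates)`.
#' @param variable `"temperature"` or `"ch4"`; CH4 values must be
#'   non-negative.
#' @return object of class `profile_series`.
#' @export
profile_series <- function(depths, dates, values,
                           variable = c("temperature", "ch4")) {
  variable <- match.arg(variable)
  values <- as.matrix(values)
  if (any(diff(depths) <= 0))
    stop("depths must be strictly increasing", call. = FALSE)
  if (nrow(values) != length(depths) || ncol(values) != length(dates))
    stop("values matrix must be length(depths) x length(dates)",
         call. = FALSE)
  if (variable == "ch4" && any(values < 0, na.rm = TRUE))
    stop("negative CH4 concentrations", call. = FALSE)
  structure(list(depths = as.numeric(depths), dates = dates,
                 values = values, variable = variable),
            class = "profile_series")
}

#' Read a long-format profile CSV into a profile series
#'
#' Expects columns `date, depth_m, value` (ISO dates, dot decimal); the
#' depth grid must be identical on every date.
#'
#' @param path CSV path.
#' @param variable `"temperature"` or `"ch4"`.
#' @return [profile_series()].
#' @export
read_profile_series <- function(path, variable = c("temperature", "ch4")) {
  variable <- match.arg(variable)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "depth_m", "value") %in% names(d)))
    stop("profile CSV needs columns date, depth_m, value", call. = FALSE)
  dates <- sort(unique(d$date))
  depths <- sort(unique(d$depth_m))
  m <- matrix(NA_real_, length(depths), length(dates))
  for (j in seq_along(dates)) {
    sub <- d[d$date == dates[j], ]
    sub <- sub[order(sub$depth_m), ]
    if (!isTRUE(all.equal(sub$depth_m, depths)))
      stop("ragged depth grid on date ", dates[j], call. = FALSE)
    m[, j] <- sub$value
  }
  profile_series(depths, as.Date(dates), m, variable)
}

#' Buoyancy frequency squared from a temperature profile
#'
#' N^2 = (g / rho) * d rho / dz with depth positive downward, so stable
#' stratification (density increasing with depth) gives N^2 > 0. Density
#' from [water_density()]; centred differences in the interior, one-sided
#' at the boundaries.
#'
#' @param depths depth grid, m.
#' @param temp_c temperature profile, degrees C.
#' @return N^2 profile, s-2.
#' @export
buoyancy_frequency <- function(depths, temp_c) {
  if (length(depths) < 2L)
    stop("need at least 2 depths for a density gradient", call. = FALSE)
  if (length(depths) != length(temp_c))
    stop("depth and temperature lengths differ", call. = FALSE)
  rho <- water_density(temp_c)
  n <- length(depths)
  drho <- numeric(n)
  drho[1] <- (rho[2] - rho[1]) / (depths[2] - depths[1])
  drho[n] <- (rho[n] - rho[n - 1]) / (depths[n] - depths[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    drho[i] <- (rho[i + 1] - rho[i - 1]) / (depths[i + 1] - depths[i - 1])
  }
  9.81 / rho * drho
}

#' Basin-scale vertical diffusivity by the heat-budget method
#'
#' For each consecutive date pair, the rate of change of heat content below
#' depth z, divided by the area-weighted local temperature gradient, gives
#' the effective (basin-scale) vertical diffusivity:
#' K_z(z) = -[d/dt integral_z^zmax A(z') T(z') dz'] / [A(z) dT/dz].
#' Cells where |dT/dz| falls below `gradient_floor` are left undefined
#' (`NA`), not zero-filled: the method degenerates in weakly stratified
#' water.
#'
#' @param temp_series a temperature [profile_series()] with >= 2 dates.
#' @param geometry a [derive_geometry()] result whose hypsometry covers the
#'   profile depths.
#' @param gradient_floor minimum |dT/dz| (degrees C per m) for a defined
#'   estimate; default 0.01.
#' @return object of class `diffusivity_profile`: depths, a
#'   `depth x date-pair` matrix `K_z` (m2 s-1), the date-pair midpoints, and
#'   the method tag.
#' @export
heat_budget_diffusivity <- function(temp_series, geometry,
                                    gradient_floor = 0.01) {
  stopifnot(inherits(temp_series, "profile_series"),
            inherits(geometry, "lake_geometry"))
  if (ncol(temp_series$values) < 2L)
    stop("heat budget needs at least 2 dates", call. = FALSE)
  z <- temp_series$depths
  area_at <- hypsometric_area_fun(geometry$hypsometry)
  A <- area_at(z)
  if (any(A <= 0))
    stop("zero planar area at a profile depth", call. = FALSE)
  nd <- ncol(temp_series$values)
  nz <- length(z)

  # heat content (temperature-weighted volume) below each grid depth
  heat_below <- function(temp) {
    f <- A * temp
    seg <- diff(z) * (utils::head(f, -1) + utils::tail(f, -1)) / 2
    rev(cumsum(rev(c(seg, 0))))
  }

  kz <- matrix(NA_real_, nz, nd - 1)
  for (j in seq_len(nd - 1)) {
    t1 <- temp_series$values[, j]
    t2 <- temp_series$values[, j + 1]
    dt_days <- as.numeric(temp_series$dates[j + 1]) -
      as.numeric(temp_series$dates[j])
    dhdt <- (heat_below(t2) - heat_below(t1)) / (dt_days * 86400)
    tm <- (t1 + t2) / 2
    dtdz <- numeric(nz)
    dtdz[1] <- (tm[2] - tm[1]) / (z[2] - z[1])
    dtdz[nz] <- (tm[nz] - tm[nz - 1]) / (z[nz] - z[nz - 1])
    if (nz > 2) {
      i <- 2:(nz - 1)
      dtdz[i] <- (tm[i + 1] - tm[i - 1]) / (z[i + 1] - z[i - 1])
    }
    ok <- abs(dtdz) >= gradient_floor
    kz[ok, j] <- -dhdt[ok] / (A[ok] * dtdz[ok])
  }
  structure(list(depths = z, K_z = kz,
                 dates = temp_series$dates, method = "heat_budget",
                 gradient_floor = gradient_floor),
            class = "diffusivity_profile")
}

#' Diffusive methane flux across the SML base (Fick's first law)
#'
#' F_z = K_z * dC/dz with the 1-m finite-difference concentration gradient
#' at the SML base and K_z taken as the maximum defined value within the
#' bottom 3 m of the SML (a conservative choice for the input to the SML).
#' Sign convention: concentration increasing downward (thermocline CH4 peak
#' below the SML) yields a positive flux into the SML.
#'
#' @param kz a `diffusivity_profile` (columns are averaged per depth) or a
#'   list with `depths` and a `K_z` vector.
#' @param ch4_depths,ch4_conc CH4 profile: depths (m) and concentrations
#'   (nmol l-1) covering `[sml_thickness - 3, sml_thickness + 1]`.
#' @param sml_thickness SML thickness, m.
#' @return flux in mmol m-2 d-1, or `NA` with a warning when no defined
#'   K_z exists in the window.
#' @export
thermocline_flux <- function(kz, ch4_depths, ch4_conc, sml_thickness) {
  kz_vec <- if (inherits(kz, "diffusivity_profile"))
    rowMeans(kz$K_z, na.rm = TRUE) else kz$K_z
  kz_depths <- kz$depths
  if (min(ch4_depths) > sml_thickness - 1 ||
      max(ch4_depths) < sml_thickness + 1)
    stop("CH4 profile must cover the SML base +/- 1 m", call. = FALSE)
  in_window <- kz_depths >= sml_thickness - 3 & kz_depths <= sml_thickness
  k_vals <- kz_vec[in_window]
  k_vals <- k_vals[is.finite(k_vals)]
  if (length(k_vals) == 0) {
    warning("no defined K_z within the bottom 3 m of the SML; flux undefined")
    return(NA_real_)
  }
  k <- max(k_vals)                                   # m2 s-1
  c_at <- stats::approx(ch4_depths, ch4_conc,
                        xout = c(sml_thickness, sml_thickness + 1))$y
  grad <- (c_at[2] - c_at[1]) / 1                    # nmol l-1 per m
  k * grad * 1e-3 * 86400                            # mmol m-2 d-1, into SML
}
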