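# Unit system for methane budget terms -----------------------------------

# molar mass of CH4, g mol^-1
CH4_MOLAR_MASS <- 16.04

.rate_units <- c("mol d-1", "kg d-1", "nmol l-1 d-1", "mmol m-2 d-1")

#' Construct a methane rate quantity
#'
#' A `quantity` couples a numeric value to one of the units used in the
#' mass-balance bookkeeping: whole-system rates (`"mol d-1"`, `"kg d-1"`),
#' per-volume rates (`"nmol l-1 d-1"`), and areal fluxes (`"mmol m-2 d-1"`).
#'
#' @param value numeric scalar (or vector).
#' @param unit one of `"mol d-1"`, `"kg d-1"`, `"nmol l-1 d-1"`,
#'   `"mmol m-2 d-1"`.
#' @return object of class `quantity`.
#' @export
quantity <- function(value, unit) {
  unit <- match.arg(unit, .rate_units)
  if (!is.numeric(value)) stop("`value` must be numeric", call. = FALSE)
  structure(list(value = value, unit = unit), class = "quantity")
}

#' @export
print.quantity <- function(x, ...) {
  cat(format(x$value, digits = 6), x$unit, "\n")
  invisible(x)
}

#' Convert a methane rate between unit systems
#'
#' Whole-system <-> mass conversions use the CH4 molar mass (16.04 g/mol).
#' Whole-system <-> per-volume conversions divide/multiply by the SML volume;
#' whole-system <-> areal conversions use the planar area selected by
#' `area`. Round trips are exact to floating-point precision.
#'
#' @param q a [quantity()].
#' @param target_unit unit to convert to.
#' @param geometry a [derive_geometry()] result; required whenever the
#'   conversion passes through a per-volume or areal unit.
#' @param area which planar area scales an areal flux: `"surface"` (A_tot),
#'   `"thermocline"` (A_th) or `"sediment"` (A_sed).
#' @return converted `quantity`.
#' @examples
#' hyp <- data.frame(depth_m = 0:10, area_m2 = rep(2e6, 11))
#' g <- derive_geometry(hyp, 6)
#' convert(quantity(752, "mol d-1"), "kg d-1")
#' @export
convert <- function(q, target_unit, geometry = NULL,
                    area = c("surface", "thermocline", "sediment")) {
  if (!inherits(q, "quantity")) stop("`q` must be a quantity", call. = FALSE)
  target_unit <- match.arg(target_unit, .rate_units)
  area <- match.arg(area)
  if (q$unit == target_unit) return(q)

  needs_geom <- any(c(q$unit, target_unit) %in%
                      c("nmol l-1 d-1", "mmol m-2 d-1"))
  if (needs_geom && !inherits(geometry, "lake_geometry"))
    stop("geometry required for per-volume or areal conversions",
         call. = FALSE)

  # hub unit: mol d-1 (whole system)
  to_mol <- switch(q$unit,
    "mol d-1" = q$value,
    "kg d-1" = q$value * 1000 / CH4_MOLAR_MASS,
    # nmol l-1 d-1 = 1e-6 mol m-3 d-1
    "nmol l-1 d-1" = q$value * 1e-6 * geometry$volume_sml,
    "mmol m-2 d-1" = q$value * 1e-3 * pick_area(geometry, area))
  out <- switch(target_unit,
    "mol d-1" = to_mol,
    "kg d-1" = to_mol * CH4_MOLAR_MASS / 1000,
    "nmol l-1 d-1" = to_mol / (1e-6 * geometry$volume_sml),
    "mmol m-2 d-1" = to_mol / (1e-3 * pick_area(geometry, area)))
  quantity(out, target_unit)
}

pick_area <- function(geometry, area) {
  switch(area,
         surface = geometry$A_tot,
         thermocline = geometry$A_th,
         sediment = geometry$A_sed)
}
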