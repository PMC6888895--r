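# Oxic methane contribution and its morphometric scaling -----------------

#' Oxic methane contribution (OMC) to SML methane sources
#'
#' Percentage of the total surface-mixed-layer methane supply attributable
#' to internal (oxic) production:
#' OMC = 100 * P / (P + L + Z), with the whole-system source terms
#' P = P_net * V, L = A_sed * F_L, Z = A_th * F_z (all in the same unit,
#' e.g. mol d-1).
#'
#' @param production whole-system internal production (P_net * V).
#' @param lateral whole-system lateral littoral input (A_sed * F_L).
#' @param diffusive whole-system thermocline diffusive input (A_th * F_z).
#' @return OMC in percent.
#' @examples
#' omc(752, 372, 56)   # Northeast-basin style source partition
#' @export
omc <- function(production, lateral, diffusive) {
  total <- production + lateral + diffusive
  if (any(!is.finite(c(production, lateral, diffusive))))
    stop("non-finite source term", call. = FALSE)
  if (any(total <= 0))
    stop("total methane source must be positive for OMC", call. = FALSE)
  100 * production / total
}

#' Exponential OMC ~ morphometry scaling model
#'
#' Represents OMC = a * exp(-b * x), where x is the ratio of littoral
#' sediment area to SML volume (m2 m-3) or, in the surface-area variant,
#' the lake surface area.
#'
#' @param a intercept, percent (OMC of a hypothetical basin with x = 0).
#' @param b decay constant per unit of the predictor.
#' @param predictor `"ased_over_volume"` or `"surface_area"`.
#' @return object of class `omc_scaling_model`.
#' @export
omc_model <- function(a, b, predictor = c("ased_over_volume",
                                          "surface_area")) {
  predictor <- match.arg(predictor)
  if (a <= 0 || a > 100) stop("a must be in (0, 100]", call. = FALSE)
  structure(list(a = a, b = b, r_squared = NA_real_, p_value = NA_real_,
                 standard_error = NA_real_, n = NA_integer_,
                 predictor = predictor),
            class = "omc_scaling_model")
}

#' Fit the exponential OMC scaling model by linearised least squares
#'
#' Ordinary least squares of ln(OMC) on the predictor; a = exp(intercept),
#' b = -slope. R-squared and the p value are reported on the linearised
#' (log) scale; the standard error is reported in OMC percentage points
#' (residual standard error of the back-transformed curve).
#'
#' @param x predictor values (A_sed / V in m2 m-3), x >= 0.
#' @param omc_percent observed OMC in (0, 100].
#' @param predictor which morphometric predictor `x` represents.
#' @return an `omc_scaling_model` with fit statistics.
#' @examples
#' x <- c(0.01, 0.05, 0.1, 0.2)
#' fit_omc_model(x, 87.49 * exp(-7.61 * x))
#' @export
fit_omc_model <- function(x, omc_percent,
                          predictor = c("ased_over_volume",
                                        "surface_area")) {
  predictor <- match.arg(predictor)
  if (length(x) != length(omc_percent))
    stop("x and omc lengths differ", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 points to fit the scaling model", call. = FALSE)
  if (any(omc_percent <= 0))
    stop("OMC must be positive: log-linearisation undefined at 0",
         call. = FALSE)
  if (any(x < 0)) stop("predictor must be non-negative", call. = FALSE)
  fit <- stats::lm(log(omc_percent) ~ x)
  sm <- suppressWarnings(summary(fit))   # exact exponential data is valid
  a <- exp(unname(stats::coef(fit)[1]))
  b <- -unname(stats::coef(fit)[2])
  pred <- a * exp(-b * x)
  se_pct <- sqrt(sum((omc_percent - pred)^2) /
                   max(length(x) - 2L, 1L))
  ss_tot <- sum((log(omc_percent) - mean(log(omc_percent)))^2)
  r2 <- if (ss_tot == 0) 0 else sm$r.squared
  m <- omc_model(min(a, 100), b, predictor)
  m$a <- a   # keep unclamped estimate; predictions clamp instead
  m$r_squared <- r2
  m$p_value <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4]
  else NA_real_
  m$standard_error <- se_pct
  m$n <- length(x)
  m
}

#' @export
print.omc_scaling_model <- function(x, ...) {
  cat(sprintf("OMC [%%] = %.2f * exp(-%.2f * x)   [x: %s]\n",
              x$a, x$b, x$predictor))
  if (is.finite(x$r_squared))
    cat(sprintf("  R^2 = %.2f (log scale), p = %.2g, SE = %.1f %%-points, n = %d\n",
                x$r_squared, x$p_value, x$standard_error, x$n))
  invisible(x)
}

#' Predict OMC from the scaling model
#'
#' @param model an `omc_scaling_model`.
#' @param x predictor values.
#' @return predicted OMC, clamped to `[0, 100]` percent.
#' @export
predict_omc <- function(model, x) {
  stopifnot(inherits(model, "omc_scaling_model"))
  pmin(pmax(model$a * exp(-model$b * x), 0), 100)
}

#' Predictor value at which the model crosses a target OMC
#'
#' Solves a * exp(-b x) = target for x: x = ln(a / target) / b. The
#' default target of 50 percent marks the morphometry below which oxic
#' production dominates the SML methane supply.
#'
#' @param model an `omc_scaling_model`.
#' @param target target OMC in percent, in (0, a].
#' @return threshold predictor value x*.
#' @examples
#' omc_threshold(omc_model(87.49, 7.61))
#' @export
omc_threshold <- function(model, target = 50) {
  stopifnot(inherits(model, "omc_scaling_model"))
  if (target <= 0 || target > model$a)
    stop("target must lie in (0, a]: no solution otherwise", call. = FALSE)
  log(model$a / target) / model$b
}

#' Emulated global lake size-class inventory
#'
#' A power-law size-abundance inventory spanning 0.01 to 1e5 km^2,
#' consistent in shape and total area (~4e6 km^2) with satellite-based
#' global lake censuses. Synthetic: class counts are rounded power-law
#' abundances, not a published census.
#'
#' @return data frame with columns `area_min_km2`, `area_max_km2`, `count`,
#'   `mean_area_km2`.
#' @export
default_lake_inventory <- function() {
  data.frame(
    area_min_km2 = c(0.01, 0.1, 1, 10, 100, 1e3, 1e4),
    area_max_km2 = c(0.1, 1, 10, 100, 1e3, 1e4, 1e5),
    count = c(2.6e7, 2.6e6, 2.6e5, 2.4e4, 1.5e3, 130, 10),
    mean_area_km2 = c(0.03, 0.3, 3, 30, 300, 3e3, 3e4))
}

#' Map lake surface area to the morphometric predictor
#'
#' Default allometry x = 0.063 * A^(-1.33) (A in km^2, x in m2 m-3),
#' calibrated so the two study basins (2.01 km^2 at x = 0.025; 1.12 km^2 at
#' x = 0.054, 6-m SML) lie on the curve. Larger lakes grow SML volume
#' faster than littoral sediment area, so x falls with size.
#'
#' @param area_km2 lake surface area, km^2.
#' @return A_sed / V predictor, m2 m-3.
#' @export
area_to_ased_ratio <- function(area_km2) {
  0.063 * area_km2^(-1.33)
}

#' Upscale OMC over a global lake inventory
#'
#' Emission-weighted mean of per-size-class OMC predictions:
#' each class is represented by its mean lake area, mapped to the model
#' predictor by `geometry_rule`, and weighted by total class lake area
#' times an areal emission intensity (constant by default, or per-class via
#' an `emission_mmol_m2_d` column).
#'
#' @param inventory data frame as from [default_lake_inventory()].
#' @param model an `omc_scaling_model`.
#' @param geometry_rule function mapping mean lake area (km^2) to the model
#'   predictor; defaults to [area_to_ased_ratio()] for the
#'   `ased_over_volume` predictor and identity for `surface_area`.
#' @return list with `global_omc` (percent), and the per-class table
#'   (`omc`, `weight`).
#' @export
global_upscale <- function(inventory, model, geometry_rule = NULL) {
  stopifnot(inherits(model, "omc_scaling_model"))
  need <- c("area_min_km2", "area_max_km2", "count", "mean_area_km2")
  if (!all(need %in% names(inventory)))
    stop("inventory needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(inventory$count < 0))
    stop("negative lake counts", call. = FALSE)
  if (is.unsorted(inventory$area_min_km2) ||
      any(inventory$area_min_km2[-1] <
            inventory$area_max_km2[-nrow(inventory)]))
    stop("size classes must be ordered and non-overlapping", call. = FALSE)
  if (is.null(geometry_rule))
    geometry_rule <- if (model$predictor == "ased_over_volume")
      area_to_ased_ratio else identity
  x <- geometry_rule(inventory$mean_area_km2)
  omc_class <- predict_omc(model, x)
  intensity <- if ("emission_mmol_m2_d" %in% names(inventory))
    inventory$emission_mmol_m2_d else rep(1, nrow(inventory))
  weight <- inventory$count * inventory$mean_area_km2 * intensity
  if (sum(weight) <= 0)
    stop("zero total emission weight", call. = FALSE)
  list(global_omc = sum(weight * omc_class) / sum(weight),
       classes = cbind(inventory, x = x, omc = omc_class, weight = weight))
}

#' Read an OMC scaling points CSV
#'
#' Columns `lake, x_value, omc_percent[, omc_lo, omc_hi]`; when a lake is
#' reported as a range (`omc_lo`/`omc_hi`), its midpoint replaces
#' `omc_percent` (the convention used for literature lakes reported as
#' intervals).
#'
#' @param path CSV path.
#' @return data frame with `lake`, `x_value`, `omc_percent`.
#' @export
read_omc_points <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lake", "x_value", "omc_percent") %in% names(d)))
    stop("points CSV needs columns lake, x_value, omc_percent",
         call. = FALSE)
  if (all(c("omc_lo", "omc_hi") %in% names(d))) {
    has_range <- !is.na(d$omc_lo) & !is.na(d$omc_hi)
    d$omc_percent[has_range] <-
      (d$omc_lo[has_range] + d$omc_hi[has_range]) / 2
  }
  d[c("lake", "x_value", "omc_percent")]
}
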