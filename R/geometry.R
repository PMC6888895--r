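# Lake geometry from hypsometry ------------------------------------------

#' Derive SML geometry from a hypsometric (depth-area) table
#'
#' Computes the morphometric quantities that scale the surface mixed layer
#' (SML) methane mass balance: total surface area `A_tot`, planar area at the
#' SML base `A_th`, littoral sediment area within the SML `A_sed`, and SML
#' volume `volume_sml`.
#'
#' The hypsometry is treated as piecewise linear in depth. The SML volume is
#' the trapezoidal integral of planar area from the surface down to
#' `sml_thickness`. `A_sed` is, by default, the lateral sediment surface of
#' the basin between the surface and the SML base, computed as the summed
#' lateral surface of the conical frusta obtained from equivalent-circle
#' radii \eqn{r(z) = \sqrt{A(z)/\pi}}. With `a_sed_method = "planar"` the
#' simpler planar-annulus convention \eqn{A_{tot} - A_{th}} is used instead;
#' for basins with moderately steep littoral slopes the two agree closely.
#'
#' @param hypsometry data frame with numeric columns `depth_m` (m, positive
#'   downward, starting at 0) and `area_m2` (planar area, m^2),
#'   non-increasing with depth.
#' @param sml_thickness SML thickness (thermocline top depth) in m; must lie
#'   strictly inside the depth range of the table.
#' @param a_sed_method `"frustum"` (default) or `"planar"`.
#' @return An object of class `lake_geometry`: a list with `hypsometry`,
#'   `sml_thickness`, `A_tot`, `A_th`, `A_sed`, `volume_sml` (all m^2 / m^3).
#' @examples
#' hyp <- data.frame(depth_m = 0:10, area_m2 = seq(2e6, 1e6, length.out = 11))
#' g <- derive_geometry(hyp, sml_thickness = 6)
#' g$volume_sml
#' @export
derive_geometry <- function(hypsometry, sml_thickness,
                            a_sed_method = c("frustum", "planar")) {
  a_sed_method <- match.arg(a_sed_method)
  hypsometry <- validate_hypsometry(hypsometry)
  d <- sml_thickness
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d))
    stop("`sml_thickness` must be a single finite number", call. = FALSE)
  if (d <= min(hypsometry$depth_m) || d >= max(hypsometry$depth_m))
    stop("`sml_thickness` (", d, " m) outside hypsometry depth range",
         call. = FALSE)

  area_at <- hypsometric_area_fun(hypsometry)
  A_tot <- area_at(min(hypsometry$depth_m))
  A_th <- area_at(d)

  # knots of the piecewise-linear area function inside [0, d]
  z <- sort(unique(c(hypsometry$depth_m[hypsometry$depth_m < d], d)))
  z <- z[z >= 0]
  a <- area_at(z)
  volume_sml <- sum(diff(z) * (utils::head(a, -1) + utils::tail(a, -1)) / 2)

  A_sed <- switch(a_sed_method,
    planar = A_tot - A_th,
    frustum = {
      r <- sqrt(a / pi)
      dr <- diff(r)
      dz <- diff(z)
      sum(pi * (utils::head(r, -1) + utils::tail(r, -1)) *
            sqrt(dr^2 + dz^2))
    })

  if (!all(is.finite(c(A_tot, A_th, A_sed, volume_sml))) ||
      any(c(A_tot, A_th, volume_sml) <= 0))
    stop("degenerate geometry: non-positive or non-finite area/volume",
         call. = FALSE)

  structure(
    list(hypsometry = hypsometry, sml_thickness = d,
         A_tot = A_tot, A_th = A_th, A_sed = A_sed,
         volume_sml = volume_sml, a_sed_method = a_sed_method),
    class = "lake_geometry")
}

#' @export
print.lake_geometry <- function(x, ...) {
  cat("Lake SML geometry (", x$a_sed_method, " A_sed convention)\n", sep = "")
  cat(sprintf("  SML thickness : %.2f m\n", x$sml_thickness))
  cat(sprintf("  A_tot         : %.4g km^2\n", x$A_tot / 1e6))
  cat(sprintf("  A_th          : %.4g km^2\n", x$A_th / 1e6))
  cat(sprintf("  A_sed         : %.4g km^2\n", x$A_sed / 1e6))
  cat(sprintf("  SML volume    : %.4g m^3\n", x$volume_sml))
  invisible(x)
}

validate_hypsometry <- function(hypsometry) {
  if (!is.data.frame(hypsometry) ||
      !all(c("depth_m", "area_m2") %in% names(hypsometry)))
    stop("hypsometry must be a data frame with columns `depth_m`, `area_m2`",
         call. = FALSE)
  h <- hypsometry[order(hypsometry$depth_m), c("depth_m", "area_m2")]
  if (nrow(h) < 2L)
    stop("hypsometry needs at least two depth levels", call. = FALSE)
  if (anyNA(h) || any(!is.finite(h$depth_m)) || any(!is.finite(h$area_m2)))
    stop("hypsometry contains missing or non-finite values", call. = FALSE)
  if (any(h$area_m2 < 0))
    stop("hypsometry areas must be non-negative", call. = FALSE)
  if (any(diff(h$area_m2) > 0))
    stop("hypsometry area must be non-increasing with depth", call. = FALSE)
  if (anyDuplicated(h$depth_m))
    stop("hypsometry has duplicated depths", call. = FALSE)
  rownames(h) <- NULL
  h
}

# linear interpolator A(z); rule = 1 errors outside the table via NA check
hypsometric_area_fun <- function(hypsometry) {
  function(z) {
    a <- stats::approx(hypsometry$depth_m, hypsometry$area_m2, xout = z,
                       rule = 1)$y
    if (anyNA(a))
      stop("depth outside hypsometry range", call. = FALSE)
    a
  }
}

#' Read a hypsometry CSV
#'
#' Expects a UTF-8, comma-separated file with mandatory header columns
#' `depth_m, area_m2` (dot decimal separator).
#'
#' @param path path to the CSV file.
#' @return validated hypsometry data frame ordered by depth.
#' @export
read_hypsometry <- function(path) {
  h <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_hypsometry(h)
}
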