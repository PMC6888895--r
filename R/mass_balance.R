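# SML methane mass balance: steady-state solvers and Monte Carlo ---------

#' Mass-balance configuration
#'
#' Encodes the seasonal parameterisation of the SML methane budget:
#' during stratification, methane oxidation (MOx) is modelled as a fixed
#' fraction `alpha` (default 0.3) of internal production and lateral
#' littoral input is active; outside stratification both are set to zero.
#' River throughflow and ebullition are fixed at zero for the deep,
#' river-free systems this balance targets.
#'
#' @param season `"stratified"` or `"non_stratified"`.
#' @param alpha oxidised fraction of internal production in `[0, 1)`;
#'   defaults to 0.3 (stratified) or 0 (non-stratified, forced).
#' @param mox_scope `"internal_only"` applies the oxidation closure to
#'   internal production alone (MOx = alpha * P_net);
#'   `"internal_plus_lateral"` applies it to the combined gross SML methane
#'   requirement, the closure used when deriving lateral input by enclosure
#'   comparison.
#' @param steady_state if `TRUE` (default) the storage term dC/dt is zero.
#' @param dc_dt storage term when not at steady state, in the same unit
#'   track as the components (per-volume: nmol l-1 d-1; whole-system:
#'   mol d-1).
#' @return object of class `balance_config`.
#' @export
balance_config <- function(season = c("stratified", "non_stratified"),
                           alpha = NULL,
                           mox_scope = c("internal_only",
                                         "internal_plus_lateral"),
                           steady_state = TRUE, dc_dt = 0) {
  season <- match.arg(season)
  mox_scope <- match.arg(mox_scope)
  if (is.null(alpha)) alpha <- if (season == "stratified") 0.3 else 0
  if (season == "non_stratified" && alpha != 0) {
    warning("non-stratified season forces alpha = 0")
    alpha <- 0
  }
  if (alpha < 0 || alpha >= 1)
    stop("alpha must lie in [0, 1): alpha = 1 makes the closure singular",
         call. = FALSE)
  if (steady_state) dc_dt <- 0
  structure(list(season = season, alpha = alpha, mox_scope = mox_scope,
                 steady_state = steady_state, dc_dt = dc_dt),
            class = "balance_config")
}

#' Mass-balance component set
#'
#' Means and standard deviations of the measured budget terms: surface
#' emission `F_S`, lateral littoral input `F_L`, and diffusive thermocline
#' input `F_z`, in one consistent unit track.
#'
#' @param f_s,f_l,f_z numeric length-2 vectors `c(mean, sd)` (a scalar is
#'   taken as a mean with sd 0).
#' @param unit `"nmol l-1 d-1"` (per-volume), `"mol d-1"` (whole-system) or
#'   `"mmol m-2 d-1"` (areal; requires geometry downstream).
#' @return object of class `flux_components`.
#' @export
flux_components <- function(f_s, f_l = c(0, 0), f_z = c(0, 0),
                            unit = c("nmol l-1 d-1", "mol d-1",
                                     "mmol m-2 d-1")) {
  unit <- match.arg(unit)
  pad <- function(x, nm) {
    if (length(x) == 1L) x <- c(x, 0)
    if (length(x) != 2L || anyNA(x) || any(!is.finite(x)))
      stop(nm, " must be c(mean, sd)", call. = FALSE)
    if (x[2] < 0) stop(nm, " sd must be >= 0", call. = FALSE)
    stats::setNames(as.numeric(x), c("mean", "sd"))
  }
  structure(list(f_s = pad(f_s, "f_s"), f_l = pad(f_l, "f_l"),
                 f_z = pad(f_z, "f_z"), unit = unit),
            class = "flux_components")
}

# core closure, vectorised over component draws; returns P_net in the
# per-volume (nmol l-1 d-1) or whole-system (mol d-1) track of the inputs
.pnet_closure <- function(fs, fl, fz, unit, cfg, geometry) {
  a <- cfg$alpha
  if (unit == "mmol m-2 d-1") {
    if (inherits(geometry, "lake_geometry")) {
      num <- fs * geometry$A_tot - fl * geometry$A_sed - fz * geometry$A_th
      # mmol d-1 over m3 -> mmol m-3 d-1 == umol l-1 d-1 -> nmol l-1 d-1
      (num / geometry$volume_sml + cfg$dc_dt * 1e-3) / (1 - a) * 1e3
    } else if (is.numeric(geometry) && length(geometry) == 1L) {
      # enclosure / unit water column of depth d: areas cancel, no lateral
      d <- geometry
      ((fs - fl - fz) / d + cfg$dc_dt * 1e-3) / (1 - a) * 1e3
    } else {
      stop("areal components need a lake_geometry or an SML depth",
           call. = FALSE)
    }
  } else {
    (fs - fl - fz + cfg$dc_dt) / (1 - a)
  }
}

#' Solve the steady-state SML methane balance for internal production
#'
#' Solves the whole-basin budget
#' dC/dt * V = A_th F_z + A_sed F_L + P_net V - (MOx V + A_tot F_S)
#' for the net internal (oxic) production `P_net`, with MOx = alpha * P_net.
#' In the per-volume and whole-system tracks the planar areas are already
#' folded into the component values and the closure reduces to
#' P_net = (F_S - F_L - F_z + dC/dt) / (1 - alpha).
#'
#' @param components a [flux_components()] set.
#' @param geometry a [derive_geometry()] result (required for areal
#'   components), or a single SML thickness in m for a laterally-enclosed
#'   water column (areas cancel).
#' @param cfg a [balance_config()].
#' @return a [quantity()]: nmol l-1 d-1 for per-volume or areal inputs,
#'   mol d-1 for whole-system inputs.
#' @examples
#' comp <- flux_components(f_s = 90, f_l = 36, f_z = 5)
#' solve_pnet(comp, cfg = balance_config("stratified"))
#' @export
solve_pnet <- function(components, geometry = NULL,
                       cfg = balance_config()) {
  stopifnot(inherits(components, "flux_components"),
            inherits(cfg, "balance_config"))
  if (cfg$season == "non_stratified" && components$f_l[["mean"]] != 0)
    warning("non-stratified balance with nonzero lateral input")
  val <- .pnet_closure(components$f_s[["mean"]], components$f_l[["mean"]],
                       components$f_z[["mean"]], components$unit, cfg,
                       geometry)
  unit_out <- if (components$unit == "mol d-1") "mol d-1" else "nmol l-1 d-1"
  quantity(val, unit_out)
}

#' Derive lateral littoral methane input by enclosure comparison
#'
#' Enclosures shielded from the shore receive no lateral input, so their
#' budget yields the internal production alone; the open water adjacent to
#' them receives both. The difference between the open-water gross SML
#' methane requirement, (F_S - F_z) / ((1 - alpha) d), and the
#' enclosure-derived production is the volumetric lateral input. Here the
#' oxidation closure necessarily spans internal plus lateral methane
#' (`mox_scope = "internal_plus_lateral"`).
#'
#' @param f_s_open,f_z_open open-water surface emission and thermocline
#'   flux, mmol m-2 d-1.
#' @param pnet_enclosure enclosure internal production, nmol l-1 d-1.
#' @param geometry [derive_geometry()] result for the open basin (its
#'   `sml_thickness`, `volume_sml` and `A_sed` are used).
#' @param cfg a [balance_config()]; `alpha` is taken from it.
#' @return list with `lateral_volumetric` (nmol l-1 d-1), `f_l_areal`
#'   (mmol m-2 d-1) and `negative` flag (physically questionable result).
#' @export
solve_lateral <- function(f_s_open, f_z_open, pnet_enclosure, geometry,
                          cfg = balance_config(
                            mox_scope = "internal_plus_lateral")) {
  stopifnot(inherits(geometry, "lake_geometry"),
            inherits(cfg, "balance_config"))
  d <- geometry$sml_thickness
  gross <- (f_s_open - f_z_open) / ((1 - cfg$alpha) * d) * 1e3 # nmol l-1 d-1
  lateral <- gross - pnet_enclosure
  if (lateral < 0)
    warning("negative lateral input: open water below enclosure production")
  f_l <- lateral * 1e-3 * geometry$volume_sml / geometry$A_sed
  list(lateral_volumetric = lateral, f_l_areal = f_l,
       negative = lateral < 0)
}

#' Monte Carlo uncertainty propagation of the production closure
#'
#' Draws each budget term independently from an untruncated normal
#' distribution with the component's mean and standard deviation (negative
#' draws are retained: the probability of positive production is itself a
#' result), applies the production closure per draw, and summarises the
#' resulting distribution.
#'
#' @param components a [flux_components()] set with means and sds.
#' @param geometry as in [solve_pnet()].
#' @param cfg a [balance_config()].
#' @param n number of iterations (default 9999).
#' @param seed integer RNG seed; required for reproducibility.
#' @return object of class `mc_result`: `mean`, `sd` (n-1 denominator),
#'   `p_positive`, `quantiles`, `n`, `seed`, `unit`, and the `draws`.
#' @examples
#' comp <- flux_components(f_s = c(90, 52), f_l = c(36, 6), f_z = c(5, 5))
#' monte_carlo_pnet(comp, cfg = balance_config(), seed = 42)
#' @export
monte_carlo_pnet <- function(components, geometry = NULL,
                             cfg = balance_config(), n = 9999, seed) {
  stopifnot(inherits(components, "flux_components"),
            inherits(cfg, "balance_config"))
  if (missing(seed) || !is.numeric(seed))
    stop("an integer `seed` is required", call. = FALSE)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  fs <- stats::rnorm(n, components$f_s[["mean"]], components$f_s[["sd"]])
  fl <- stats::rnorm(n, components$f_l[["mean"]], components$f_l[["sd"]])
  fz <- stats::rnorm(n, components$f_z[["mean"]], components$f_z[["sd"]])
  draws <- .pnet_closure(fs, fl, fz, components$unit, cfg, geometry)
  unit_out <- if (components$unit == "mol d-1") "mol d-1" else "nmol l-1 d-1"
  structure(
    list(mean = mean(draws), sd = stats::sd(draws),
         p_positive = mean(draws > 0),
         quantiles = stats::quantile(draws,
                                     c(0.025, 0.25, 0.5, 0.75, 0.975)),
         n = n, seed = seed, unit = unit_out, draws = draws),
    class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte Carlo production closure (n = %d, seed = %s)\n",
              x$n, format(x$seed)))
  cat(sprintf("  P_net = %.1f +/- %.1f %s  (P(>0) = %.0f%%)\n",
              x$mean, x$sd, x$unit, 100 * x$p_positive))
  invisible(x)
}

#' Seasonal mass-balance parameterisation for a sampling date
#'
#' Before the onset of stratification the balance runs without lateral
#' input or oxidation; after full stratification the stratified closure
#' applies. Within the transitional window the month is split at mid-month
#' (day 15): first half non-stratified, second half stratified.
#'
#' @param date sampling date (`Date` or parseable string).
#' @param stratification_onset date stratification begins to develop.
#' @param stratification_full date the water column is fully stratified.
#' @return a [balance_config()].
#' @export
seasonal_config <- function(date, stratification_onset,
                            stratification_full) {
  date <- as.Date(date)
  onset <- as.Date(stratification_onset)
  full <- as.Date(stratification_full)
  if (onset > full)
    stop("stratification onset must not postdate full stratification",
         call. = FALSE)
  if (date < onset) return(balance_config("non_stratified"))
  if (date >= full) return(balance_config("stratified"))
  day <- as.integer(format(date, "%d"))
  if (day <= 15) balance_config("non_stratified")
  else balance_config("stratified")
}

#' Read a mass-balance component CSV
#'
#' Expects columns `site, season, term, mean, sd, unit` with terms `f_s`,
#' `f_l`, `f_z`. Unknown units are rejected.
#'
#' @param path CSV path.
#' @param site,season optional filters selecting one component set.
#' @return a [flux_components()] set (when filtered to one site/season) or
#'   the validated data frame.
#' @export
read_components <- function(path, site = NULL, season = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "season", "term", "mean", "sd", "unit")
  if (!all(need %in% names(d)))
    stop("component CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(d$unit %in% .rate_units))
    stop("unknown unit in component CSV: ",
         paste(setdiff(d$unit, .rate_units), collapse = ", "),
         call. = FALSE)
  if (!is.null(site)) d <- d[d$site == site, ]
  if (!is.null(season)) d <- d[d$season == season, ]
  if (is.null(site) && is.null(season)) return(d)
  if (nrow(d) == 0) stop("no components match the filter", call. = FALSE)
  if (length(unique(d$unit)) != 1)
    stop("mixed units within one component set", call. = FALSE)
  pick <- function(term) {
    row <- d[d$term == term, ]
    if (nrow(row) == 0) c(0, 0) else c(row$mean[1], row$sd[1])
  }
  flux_components(pick("f_s"), pick("f_l"), pick("f_z"),
                  unit = d$unit[1])
}
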