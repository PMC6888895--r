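# Pipeline orchestration and atomic file output --------------------------

# temp-file + rename write so partial outputs never parse as complete
atomic_write_csv <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(x, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

atomic_write_json <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full SML methane mass-balance pipeline on a campaign
#'
#' Executes the analysis chain on a (synthetic or assembled) campaign
#' bundle: chamber fluxes -> k600-wind model -> wind-based surface
#' emission; heat-budget diffusivity -> thermocline flux; Monte Carlo
#' solution of the production closure; and the oxic methane contribution
#' of the resulting source partition. Lateral input is taken from the
#' campaign's component table (as in a study where it is derived once by
#' enclosure comparison and carried forward).
#'
#' @param campaign a [generate_campaign()] result (or a list with the same
#'   fields).
#' @param seed RNG seed for the Monte Carlo stage.
#' @param n_iterations Monte Carlo iterations (default 9999).
#' @param cfg a [balance_config()]; defaults to the stratified closure.
#' @param sc_exponent,atm_ppm gas-exchange settings (see
#'   [k600_from_flux()]).
#' @return list of class `pipeline_result`: `f_s`, `f_z`, `f_l` (areal,
#'   mmol m-2 d-1, with sds), `k600_model`, `pnet_mc` ([monte_carlo_pnet()]
#'   summary), `pnet_point` (deterministic closure, nmol l-1 d-1), `omc`
#'   (percent), `sources_mol_d`, and a `config` echo.
#' @export
run_pipeline <- function(campaign, seed, n_iterations = 9999,
                         cfg = balance_config("stratified"),
                         sc_exponent = 0.5, atm_ppm = 1.9) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  geom <- campaign$geometry
  truth <- campaign$truth
  d <- geom$sml_thickness

  k600_model <- with_stage("gas_exchange", {
    pairs <- vapply(campaign$chambers, function(ch) {
      flux <- chamber_flux(ch$deployment)
      k <- k600_from_flux(flux, truth$surface_conc,
                          ch$deployment$water_temp_c, atm_ppm,
                          sc_exponent)
      c(ch$u10, k)
    }, numeric(2))
    fit_k600_wind(pairs[1, ], pairs[2, ])
  })

  emission <- with_stage("surface_emission",
    estimate_emission(k600_model, campaign$wind$u10, truth$surface_conc,
                      truth$surface_temp_c, atm_ppm, sc_exponent))

  f_z <- with_stage("vertical_mixing", {
    kz <- heat_budget_diffusivity(campaign$temperature, geom)
    per_date <- vapply(seq_len(ncol(campaign$ch4$values)), function(j)
      thermocline_flux(kz, campaign$ch4$depths,
                       campaign$ch4$values[, j], d),
      numeric(1))
    c(mean = mean(per_date, na.rm = TRUE),
      sd = if (sum(is.finite(per_date)) > 1)
        stats::sd(per_date, na.rm = TRUE) else 0)
  })

  f_l <- with_stage("lateral_input", {
    row <- campaign$components[campaign$components$term == "f_l", ]
    if (nrow(row) == 0) c(mean = 0, sd = 0)
    else c(mean = row$mean[1], sd = row$sd[1])
  })

  comp <- flux_components(
    f_s = c(emission$mean, emission$sd),
    f_l = f_l, f_z = f_z, unit = "mmol m-2 d-1")

  mc <- with_stage("mass_balance",
    monte_carlo_pnet(comp, geom, cfg, n = n_iterations, seed = seed))
  pnet_point <- solve_pnet(comp, geom, cfg)

  sources <- with_stage("omc", {
    p_ws <- pnet_point$value * 1e-6 * geom$volume_sml       # mol d-1
    l_ws <- f_l[["mean"]] * 1e-3 * geom$A_sed
    z_ws <- f_z[["mean"]] * 1e-3 * geom$A_th
    c(production = p_ws, lateral = l_ws, diffusive = z_ws)
  })
  omc_pct <- omc(sources[["production"]], sources[["lateral"]],
                 sources[["diffusive"]])

  structure(list(
    f_s = c(mean = emission$mean, sd = emission$sd),
    f_z = f_z, f_l = f_l,
    k600_model = k600_model,
    pnet_mc = mc, pnet_point = pnet_point,
    omc = omc_pct, sources_mol_d = sources,
    config = list(seed = seed, n_iterations = n_iterations,
                  season = cfg$season, alpha = cfg$alpha,
                  mox_scope = cfg$mox_scope,
                  steady_state = cfg$steady_state,
                  sc_exponent = sc_exponent, atm_ppm = atm_ppm)),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("SML methane mass-balance pipeline\n")
  cat(sprintf("  F_S   = %.3f +/- %.3f mmol m-2 d-1\n",
              x$f_s[["mean"]], x$f_s[["sd"]]))
  cat(sprintf("  F_L   = %.3f +/- %.3f mmol m-2 d-1\n",
              x$f_l[["mean"]], x$f_l[["sd"]]))
  cat(sprintf("  F_z   = %.4f +/- %.4f mmol m-2 d-1\n",
              x$f_z[["mean"]], x$f_z[["sd"]]))
  cat(sprintf("  P_net = %.1f +/- %.1f nmol l-1 d-1 (MC, n = %d)\n",
              x$pnet_mc$mean, x$pnet_mc$sd, x$pnet_mc$n))
  cat(sprintf("  OMC   = %.1f %%\n", x$omc))
  invisible(x)
}

#' Write a pipeline result as JSON
#'
#' Serialises the numeric results together with the full configuration
#' echo (seed, iterations, closure settings) for reproducibility. Atomic
#' write.
#'
#' @param result a [run_pipeline()] result.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_pipeline_result <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  out <- list(
    f_s = as.list(result$f_s), f_l = as.list(result$f_l),
    f_z = as.list(result$f_z),
    k600 = list(slope = result$k600_model$slope,
                intercept = result$k600_model$intercept,
                r_squared = result$k600_model$r_squared),
    pnet = list(mean = result$pnet_mc$mean, sd = result$pnet_mc$sd,
                p_positive = result$pnet_mc$p_positive,
                point = result$pnet_point$value,
                unit = result$pnet_mc$unit),
    omc_percent = result$omc,
    sources_mol_d = as.list(result$sources_mol_d),
    config = result$config)
  atomic_write_json(out, path)
}
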