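#' Run the full analysis pipeline on a synthetic scenario
#'
#' Ties the stages together in dependency order:
#' synthetic trace -> rate extraction -> steady-state model (with optional
#' calibration to the extracted rates) -> derived CCM metrics -> energy cost.
#' Each enabled stage contributes a named report; when `out_dir` is given,
#' per-stage JSON reports and a combined `summary.json` are written (floats
#' serialized with 12 significant digits so reruns are comparable).
#'
#' @param config either a path to a JSON configuration file or a list with
#'   elements `conditions` (list: `temperature_C`, `salinity`, `pH`),
#'   `dic_mM`, `seed`, optional `noise_sd_uM` (list `o2`, `co2`), optional
#'   `stages` (subset of `c("synth", "rates", "ccm", "metrics", "energy")`,
#'   default all), optional `calibrate` (logical, default `TRUE`), optional
#'   `atp_per_hco3` (list `plasmalemma`, `envelope`), optional `out_dir`.
#' @return list of class `"ccm_pipeline"` with one element per executed
#'   stage plus `config` and `assumptions` (the flags carried into every
#'   report: carbonate formulation, photosynthetic quotient, volume
#'   fractions).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config), !is.null(config$conditions))
  cfgc <- config$conditions
  cond <- seawater_conditions(cfgc$temperature_C, cfgc$salinity %||% 35,
                              cfgc$pH %||% 8.10)
  stages <- config$stages %||% c("synth", "rates", "ccm", "metrics", "energy")
  dic <- config$dic_mM %||% 2
  seed <- config$seed %||% 1L
  ccmp <- ccm_params(cond, dic_mM = dic)
  report <- list(config = config)
  report$assumptions <- list(
    carbonate_formulation = ccmp$formulation,
    photosynthetic_quotient = 1,
    volume_fractions = as.list(ccmp$geometry$fractions),
    transporter_k_half_uM = c(plasmalemma = ccmp$k_plm,
                              envelope = ccmp$k_env))
  fail <- function(stage, e) stop(sprintf("pipeline stage '%s' failed: %s",
                                          stage, conditionMessage(e)),
                                  call. = FALSE)
  synth <- NULL
  if ("synth" %in% stages) {
    synth <- tryCatch({
      ns <- config$noise_sd_uM %||% list(o2 = 0, co2 = 0)
      spec <- mims_scenario(cond, ccm = ccmp, dic_steps_mM = dic,
                            noise_sd_uM = c(o2 = ns$o2, co2 = ns$co2),
                            seed = seed)
      gen_mims_trace(spec)
    }, error = function(e) fail("synth", e))
    report$synth <- list(truth = synth$truth,
                         n_samples = nrow(synth$trace))
  }
  if ("rates" %in% stages) {
    report$rates <- tryCatch({
      carb <- compute_constants(cond)
      tr <- synth$trace
      light <- grep("light", unique(tr$segment), value = TRUE)[1]
      darks <- grep("dark", unique(tr$segment), value = TRUE)
      p_light <- segment_rate(tr, light, "o2")$rate
      r_dark <- segment_rate(tr, darks[length(darks)], "o2")$rate
      part <- partition_ci_uptake(tr, carb, dic_mM = dic, segment = light)
      list(net_photosynthesis = p_light, dark_respiration = r_dark,
           daily_net_o2 = daily_net_o2(p_light, r_dark),
           gross_o2 = gross_o2(p_light, r_dark),
           u_co2 = part$u_co2, u_hco3 = part$u_hco3,
           co2_fraction = part$co2_fraction, bulk_co2_uM = part$bulk_co2_uM,
           flag = part$flag)
    }, error = function(e) fail("rates", e))
  }
  ss <- NULL
  if ("ccm" %in% stages) {
    report$ccm <- tryCatch({
      do_cal <- isTRUE(config$calibrate %||% TRUE) && !is.null(report$rates)
      if (do_cal) {
        obs <- list(net_o2 = report$rates$net_photosynthesis,
                    u_co2 = report$rates$u_co2,
                    u_hco3 = report$rates$u_hco3)
        cal <- calibrate(ccmp, obs)
        ss <- cal$steady
        list(calibrated = TRUE, estimates = as.list(coef(cal)),
             converged = cal$converged,
             state_mol_m3 = as.list(ss$state),
             fluxes = lapply(ss$fluxes, unname),
             rel_residual = ss$rel_residual)
      } else {
        ss <- solve_steady_state(ccmp)
        list(calibrated = FALSE, state_mol_m3 = as.list(ss$state),
             fluxes = lapply(ss$fluxes, unname),
             rel_residual = ss$rel_residual)
      }
    }, error = function(e) fail("ccm", e))
  }
  if ("metrics" %in% stages && !is.null(ss))
    report$metrics <- tryCatch(derived_metrics(ss),
                               error = function(e) fail("metrics", e))
  if ("energy" %in% stages && !is.null(ss)) {
    report$energy <- tryCatch({
      atp <- config$atp_per_hco3 %||% list(plasmalemma = 0.5, envelope = 0.5)
      grad <- ss$state[["hco3_stroma"]] / ss$state[["hco3_cytosol"]]
      TK <- cond$temperature_C + 273.15
      list(
        dG_envelope_kJ_mol = transport_dG(grad, -20, -1, TK),
        dG_plasmalemma_kJ_mol = transport_dG(
          ss$state[["hco3_cytosol"]] / dic, -84, -1, TK),
        atp_per_co2 = ccm_cost(ss, c(plasmalemma = atp$plasmalemma,
                                     envelope = atp$envelope)))
    }, error = function(e) fail("energy", e))
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in setdiff(names(report), "config"))
      jsonlite::write_json(report[[nm]],
                           file.path(config$out_dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = 12, pretty = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 12, pretty = TRUE)
  }
  class(report) <- "ccm_pipeline"
  report
}

#' @export
print.ccm_pipeline <- function(x, ...) {
  cat("CCM analysis pipeline report; stages:",
      paste(setdiff(names(x), c("config", "assumptions")), collapse = ", "),
      "\n")
  if (!is.null(x$rates))
    cat(sprintf("  net P %.3g, dark R %.3g, CO2 fraction %.2f\n",
                x$rates$net_photosynthesis, x$rates$dark_respiration,
                x$rates$co2_fraction))
  if (!is.null(x$metrics))
    cat(sprintf("  pump/fixation %.2f, leak/pump %.2f, gradient %.1f-fold\n",
                x$metrics$pump_per_fixation, x$metrics$leak_per_pump,
                x$metrics$hco3_gradient_fold))
  if (!is.null(x$energy))
    cat(sprintf("  ATP per CO2 fixed: %.2f\n", x$energy$atp_per_co2))
  invisible(x)
}
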