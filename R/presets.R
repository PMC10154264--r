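#' Temperature-calibrated demonstration parameter sets
#'
#' Compartment-model parameter sets for 10, 18 and 25 degC that reproduce the
#' qualitative temperature pattern of the chloroplast-pump CCM: RuBisCO
#' kinetics from the packaged assay table, CO2 mass-transfer and effective
#' carbonic anhydrase rates rising with temperature, a roughly constant
#' ~0.7 mM cytosolic HCO3- pool, chloroplast HCO3- rising from ~15 mM (cold)
#' to ~30 mM (warm), and a shift from CO2-dominated uptake (~80%) at 10-18
#' degC toward ~50% at 25 degC. Transporter capacities and CA accelerations
#' are model calibrations (the measured quantities constrain them only
#' jointly), flagged as assumptions in reports.
#'
#' @param temperature_C one of 10, 18, 25.
#' @param dic_mM bulk DIC, default 2.
#' @return a [ccm_params()] object.
#' @examples
#' summary(solve_steady_state(ccm_preset(25)))
#' @export
ccm_preset <- function(temperature_C, dic_mM = 2) {
  cond <- seawater_conditions(temperature_C, 35, 8.10)
  switch(as.character(temperature_C),
    "10" = ccm_params(cond, dic_mM = dic_mM,
                      fc = c(1e-13, 1.6e-15, 1.0e-15, 0.8e-16),
                      ca = c(surface = 0, cytosol = 10000, stroma = 0,
                             pyrenoid = 35000),
                      vmax_plm = 1.2e-18, vmax_env = 1.6e-17,
                      kcatC = 0.9, KCair_uM = 22, respiration = 1.5e-18),
    "18" = ccm_params(cond, dic_mM = dic_mM),
    "25" = ccm_params(cond, dic_mM = dic_mM,
                      fc = c(1e-13, 3.5e-15, 2.1e-15, 1.9e-16),
                      ca = c(surface = 0, cytosol = 7000, stroma = 0,
                             pyrenoid = 18000),
                      vmax_plm = 1.3e-17, vmax_env = 5.8e-17,
                      kcatC = 3.3, KCair_uM = 55, respiration = 6e-18),
    stop("no preset for temperature ", temperature_C,
         " degC (available: 10, 18, 25)"))
}

#' Exchange-assay ground-truth presets per temperature
#'
#' Cell-level exchange parameters matching [ccm_preset()]: CO2 permeability
#' fc rising with temperature, HCO3- permeability fb three orders of
#' magnitude lower and temperature-insensitive, intracellular CA
#' acceleration as in the compartment model's cytosol.
#'
#' @param temperature_C one of 10, 18, 25.
#' @param cell_density cells per m^3 in the assay chamber (default 3.5e12,
#'   i.e. 3.5e6 cells/mL).
#' @return an [exchange_params()] object.
#' @export
exchange_preset <- function(temperature_C, cell_density = 3.5e12) {
  p <- ccm_preset(temperature_C)
  exchange_params(fc = p$fc[["surface_cytosol"]], fb = 2.5e-18,
                  ca_intracellular = p$ca[["cytosol"]],
                  ca_extracellular = 0, cell_density = cell_density,
                  cell_volume = p$geometry$cell_volume_m3)
}
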