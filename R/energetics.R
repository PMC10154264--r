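#' Gibbs free energy of membrane transport
#'
#' Free-energy input required to move one mole of an ion from a source to a
#' destination compartment against its electrochemical gradient:
#' `dG = R*T*ln(ratio) + z*F*dpsi`, with `ratio` the destination/source
#' concentration ratio and `dpsi` the membrane potential of the destination
#' minus the source. Positive values mean energy input is required for the
#' stated direction. For an anion (`z = -1`), a destination that is
#' electrically negative relative to the source (`dpsi < 0`) opposes entry
#' and adds to the cost.
#'
#' @param ratio destination/source concentration ratio, > 0.
#' @param dpsi_mV membrane potential, millivolts, destination minus source;
#'   `|dpsi| < 500` sanity bound.
#' @param z signed ion charge (HCO3-: -1).
#' @param temperature_K temperature; default 298.15 K.
#' @return Free energy, kJ per mol.
#' @examples
#' transport_dG(40, -20)                # chloroplast pump, ~11 kJ/mol
#' transport_dG(0.7 / 2, -84)           # plasmalemma uptake, ~5.5 kJ/mol
#' @export
transport_dG <- function(ratio, dpsi_mV, z = -1, temperature_K = 298.15) {
  if (ratio <= 0) stop("concentration ratio must be positive")
  if (abs(dpsi_mV) >= 500) stop("membrane potential outside sanity bound")
  R <- 8.314462618
  Fa <- 96485.33212
  (R * temperature_K * log(ratio) + z * Fa * dpsi_mV * 1e-3) / 1000
}

#' ATP cost of the CCM per CO2 fixed
#'
#' Sums each active HCO3- transport flux weighted by its assumed ATP
#' stoichiometry and divides by the RuBisCO fixation flux.
#'
#' @param flux either a `"ccm_steady"` object or a list with elements
#'   `hco3_uptake_plasmalemma`, `hco3_pump_envelope`, `fixation`
#'   (mol cell^-1 s^-1).
#' @param atp_per_hco3 named numeric: ATP per HCO3- at `plasmalemma` and
#'   `envelope` (0.5 or 1 in the literature; default both 0.5).
#' @return ATP consumed per CO2 fixed (dimensionless).
#' @examples
#' ccm_cost(list(hco3_uptake_plasmalemma = 0.4e-17,
#'               hco3_pump_envelope = 1.6e-17, fixation = 1e-17))
#' @export
ccm_cost <- function(flux, atp_per_hco3 = c(plasmalemma = 0.5,
                                            envelope = 0.5)) {
  f <- if (inherits(flux, "ccm_steady")) flux$fluxes else flux
  stopifnot(all(c("plasmalemma", "envelope") %in% names(atp_per_hco3)))
  if (f$fixation <= 0) stop("zero fixation: ATP cost undefined")
  (f$hco3_uptake_plasmalemma * atp_per_hco3[["plasmalemma"]] +
      f$hco3_pump_envelope * atp_per_hco3[["envelope"]]) / f$fixation
}
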