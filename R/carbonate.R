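#' Seawater conditions
#'
#' Bundle of the physico-chemical chamber/culture conditions under which all
#' rate and speciation calculations are carried out. The chamber is assumed
#' pH-buffered (25 mM HEPES), so pH is treated as clamped throughout.
#'
#' @param temperature_C temperature in degrees Celsius, in \[-2, 40\].
#' @param salinity practical salinity, in \[0, 45\].
#' @param pH pH on the scale of the chosen carbonate formulation
#'   (NBS for `"mehrbach"`, total for `"lueker"`), in \[6, 10\].
#' @param buffered logical; pH held constant by buffer (default `TRUE`).
#' @return An object of class `"seawater_conditions"`.
#' @examples
#' seawater_conditions(18, 35, 8.10)
#' @export
seawater_conditions <- function(temperature_C, salinity = 35, pH = 8.10,
                                buffered = TRUE) {
  stopifnot(is.numeric(temperature_C), length(temperature_C) == 1L,
            is.numeric(salinity), length(salinity) == 1L,
            is.numeric(pH), length(pH) == 1L)
  if (temperature_C < -2 || temperature_C > 40)
    stop("temperature_C out of range [-2, 40]: ", temperature_C)
  if (salinity < 0 || salinity > 45)
    stop("salinity out of range [0, 45]: ", salinity)
  if (pH < 6 || pH > 10)
    stop("pH out of range [6, 10]: ", pH)
  structure(list(temperature_C = temperature_C, salinity = salinity,
                 pH = pH, buffered = isTRUE(buffered)),
            class = "seawater_conditions")
}

#' @export
print.seawater_conditions <- function(x, ...) {
  cat(sprintf("Seawater conditions: %.2f degC, S = %.1f, pH = %.2f%s\n",
              x$temperature_C, x$salinity, x$pH,
              if (x$buffered) " (buffered)" else ""))
  invisible(x)
}

# -- stoichiometric dissociation constants -----------------------------------
# K1, K2 of carbonic acid in seawater. Two named formulations:
#   "mehrbach": Mehrbach et al. (1973) original fits, NBS pH scale. Default,
#     matching pH set with an NBS-buffer-calibrated bench electrode.
#   "lueker":   Lueker et al. (2000) refit, total pH scale.
# T in Kelvin, S practical salinity; constants in mol/kg (treated as mol/L;
# the ~2.5% density difference cancels in every ratio used downstream).
carb_K1K2 <- function(TK, S, formulation) {
  switch(formulation,
    mehrbach = {
      pK1 <- -13.7201 + 0.031334 * TK + 3235.76 / TK +
        1.3e-5 * S * TK - 0.1032 * sqrt(S)
      pK2 <- 5371.9645 + 1.671221 * TK + 0.22913 * S + 18.3802 * log10(S) -
        128375.28 / TK - 2194.3055 * log10(TK) - 8.0944e-4 * S * TK -
        5617.11 * log10(S) / TK + 2.136 * S / TK
      list(K1 = 10^-pK1, K2 = 10^-pK2)
    },
    lueker = {
      pK1 <- 3633.86 / TK - 61.2172 + 9.67770 * log(TK) -
        0.011555 * S + 0.0001152 * S^2
      pK2 <- 471.78 / TK + 25.9290 - 3.16967 * log(TK) -
        0.01781 * S + 0.0001122 * S^2
      list(K1 = 10^-pK1, K2 = 10^-pK2)
    },
    stop("unknown carbonate formulation: ", formulation)
  )
}

# Ion product of water, Millero (1995), mol^2/kg^2.
carb_KW <- function(TK, S) {
  exp(148.9652 - 13847.26 / TK - 23.6521 * log(TK) +
        (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sqrt(S) - 0.01615 * S)
}

# Uncatalyzed CO2 hydration: k+1 (CO2 + H2O), Johnson (1982), s^-1,
# plus the hydroxylation route k+4[OH-] (A = 4.70e7 kg mol^-1 s^-1,
# Ea = 23.2 kJ/mol).
carb_kplus1 <- function(TK) exp(1246.98 - 6.19e4 / TK - 183.0 * log(TK))
carb_kplus4 <- function(TK) 4.70e7 * exp(-23200 / (8.314462618 * TK))

#' Carbonate system constants
#'
#' Stoichiometric dissociation constants of carbonic acid and pseudo-first-order
#' CO2 hydration / HCO3- dehydration rate constants at clamped pH. The
#' dehydration constant is derived from the hydration constant by detailed
#' balance, `kr = kf / Keq`, with `Keq = [HCO3-]/[CO2] = K1/[H+]`, so the
#' equilibrium invariant `kf/kr == Keq` holds exactly.
#'
#' @param cond a [seawater_conditions()] object.
#' @param formulation `"mehrbach"` (NBS scale, default) or `"lueker"`
#'   (total scale).
#' @return Object of class `"carb_system"` with fields `K1`, `K2` (mol/L),
#'   `kf`, `kr` (1/s), `Keq_CO2_HCO3` (dimensionless), `ratio_co3_hco3`,
#'   plus the input conditions and formulation name.
#' @examples
#' cs <- compute_constants(seawater_conditions(18, 35, 8.10))
#' cs$Keq_CO2_HCO3    # ~100: HCO3-/CO2 ratio at chamber pH
#' @export
compute_constants <- function(cond, formulation = c("mehrbach", "lueker")) {
  stopifnot(inherits(cond, "seawater_conditions"))
  formulation <- match.arg(formulation)
  TK <- cond$temperature_C + 273.15
  S <- cond$salinity
  K <- carb_K1K2(TK, S, formulation)
  h <- 10^(-cond$pH)
  Keq <- K$K1 / h
  oh <- carb_KW(TK, S) / h
  kf <- carb_kplus1(TK) + carb_kplus4(TK) * oh
  kr <- kf / Keq
  structure(list(K1 = K$K1, K2 = K$K2, kf = kf, kr = kr,
                 Keq_CO2_HCO3 = Keq, ratio_co3_hco3 = K$K2 / h,
                 conditions = cond, formulation = formulation),
            class = "carb_system")
}

#' @export
print.carb_system <- function(x, ...) {
  cat(sprintf("Carbonate system (%s, %.1f degC, S %.1f, pH %.2f)\n",
              x$formulation, x$conditions$temperature_C,
              x$conditions$salinity, x$conditions$pH))
  cat(sprintf("  pK1 = %.4f  pK2 = %.4f\n", -log10(x$K1), -log10(x$K2)))
  cat(sprintf("  kf = %.5g /s  kr = %.5g /s  Keq(HCO3/CO2) = %.1f\n",
              x$kf, x$kr, x$Keq_CO2_HCO3))
  invisible(x)
}

#' Speciate dissolved inorganic carbon at fixed pH
#'
#' Partitions a DIC concentration into CO2, HCO3- and CO3(2-) at the clamped
#' pH of the given conditions. Components always sum to the input DIC.
#'
#' @param dic total dissolved inorganic carbon (any concentration unit;
#'   output in the same unit).
#' @param cond a [seawater_conditions()] object, or a `"carb_system"` from
#'   [compute_constants()].
#' @param formulation passed to [compute_constants()] when `cond` is a
#'   conditions object.
#' @return Named numeric vector `c(co2, hco3, co3)`.
#' @examples
#' speciate_dic(2.0, seawater_conditions(18, 35, 8.10))  # mM in, mM out
#' @export
speciate_dic <- function(dic, cond, formulation = "mehrbach") {
  stopifnot(is.numeric(dic), length(dic) == 1L)
  if (dic < 0) stop("dic must be non-negative")
  cs <- if (inherits(cond, "carb_system")) cond
        else compute_constants(cond, formulation)
  r1 <- cs$Keq_CO2_HCO3
  r2 <- cs$ratio_co3_hco3
  co2 <- dic / (1 + r1 + r1 * r2)
  hco3 <- co2 * r1
  co3 <- dic - co2 - hco3          # exact closure of the sum
  c(co2 = co2, hco3 = hco3, co3 = co3)
}
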