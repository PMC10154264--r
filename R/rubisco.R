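#' Fit the Arcus temperature-rate equation
#'
#' Fits `ln k = a*ln(T) + b*(1/T) + c` to rate observations across temperature
#' by linear least squares in the log domain. With exactly three distinct
#' temperatures the fit is exact (three equations, three unknowns); with more
#' it is the ordinary least-squares solution. The `a = 0` subfamily is the
#' Arrhenius law; `a != 0` allows curvature in the Arrhenius plot as seen in
#' enzyme kinetics over wide temperature spans.
#'
#' @param temps temperatures in Kelvin (>= 3 distinct positive values).
#' @param rates positive rates, same length as `temps`.
#' @return Object of class `"arcus_fit"` with components `a`, `b`, `c`,
#'   `temperature_range` (Kelvin), `residuals` (log-domain) and the data.
#' @seealso [eval_arcus()], [predict.arcus_fit()]
#' @examples
#' fit <- fit_arcus(c(279.15, 285.15, 291.15, 298.15), c(0.8, 1.3, 2.0, 3.3))
#' eval_arcus(fit, 291.15)
#' @export
fit_arcus <- function(temps, rates) {
  stopifnot(is.numeric(temps), is.numeric(rates))
  if (length(temps) != length(rates)) stop("temps and rates lengths differ")
  if (length(temps) < 3) stop("need at least 3 points to fit (a, b, c)")
  if (any(temps <= 0)) stop("temperatures must be positive (Kelvin)")
  if (anyDuplicated(temps)) stop("duplicate temperatures")
  if (any(rates <= 0)) stop("rates must be positive")
  X <- cbind(lnT = log(temps), invT = 1 / temps, const = 1)
  y <- log(rates)
  beta <- qr.coef(qr(X), y)
  res <- y - drop(X %*% beta)
  structure(list(a = unname(beta[1]), b = unname(beta[2]),
                 c = unname(beta[3]),
                 temperature_range = range(temps),
                 residuals = res, temps = temps, rates = rates),
            class = "arcus_fit")
}

#' Evaluate an Arcus fit at a temperature
#'
#' @param fit an `"arcus_fit"` (or a bare list with `a`, `b`, `c`).
#' @param T_K temperature(s) in Kelvin; must be positive. Values outside the
#'   fitted `temperature_range` are allowed but flagged with a warning
#'   (extrapolation).
#' @return Rate(s), strictly positive.
#' @export
eval_arcus <- function(fit, T_K) {
  stopifnot(is.numeric(T_K))
  if (any(T_K <= 0)) stop("temperature must be positive Kelvin")
  rng <- fit$temperature_range
  if (!is.null(rng) && any(T_K < rng[1] | T_K > rng[2]))
    warning("evaluating Arcus fit outside its fitted temperature range")
  exp(fit$a * log(T_K) + fit$b / T_K + fit$c)
}

#' @export
coef.arcus_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @rdname eval_arcus
#' @param object an `"arcus_fit"`.
#' @param newdata optional list/data.frame with element `T_K`.
#' @param ... unused.
#' @export
predict.arcus_fit <- function(object, newdata = NULL, ...) {
  T_K <- if (is.null(newdata)) object$temps else newdata$T_K
  eval_arcus(object, T_K)
}

#' @export
print.arcus_fit <- function(x, ...) {
  cat(sprintf("Arcus fit: ln k = %.4g*lnT + %.6g/T + %.6g  (T in [%.1f, %.1f] K)\n",
              x$a, x$b, x$c, x$temperature_range[1], x$temperature_range[2]))
  cat(sprintf("  log-domain RMS residual: %.3g over %d points\n",
              sqrt(mean(x$residuals^2)), length(x$residuals)))
  invisible(x)
}

#' RuBisCO saturation state
#'
#' Fraction of RuBisCO carboxylation capacity in use: gross CO2 fixation rate
#' divided by the product of carboxylation turnover and active-site abundance.
#'
#' @param gross_fix gross CO2 fixation, mol cell^-1 s^-1.
#' @param kcat carboxylation turnover kcatC, s^-1.
#' @param abundance RuBisCO active sites, mol cell^-1.
#' @return Saturation fraction in (0, 1\]. Values above 1.05 (demand exceeding
#'   capacity beyond rounding slack) raise an error.
#' @examples
#' saturation(3.0e-17, 3.3, 1.24e-17)   # ~0.73
#' @export
saturation <- function(gross_fix, kcat, abundance) {
  stopifnot(gross_fix > 0, kcat > 0, abundance > 0)
  s <- gross_fix / (kcat * abundance)
  if (s > 1.05)
    stop(sprintf("saturation %.3f > 1.05: fixation demand exceeds capacity", s))
  s
}

#' Back-calculate CO2 concentration at RuBisCO
#'
#' Inverts the Michaelis-Menten relation: a saturation fraction `s` at
#' half-saturation constant `KC` implies substrate concentration
#' `C = KC * s / (1 - s)`.
#'
#' @param KC half-saturation CO2 concentration (KCair), micromolar.
#' @param s saturation fraction, strictly in (0, 1).
#' @return CO2 concentration, micromolar.
#' @examples
#' co2_at_rubisco(55, saturation(3.0e-17, 3.3, 1.24e-17))  # ~151 uM
#' @export
co2_at_rubisco <- function(KC, s) {
  stopifnot(KC > 0)
  if (s <= 0 || s >= 1)
    stop("saturation must be strictly inside (0, 1); got ", s)
  KC * s / (1 - s)
}

#' Estimate RuBisCO abundance from an assumed saturation
#'
#' @param gross_fix gross CO2 fixation, mol cell^-1 s^-1.
#' @param kcat carboxylation turnover, s^-1.
#' @param target_saturation assumed saturation fraction in (0, 1\];
#'   `1` gives the minimum-abundance bound `gross_fix / kcat`.
#' @return Active-site abundance, mol cell^-1.
#' @export
estimate_abundance <- function(gross_fix, kcat, target_saturation) {
  stopifnot(gross_fix > 0, kcat > 0)
  if (target_saturation <= 0 || target_saturation > 1)
    stop("target_saturation must be in (0, 1]")
  gross_fix / (target_saturation * kcat)
}

#' Packaged RuBisCO kinetic parameters across temperature
#'
#' Carboxylation turnover (kcatC) and half-saturation CO2 in air (KCair) for
#' the diatom at the three study temperatures. The 10 and 25 degC rows are
#' measured assay endpoints; the 18 degC row is interpolated between them with
#' the Arrhenius (a = 0) member of the Arcus family, since two endpoints
#' cannot constrain all three Arcus constants. The interpolated KCair
#' (36.3 uM) is consistent with the value implied by 80% saturation at
#' 147 uM CO2 (~36.8 uM).
#'
#' @return data.frame with columns `temperature_C`, `kcatC_s`, `KCair_uM`,
#'   `source`.
#' @export
rubisco_params <- function() {
  path <- system.file("extdata", "rubisco_params.tsv", package = "ccmflux")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Interpolate RuBisCO kinetics at a temperature
#'
#' Two-point log-linear (Arrhenius) interpolation between the packaged assay
#' endpoints, matching how the packaged 18 degC values were produced.
#'
#' @param temperature_C temperature in Celsius within the assay range.
#' @return list with `kcatC_s` and `KCair_uM`.
#' @examples
#' rubisco_interp(18)
#' @export
rubisco_interp <- function(temperature_C) {
  tab <- rubisco_params()
  tab <- tab[tab$source == "measured", ]
  TK <- temperature_C + 273.15
  t1 <- min(tab$temperature_C) + 273.15
  t2 <- max(tab$temperature_C) + 273.15
  if (TK < t1 || TK > t2)
    warning("temperature outside the assayed range; extrapolating")
  w <- (1 / t1 - 1 / TK) / (1 / t1 - 1 / t2)   # linear in 1/T
  interp <- function(v) exp((1 - w) * log(v[which.min(tab$temperature_C)]) +
                              w * log(v[which.max(tab$temperature_C)]))
  list(kcatC_s = interp(tab$kcatC_s), KCair_uM = interp(tab$KCair_uM))
}
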