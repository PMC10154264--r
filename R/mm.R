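#' Fit a Michaelis-Menten response curve
#'
#' Nonlinear least-squares fit of `rate = vmax * conc / (k_half + conc)` via
#' Levenberg-Marquardt ([minpack.lm::nlsLM]), with self-starting initial
#' values (vmax from the largest rates, k_half from the concentration nearest
#' half of that).
#'
#' @param conc substrate concentrations (>= 0), length >= 4, not all equal.
#' @param rate observed rates, same length.
#' @return Object of class `"mm_fit"`: list with `vmax`, `k_half`, `se`
#'   (named standard errors), `ci` (95% Wald intervals), `fit` (the `nls`
#'   object), `warn` (character, non-empty if no concentration exceeded the
#'   fitted `k_half`).
#' @examples
#' co <- c(0.5, 1, 2, 4, 8, 16)
#' fit_mm(co, 5 * co / (1 + co))
#' @export
fit_mm <- function(conc, rate) {
  stopifnot(is.numeric(conc), is.numeric(rate), length(conc) == length(rate))
  if (length(conc) < 4) stop("need at least 4 points")
  if (any(conc < 0)) stop("negative concentrations")
  if (diff(range(conc)) == 0) stop("degenerate data: all concentrations equal")
  v0 <- max(rate) * 1.05
  k0 <- conc[which.min(abs(rate - v0 / 2))]
  if (k0 <= 0) k0 <- stats::median(conc[conc > 0])
  df <- data.frame(conc = conc, rate = rate)
  fit <- minpack.lm::nlsLM(rate ~ vmax * conc / (k_half + conc), data = df,
                           start = list(vmax = v0, k_half = k0),
                           lower = c(0, 1e-12),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, k_half = NA_real_))
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  warn <- ""
  if (max(conc) < est[["k_half"]]) {
    warn <- "no concentration above fitted k_half: estimate poorly constrained"
    warning(warn)
  }
  structure(list(vmax = est[["vmax"]], k_half = est[["k_half"]], se = se,
                 ci = ci, fit = fit, warn = warn),
            class = "mm_fit")
}

#' @export
coef.mm_fit <- function(object, ...) {
  c(vmax = object$vmax, k_half = object$k_half)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: vmax = %.4g (se %.2g), k_half = %.4g (se %.2g)\n",
              x$vmax, x$se[["vmax"]], x$k_half, x$se[["k_half"]]))
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) summary(object$fit, ...)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit))
  object$vmax * newdata$conc / (object$k_half + newdata$conc)
}
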