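#' Parameters of the 18O/13C isotope-exchange assay model
#'
#' @param fc CO2 mass-transfer coefficient across membrane + frustule,
#'   m^3 cell^-1 s^-1.
#' @param fb HCO3- mass-transfer coefficient, m^3 cell^-1 s^-1 (expected
#'   orders of magnitude below `fc`; a warning is issued if `fb > fc/100`).
#' @param ca_intracellular intracellular carbonic anhydrase catalytic
#'   acceleration, dimensionless, >= 0: total interconversion rate is
#'   `(1 + a) *` the uncatalyzed rate, so 0 means uncatalyzed chemistry only.
#' @param ca_extracellular same for extracellular CA; 0 under acetazolamide.
#' @param cell_density cells per m^3 chamber.
#' @param cell_volume m^3 per cell.
#' @return Object of class `"exchange_params"`.
#' @export
exchange_params <- function(fc, fb, ca_intracellular, ca_extracellular = 0,
                            cell_density, cell_volume) {
  stopifnot(fc >= 0, fb >= 0, ca_intracellular >= 0, ca_extracellular >= 0,
            cell_density >= 0, cell_volume > 0)
  if (fc > 0 && fb > fc / 100)
    warning("fb > fc/100: HCO3- permeability unexpectedly high")
  structure(list(fc = fc, fb = fb, ca_intracellular = ca_intracellular,
                 ca_extracellular = ca_extracellular,
                 cell_density = cell_density, cell_volume = cell_volume),
            class = "exchange_params")
}

#' Initial isotope state for an exchange assay
#'
#' The assay starts by spiking 18O,13C-labeled bicarbonate into unlabeled
#' buffered seawater: all labeled carbon is initially HCO3- with a uniform
#' 18O atom fraction; labeled CO2 species grow in by dehydration.
#'
#' @param dic_mM labeled DIC spike, mM (~2 in the assay).
#' @param frac18O initial 18O atom fraction of the bicarbonate oxygens.
#' @return Named numeric state vector (mol m^-3 for concentrations;
#'   `lbe`/`lbi` are 18O atom concentrations, = 3 * conc * atom fraction).
#' @export
exchange_init <- function(dic_mM = 2, frac18O = 0.98) {
  stopifnot(dic_mM >= 0, frac18O >= 0, frac18O <= 1)
  c(ce45 = 0, ce47 = 0, ce49 = 0, be = dic_mM, lbe = 3 * dic_mM * frac18O,
    ci45 = 0, ci47 = 0, ci49 = 0, bi = 0, lbi = 0)
}

# ODE right-hand side of the exchange model. Each hydration carries the CO2
# oxygens into HCO3- plus one unlabeled water oxygen; each dehydration
# removes a random oxygen to water (binomial bookkeeping over the
# well-scrambled pool), so 18O is progressively lost to the (infinite,
# unlabeled) water pool and never regained.
exchange_rhs <- function(t, y, p) {
  me <- 1 + p$ae              # extracellular chemistry acceleration
  mi <- 1 + p$ai              # intracellular
  be <- max(y[["be"]], 0); bi <- max(y[["bi"]], 0)
  betae <- if (be > 1e-15) min(max(y[["lbe"]] / (3 * be), 0), 1) else 0
  betai <- if (bi > 1e-15) min(max(y[["lbi"]] / (3 * bi), 0), 1) else 0
  De <- me * p$kr * be
  Di <- mi * p$kr * bi
  nfc <- p$n * p$fc; nfb <- p$n * p$fb
  tc45 <- y[["ce45"]] - y[["ci45"]]
  tc47 <- y[["ce47"]] - y[["ci47"]]
  tc49 <- y[["ce49"]] - y[["ci49"]]
  tb <- y[["be"]] - y[["bi"]]
  tlb <- y[["lbe"]] - y[["lbi"]]
  hyd_e <- me * p$kf
  hyd_i <- mi * p$kf
  cells <- as.numeric(p$n > 0)   # no cells -> intracellular pools inert
  d <- c(
    ce45 = -hyd_e * y[["ce45"]] + De * (1 - betae)^2 - nfc * tc45,
    ce47 = -hyd_e * y[["ce47"]] + De * 2 * betae * (1 - betae) - nfc * tc47,
    ce49 = -hyd_e * y[["ce49"]] + De * betae^2 - nfc * tc49,
    be = hyd_e * (y[["ce45"]] + y[["ce47"]] + y[["ce49"]]) - De - nfb * tb,
    lbe = hyd_e * (y[["ce47"]] + 2 * y[["ce49"]]) - me * p$kr * y[["lbe"]] -
      nfb * tlb,
    ci45 = cells * (-hyd_i * y[["ci45"]] + Di * (1 - betai)^2 +
                      p$fc * tc45 / p$Vc),
    ci47 = cells * (-hyd_i * y[["ci47"]] + Di * 2 * betai * (1 - betai) +
                      p$fc * tc47 / p$Vc),
    ci49 = cells * (-hyd_i * y[["ci49"]] + Di * betai^2 +
                      p$fc * tc49 / p$Vc),
    bi = cells * (hyd_i * (y[["ci45"]] + y[["ci47"]] + y[["ci49"]]) - Di +
                    p$fb * tb / p$Vc),
    lbi = cells * (hyd_i * (y[["ci47"]] + 2 * y[["ci49"]]) -
                     mi * p$kr * y[["lbi"]] + p$fb * tlb / p$Vc))
  list(d)
}

#' Simulate the 18O/13C exchange assay
#'
#' Integrates the coupled isotopologue ODE system: CA-accelerated
#' CO2/HCO3- interconversion in the chamber and inside the cells (with
#' binomial 18O bookkeeping on every interconversion event), CO2 membrane
#' exchange at `fc * dC` per cell and HCO3- exchange at `fb * dB`.
#' Total labeled carbon is conserved; total 18O in the DIC pool is
#' non-increasing.
#'
#' @param params an [exchange_params()] object.
#' @param init state vector from [exchange_init()] (or a modified one).
#' @param carb a `"carb_system"` giving the uncatalyzed `kf`, `kr`.
#' @param times increasing numeric vector of output times, seconds.
#' @param rtol,atol solver tolerances (lsoda); defaults 1e-8 / 1e-12.
#' @return data.frame of class `"exchange_sim"`: `time` plus the ten state
#'   columns (mol m^-3; `lbe`, `lbi` in atom mol m^-3), with the parameters
#'   attached as attribute `params`.
#' @export
simulate_exchange <- function(params, init, carb, times,
                              rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(params, "exchange_params"), inherits(carb, "carb_system"))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(init < -1e-12)) stop("negative initial state")
  p <- list(kf = carb$kf, kr = carb$kr, ae = params$ca_extracellular,
            ai = params$ca_intracellular, fc = params$fc, fb = params$fb,
            n = params$cell_density, Vc = params$cell_volume)
  out <- deSolve::lsoda(y = init, times = times, func = exchange_rhs,
                        parms = p, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("exchange ODE solver failed to converge; istate = ",
         attr(out, "istate")[1])
  df <- as.data.frame(out)
  structure(df, params = params, class = c("exchange_sim", "data.frame"))
}

#' Total labeled carbon in an exchange state (chamber-volume basis)
#'
#' @param sim an `"exchange_sim"` data.frame.
#' @return numeric vector, mol m^-3 of chamber, one value per time point.
#' @export
total_13c <- function(sim) {
  p <- attr(sim, "params")
  cellfrac <- p$cell_density * p$cell_volume
  with(sim, ce45 + ce47 + ce49 + be +
         cellfrac * (ci45 + ci47 + ci49 + bi))
}

#' Total 18O atoms in the DIC pool (chamber-volume basis)
#' @param sim an `"exchange_sim"` data.frame.
#' @return numeric vector, atom mol m^-3.
#' @export
total_18o <- function(sim) {
  p <- attr(sim, "params")
  cellfrac <- p$cell_density * p$cell_volume
  with(sim, ce47 + 2 * ce49 + lbe + cellfrac * (ci47 + 2 * ci49 + lbi))
}

# Piecewise forward model for a full assay: cell-free phase up to t_add,
# then cells present with unlabeled internal pools.
exchange_forward <- function(fc, fb, ca_i, ca_e, cell_density, cell_volume,
                             init, carb, times, t_add) {
  pre_t <- times[times < t_add]
  post_t <- times[times >= t_add]
  nocell <- exchange_params(fc, fb, ca_i, ca_e, 0, cell_volume)
  out <- NULL
  state <- init
  if (length(pre_t)) {
    sim <- simulate_exchange(nocell, state, carb, unique(c(pre_t, t_add)))
    state <- unlist(sim[nrow(sim), -1])
    out <- sim[sim$time %in% pre_t, ]
  } else {
    sim0 <- simulate_exchange(nocell, state, carb, c(min(times) - 1, t_add))
    state <- unlist(sim0[nrow(sim0), -1])
  }
  withcell <- exchange_params(fc, fb, ca_i, ca_e, cell_density, cell_volume)
  if (length(post_t)) {
    sim2 <- simulate_exchange(withcell, state, carb, unique(c(t_add, post_t)))
    sim2 <- sim2[sim2$time %in% post_t, ]
    out <- if (is.null(out)) sim2 else rbind(out, sim2)
  }
  structure(out, params = withcell, class = c("exchange_sim", "data.frame"))
}

#' Estimate exchange parameters from an observed isotopologue trace
#'
#' Weighted least-squares fit of the forward exchange model to observed
#' extracellular mass-45/47/49 CO2 series over free parameters
#' (`fc`, `fb`, `ca_intracellular`), on log scale to enforce positivity,
#' by Levenberg-Marquardt.
#'
#' @param observed a `"mims_trace"` whose CO2 isotopologue columns cover a
#'   cell-free phase and a post-cell-addition phase.
#' @param carb a `"carb_system"` at the assay temperature.
#' @param fixed list with mandatory `cell_volume` (m^3), `t_add` (s, cell
#'   addition time), `init` (state vector), and optional
#'   `ca_extracellular` (default 0, AZ present), `cell_density` (default
#'   taken from the trace).
#' @param start optional named list of starting values for `fc`, `fb`,
#'   `ca_intracellular`.
#' @return Object of class `"exchange_fit"`: estimated [exchange_params()],
#'   `se` (delta-method standard errors on the natural scale), `resid_norm`,
#'   `condition_number` of the scaled Jacobian, and `flags` (character;
#'   notes weak identifiability when the condition number exceeds 1e6).
#' @export
estimate_params <- function(observed, carb, fixed, start = NULL) {
  stopifnot(inherits(observed, "mims_trace"), inherits(carb, "carb_system"))
  need <- c("cell_volume", "t_add", "init")
  if (!all(need %in% names(fixed)))
    stop("fixed must contain: ", paste(need, collapse = ", "))
  dens <- fixed$cell_density %||% attr(observed, "cell_density")
  ca_e <- fixed$ca_extracellular %||% 0
  times <- observed$time_s
  obs <- cbind(observed$co2_45_uM, observed$co2_47_uM,
               observed$co2_49_uM) * 1e-3   # uM -> mol/m^3
  # relative weighting (MIMS noise scales with signal), floored at 10% of
  # the largest isotopologue signal so near-zero tails are not overweighted
  W <- pmax(abs(obs), 0.1 * max(obs))
  residfun <- function(theta) {
    pr <- exp(theta)
    sim <- suppressWarnings(
      exchange_forward(pr[1], pr[2], pr[3], ca_e, dens,
                       fixed$cell_volume, fixed$init, carb, times,
                       fixed$t_add))
    pred <- as.matrix(sim[, c("ce45", "ce47", "ce49")])
    as.vector((pred - obs) / W)
  }
  if (is.null(start)) {
    # coarse grid start: the residual surface has a plateau in fc once
    # membrane transfer outpaces chamber chemistry, so Levenberg-Marquardt
    # needs a start on the right side of it
    grid <- expand.grid(fc = 10^seq(-16, -14, length.out = 5),
                        ca = 10^seq(1.5, 4, length.out = 6))
    ssq <- apply(grid, 1, function(g)
      sum(residfun(log(c(g[["fc"]], 1e-18, g[["ca"]])))^2))
    best <- grid[which.min(ssq), ]
    start <- list(fc = best$fc, fb = 1e-18, ca_intracellular = best$ca)
  }
  theta0 <- log(unlist(start[c("fc", "fb", "ca_intracellular")]))
  fit <- minpack.lm::nls.lm(par = theta0, fn = residfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 300, ftol = 1e-14, ptol = 1e-12,
                              epsfcn = 1e-6))
  theta <- fit$par
  est <- exp(theta)
  names(est) <- c("fc", "fb", "ca_intracellular")
  J <- fit$hessian
  sv <- svd(J)$d
  kappa <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  dof <- max(length(fit$fvec) - length(theta), 1)
  sigma2 <- sum(fit$fvec^2) / dof
  cov_theta <- tryCatch(sigma2 * solve(J), error = function(e) NULL)
  se <- if (is.null(cov_theta)) rep(NA_real_, 3) else
    sqrt(pmax(diag(cov_theta), 0)) * est   # delta method for exp()
  names(se) <- names(est)
  flags <- character()
  if (!is.finite(kappa) || kappa > 1e6)
    flags <- c(flags, "weakly identified: flat residual surface (condition number)")
  if (est[["fb"]] > est[["fc"]] / 100)
    flags <- c(flags, "fitted fb > fc/100")
  structure(list(
    params = suppressWarnings(
      exchange_params(est[["fc"]], est[["fb"]],
                      est[["ca_intracellular"]], ca_e, dens,
                      fixed$cell_volume)),
    estimates = est, se = se, resid_norm = sqrt(sum(fit$fvec^2)),
    condition_number = kappa, flags = flags, converged = fit$info %in% 1:4),
    class = "exchange_fit")
}

#' @export
coef.exchange_fit <- function(object, ...) object$estimates

#' @export
print.exchange_fit <- function(x, ...) {
  cat("18O-exchange parameter fit\n")
  for (nm in names(x$estimates))
    cat(sprintf("  %-16s %.4g (se %.2g)\n", nm, x$estimates[[nm]],
                x$se[[nm]]))
  cat(sprintf("  residual norm %.3g, condition number %.3g\n",
              x$resid_norm, x$condition_number))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
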