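#' Cell geometry for the compartment model
#'
#' Spherical cell with nested well-mixed compartments. Volume fractions are
#' model assumptions (flagged as such in reports), not measured quantities.
#'
#' @param cell_volume_m3 total cell volume, m^3 (default 2.87e-17,
#'   a ~3.8 um diameter sphere).
#' @param frac_cytosol,frac_stroma,frac_pyrenoid volume fractions of cytosol,
#'   chloroplast stroma and pyrenoid (defaults 0.5 / 0.3 / 0.02).
#' @param frac_surface volume fraction standing in for the periplasmic +
#'   frustule "surface" layer outside the plasma membrane (default 0.1).
#' @return Object of class `"ccm_geometry"` with per-compartment volumes (m^3).
#' @export
ccm_geometry <- function(cell_volume_m3 = 2.87e-17, frac_cytosol = 0.5,
                         frac_stroma = 0.3, frac_pyrenoid = 0.02,
                         frac_surface = 0.1) {
  fr <- c(frac_cytosol, frac_stroma, frac_pyrenoid)
  stopifnot(cell_volume_m3 > 0, all(fr > 0), all(fr < 1), sum(fr) <= 1,
            frac_surface > 0)
  structure(list(cell_volume_m3 = cell_volume_m3,
                 V = c(surface = frac_surface * cell_volume_m3,
                       cytosol = frac_cytosol * cell_volume_m3,
                       stroma = frac_stroma * cell_volume_m3,
                       pyrenoid = frac_pyrenoid * cell_volume_m3),
                 fractions = c(surface = frac_surface, cytosol = frac_cytosol,
                               stroma = frac_stroma,
                               pyrenoid = frac_pyrenoid)),
            class = "ccm_geometry")
}

#' Full parameter set of the chloroplast-pump compartment model
#'
#' Topology is a chain: bulk <-> surface <-> cytosol <-> stroma <-> pyrenoid.
#' CO2 moves diffusively at every boundary; HCO3- moves by active
#' Michaelis-Menten transport at the plasmalemma (surface -> cytosol) and the
#' chloroplast envelope (cytosol -> stroma), diffusively through frustule and
#' between stroma and pyrenoid, and only marginally (passive leak
#' coefficients, default tiny/zero) across the two membranes.
#'
#' @param conditions a [seawater_conditions()] object for the bulk medium.
#' @param dic_mM bulk DIC, mM; bulk CO2/HCO3- come from [speciate_dic()].
#' @param fc named or positional numeric(4): CO2 transfer coefficients at
#'   bulk-surface, surface-cytosol, cytosol-stroma, stroma-pyrenoid
#'   boundaries, m^3 cell^-1 s^-1.
#' @param fb_frustule HCO3- transfer through the frustule (bulk-surface).
#' @param fb_plasmalemma_passive,fb_envelope_passive passive HCO3- leak
#'   coefficients at the two membranes (defaults 0; membranes treated as
#'   essentially HCO3- impermeable).
#' @param fb_stroma_pyrenoid HCO3- transfer stroma-pyrenoid (no membrane).
#' @param ca named numeric: CA catalytic accelerations (`a`, total rate =
#'   `(1+a) * uncatalyzed`) for `surface`, `cytosol`, `stroma`, `pyrenoid`.
#'   Stroma defaults to 0 (no CA, uncatalyzed chemistry persists); surface 0
#'   (eCA inhibited).
#' @param vmax_plm,k_plm plasmalemma HCO3- transporter: maximal rate
#'   (mol cell^-1 s^-1) and half-saturation (uM, default 50).
#' @param vmax_env,k_env chloroplast-envelope HCO3- pump, same units.
#' @param kcatC,KCair_uM,abundance RuBisCO carboxylation turnover (s^-1),
#'   half-saturation CO2 (uM) and active sites (mol cell^-1).
#' @param respiration mitochondrial CO2 source into the cytosol,
#'   mol cell^-1 s^-1.
#' @param geometry a [ccm_geometry()].
#' @param formulation carbonate-constant formulation name.
#' @return Object of class `"ccm_params"`.
#' @export
ccm_params <- function(conditions, dic_mM = 2,
                       fc = c(1e-13, 2.5e-15, 1.5e-15, 1.2e-16),
                       fb_frustule = 1e-13,
                       fb_plasmalemma_passive = 2.5e-19,
                       fb_envelope_passive = 0,
                       fb_stroma_pyrenoid = 1e-15,
                       ca = c(surface = 0, cytosol = 13000, stroma = 0,
                              pyrenoid = 18000),
                       vmax_plm = 2.8e-18, k_plm = 50,
                       vmax_env = 3.6e-17, k_env = 50,
                       kcatC = 1.83, KCair_uM = 36.3, abundance = 1.24e-17,
                       respiration = 3e-18,
                       geometry = ccm_geometry(),
                       formulation = "mehrbach") {
  stopifnot(inherits(conditions, "seawater_conditions"), length(fc) == 4,
            all(fc >= 0), fb_frustule >= 0, fb_plasmalemma_passive >= 0,
            fb_envelope_passive >= 0, fb_stroma_pyrenoid >= 0,
            length(ca) == 4, all(ca >= 0), vmax_plm >= 0, vmax_env >= 0,
            k_plm > 0, k_env > 0, kcatC >= 0, KCair_uM > 0, abundance > 0,
            respiration >= 0, inherits(geometry, "ccm_geometry"))
  names(fc) <- c("bulk_surface", "surface_cytosol", "cytosol_stroma",
                 "stroma_pyrenoid")
  names(ca) <- c("surface", "cytosol", "stroma", "pyrenoid")
  structure(list(conditions = conditions, dic_mM = dic_mM, fc = fc,
                 fb_frustule = fb_frustule,
                 fb_plasmalemma_passive = fb_plasmalemma_passive,
                 fb_envelope_passive = fb_envelope_passive,
                 fb_stroma_pyrenoid = fb_stroma_pyrenoid, ca = ca,
                 vmax_plm = vmax_plm, k_plm = k_plm, vmax_env = vmax_env,
                 k_env = k_env, kcatC = kcatC, KCair_uM = KCair_uM,
                 abundance = abundance, respiration = respiration,
                 geometry = geometry, formulation = formulation),
            class = "ccm_params")
}

# Internal: assemble the pieces used by both the root solver and the ODE.
# State x: mol m^-3, order (Cs, Bs, Cc, Bc, Cst, Bst, Cp, Bp).
ccm_env <- function(params) {
  carb <- compute_constants(params$conditions, params$formulation)
  bulk <- speciate_dic(params$dic_mM, carb)
  list(carb = carb, Cb = bulk[["co2"]], Bb = bulk[["hco3"]],
       V = params$geometry$V)
}

ccm_fluxes <- function(x, params, env) {
  kf <- env$carb$kf; kr <- env$carb$kr
  V <- env$V
  x <- unname(x)
  Cs <- x[1]; Bs <- x[2]; Cc <- x[3]; Bc <- x[4]
  Cst <- x[5]; Bst <- x[6]; Cp <- x[7]; Bp <- x[8]
  chem <- function(a, Vk, C, B) Vk * (1 + a) * (kr * B - kf * C)
  ch_s <- chem(params$ca[["surface"]], V[["surface"]], Cs, Bs)
  ch_c <- chem(params$ca[["cytosol"]], V[["cytosol"]], Cc, Bc)
  ch_st <- chem(params$ca[["stroma"]], V[["stroma"]], Cst, Bst)
  ch_p <- chem(params$ca[["pyrenoid"]], V[["pyrenoid"]], Cp, Bp)
  t_plm <- params$vmax_plm * Bs / (params$k_plm * 1e-3 + Bs)
  t_env <- params$vmax_env * Bc / (params$k_env * 1e-3 + Bc)
  fix <- params$kcatC * params$abundance * Cp / (params$KCair_uM * 1e-3 + Cp)
  list(
    co2_bulk_surface = params$fc[["bulk_surface"]] * (env$Cb - Cs),
    co2_surface_cytosol = params$fc[["surface_cytosol"]] * (Cs - Cc),
    co2_cytosol_stroma = params$fc[["cytosol_stroma"]] * (Cc - Cst),
    co2_pyrenoid_stroma = params$fc[["stroma_pyrenoid"]] * (Cp - Cst),
    hco3_bulk_surface = params$fb_frustule * (env$Bb - Bs),
    hco3_uptake_plasmalemma = t_plm,
    hco3_passive_plasmalemma = params$fb_plasmalemma_passive * (Bs - Bc),
    hco3_pump_envelope = t_env,
    hco3_passive_envelope = params$fb_envelope_passive * (Bc - Bst),
    hco3_stroma_pyrenoid = params$fb_stroma_pyrenoid * (Bst - Bp),
    chem_surface = ch_s, chem_cytosol = ch_c, chem_stroma = ch_st,
    chem_pyrenoid = ch_p,
    fixation = fix, respiration = params$respiration)
}

# Node residuals, mol cell^-1 s^-1; 0 at steady state.
ccm_residuals <- function(x, params, env) {
  f <- ccm_fluxes(x, params, env)
  c(co2_surface = f$co2_bulk_surface - f$co2_surface_cytosol + f$chem_surface,
    hco3_surface = f$hco3_bulk_surface - f$chem_surface -
      f$hco3_uptake_plasmalemma - f$hco3_passive_plasmalemma,
    co2_cytosol = f$co2_surface_cytosol - f$co2_cytosol_stroma +
      f$chem_cytosol + f$respiration,
    hco3_cytosol = f$hco3_uptake_plasmalemma + f$hco3_passive_plasmalemma -
      f$chem_cytosol - f$hco3_pump_envelope - f$hco3_passive_envelope,
    co2_stroma = f$co2_cytosol_stroma + f$co2_pyrenoid_stroma + f$chem_stroma,
    hco3_stroma = f$hco3_pump_envelope + f$hco3_passive_envelope -
      f$chem_stroma - f$hco3_stroma_pyrenoid,
    co2_pyrenoid = -f$co2_pyrenoid_stroma + f$chem_pyrenoid - f$fixation,
    hco3_pyrenoid = f$hco3_stroma_pyrenoid - f$chem_pyrenoid)
}

ccm_flux_scale <- function(x, params, env) {
  f <- ccm_fluxes(x, params, env)
  max(abs(unlist(f)), 1e-25)
}

#' Time-integrate the compartment model
#'
#' Explicit ODE route to the stationary state; serves as the fallback and the
#' independent cross-check for the root solver (same mass balances, different
#' numerical route).
#'
#' @param params a [ccm_params()] object.
#' @param t_end integration horizon, seconds (default 5000; compartment
#'   turnover times are well under a minute at study-scale parameters).
#' @param init optional initial state (mol m^-3, length 8); default bulk
#'   speciation in every compartment.
#' @param rtol,atol solver tolerances.
#' @return list with `state` (named length-8 vector) and `times` ignored
#'   internals; primarily for use by [solve_steady_state()] and tests.
#' @export
ccm_integrate <- function(params, t_end = 5000, init = NULL,
                          rtol = 1e-10, atol = 1e-14) {
  env <- ccm_env(params)
  if (is.null(init))
    init <- rep(c(env$Cb, env$Bb), 4)
  names(init) <- state_names()
  Vvec <- rep(env$V, each = 2)
  rhs <- function(t, y, p) list(ccm_residuals(y, params, env) / Vvec)
  out <- deSolve::lsoda(init, c(0, t_end / 10, t_end), rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0) stop("ccm time integration failed")
  state <- unlist(out[nrow(out), -1])
  names(state) <- state_names()
  list(state = state, env = env)
}

state_names <- function() c("co2_surface", "hco3_surface", "co2_cytosol",
                            "hco3_cytosol", "co2_stroma", "hco3_stroma",
                            "co2_pyrenoid", "hco3_pyrenoid")

#' Solve the steady state of the chloroplast-pump model
#'
#' Damped Newton iteration on log-concentrations (positivity enforced by
#' construction) with a numerically differenced Jacobian, initialized from
#' bulk speciation in every compartment. If Newton stalls, the solver falls
#' back to time integration to stationarity followed by a Newton polish;
#' the time-integration limit also resolves any multiple-root ambiguity
#' deterministically.
#'
#' @param params a [ccm_params()] object.
#' @param tol convergence tolerance: max node residual relative to the
#'   largest flux magnitude (default 1e-12).
#' @param max_iter Newton iteration cap.
#' @return Object of class `"ccm_steady"`: `state` (named concentrations,
#'   mol m^-3), `fluxes` (named net fluxes, mol cell^-1 s^-1), `residuals`,
#'   `rel_residual`, `params`, `carb`, `bulk`.
#' @export
solve_steady_state <- function(params, tol = 1e-12, max_iter = 200) {
  stopifnot(inherits(params, "ccm_params"))
  env <- ccm_env(params)
  x0 <- rep(c(env$Cb, env$Bb), 4)
  x <- newton_log(x0, params, env, tol, max_iter)
  if (is.null(x)) {
    for (t_end in c(5e3, 1e5)) {
      x <- ccm_integrate(params, t_end = t_end)$state
      x <- newton_log(x, params, env, tol, max_iter) %||% x
      res <- ccm_residuals(x, params, env)
      if (max(abs(res)) / ccm_flux_scale(x, params, env) < 1e-8) break
    }
  }
  res <- ccm_residuals(x, params, env)
  scale <- ccm_flux_scale(x, params, env)
  rel <- max(abs(res)) / scale
  if (rel > 1e-8)
    stop(sprintf("steady-state solver failed: relative residual %.3g", rel))
  fl <- ccm_fluxes(x, params, env)
  names(x) <- state_names()
  structure(list(state = x, fluxes = fl, residuals = res,
                 rel_residual = rel, params = params, carb = env$carb,
                 bulk = c(co2 = env$Cb, hco3 = env$Bb)),
            class = "ccm_steady")
}

# Damped Newton in z = log(x); returns state or NULL on failure.
newton_log <- function(x0, params, env, tol, max_iter) {
  z <- log(pmax(x0, 1e-12))
  fz <- function(z) ccm_residuals(exp(z), params, env)
  r <- fz(z)
  for (it in seq_len(max_iter)) {
    scale <- ccm_flux_scale(exp(z), params, env)
    if (max(abs(r)) / scale < tol) return(exp(z))
    J <- matrix(0, 8, 8)
    h <- 1e-7
    for (j in 1:8) {
      zp <- z; zp[j] <- zp[j] + h
      J[, j] <- (fz(zp) - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    step <- pmin(pmax(step, -2), 2)       # trust region in log space
    lambda <- 1
    n0 <- sum((r / scale)^2)
    repeat {
      zn <- z + lambda * step
      rn <- fz(zn)
      if (all(is.finite(rn)) && sum((rn / scale)^2) < n0) break
      lambda <- lambda / 2
      if (lambda < 1e-6) return(NULL)
    }
    z <- zn; r <- rn
  }
  if (max(abs(r)) / ccm_flux_scale(exp(z), params, env) < tol) exp(z) else NULL
}

#' @export
print.ccm_steady <- function(x, ...) {
  cat("Steady state of the chloroplast-pump compartment model\n")
  st <- x$state
  comp <- c("surface", "cytosol", "stroma", "pyrenoid")
  for (i in seq_along(comp))
    cat(sprintf("  %-9s CO2 %8.3f uM   HCO3 %9.4f mM\n", comp[i],
                st[2 * i - 1] * 1e3, st[2 * i]))
  cat(sprintf("  fixation %.3g mol cell^-1 s^-1; max node residual %.2g of flux scale\n",
              x$fluxes$fixation, x$rel_residual))
  invisible(x)
}

#' @export
summary.ccm_steady <- function(object, ...) {
  m <- derived_metrics(object)
  print(object)
  cat(sprintf("  pump/fixation %.3f, leak/pump %.3f, total transport ratio %.3f\n",
              m$pump_per_fixation, m$leak_per_pump, m$total_transport_ratio))
  cat(sprintf("  chloroplast/cytosol HCO3 gradient %.1f-fold; CO2 supply fraction %.2f\n",
              m$hco3_gradient_fold, m$co2_supply_fraction))
  invisible(m)
}

#' Observable rates implied by a solved steady state
#'
#' The quantities a MIMS experiment reports: net O2 evolution (fixation minus
#' respiration at photosynthetic quotient 1), cellular CO2 uptake (net CO2
#' flux across the plasmalemma) and HCO3- uptake (active + passive
#' plasmalemma flux).
#'
#' @param ss a `"ccm_steady"`.
#' @return list `net_o2`, `u_co2`, `u_hco3`, `bulk_co2_uM`.
#' @export
ccm_observables <- function(ss) {
  f <- ss$fluxes
  list(net_o2 = f$fixation - f$respiration,
       u_co2 = f$co2_surface_cytosol,
       u_hco3 = f$hco3_uptake_plasmalemma + f$hco3_passive_plasmalemma,
       bulk_co2_uM = unname(ss$bulk[["co2"]] * 1e3))
}

#' Derived CCM performance metrics
#'
#' Leakage and transport ratios of the chloroplast pump. `leak_per_pump` uses
#' the net CO2 efflux from the pyrenoid as the leak; with that definition the
#' chloroplast mass balance gives the exact identity
#' `pump_per_fixation * (1 - leak_per_pump) - 1 ==
#'  (stromal net interconversion) / fixation`
#' (pump here includes any passive envelope HCO3- flux). The CO2 efflux from the
#' chloroplast as a whole is also reported (`leak_chloroplast`).
#'
#' @param ss a `"ccm_steady"`.
#' @return list of named metrics; `identity_gap` is the residual of the
#'   identity above (zero to numerical precision for any converged run with
#'   no envelope passive leak).
#' @export
derived_metrics <- function(ss) {
  f <- ss$fluxes
  fix <- f$fixation
  if (fix <= 0) {
    warning("zero fixation: transport/leak metrics undefined")
    return(list(pump_per_fixation = NA_real_, leak_per_pump = NA_real_,
                total_transport_ratio = NA_real_,
                hco3_gradient_fold = ss$state[["hco3_stroma"]] /
                  ss$state[["hco3_cytosol"]],
                co2_supply_fraction = NA_real_, identity_gap = NA_real_,
                leak_chloroplast = f$co2_cytosol_stroma * -1))
  }
  pump <- f$hco3_pump_envelope + f$hco3_passive_envelope
  leak_pyr <- f$co2_pyrenoid_stroma
  Tr <- pump / fix
  L <- leak_pyr / pump
  obs <- ccm_observables(ss)
  stromal_interconv <- f$chem_stroma      # net dehydration HCO3 -> CO2
  list(pump_per_fixation = Tr,
       leak_per_pump = L,
       leak_chloroplast = -f$co2_cytosol_stroma,
       total_transport_ratio = (f$hco3_uptake_plasmalemma + pump) / fix,
       hco3_gradient_fold = unname(ss$state[["hco3_stroma"]] /
                                     ss$state[["hco3_cytosol"]]),
       co2_supply_fraction = obs$u_co2 / (obs$u_co2 + obs$u_hco3),
       stromal_interconv_per_fixation = stromal_interconv / fix,
       identity_gap = Tr * (1 - L) - 1 - stromal_interconv / fix)
}

#' Calibrate transporter capacities against observed rates
#'
#' Adjusts the plasmalemma and chloroplast-envelope HCO3- transporter
#' maximal rates (log scale, Levenberg-Marquardt) so the solved steady state
#' reproduces observed net O2 evolution, CO2 uptake and HCO3- uptake. All
#' measured parameters (mass-transfer coefficients, CA activities, RuBisCO
#' kinetics, respiration) are held fixed.
#'
#' @param params starting [ccm_params()]; its `vmax_plm` / `vmax_env` seed
#'   the search.
#' @param observed list with `net_o2`, `u_co2`, `u_hco3`
#'   (mol cell^-1 s^-1), e.g. from [partition_ci_uptake()] or
#'   [ccm_observables()].
#' @param free character vector of parameters to adjust; default
#'   `c("vmax_plm", "vmax_env")` (optionally add `"ca_pyrenoid"`).
#' @return Object of class `"ccm_calibration"`: calibrated `params`, the
#'   solved `steady` state, `residuals` (relative), `converged`.
#' @export
calibrate <- function(params, observed,
                      free = c("vmax_plm", "vmax_env")) {
  stopifnot(inherits(params, "ccm_params"),
            all(c("net_o2", "u_co2", "u_hco3") %in% names(observed)))
  tot <- observed$u_co2 + observed$u_hco3
  if (abs(tot - observed$net_o2) > 0.2 * abs(observed$net_o2))
    warning("observed u_co2 + u_hco3 deviates from net O2 by > 20%")
  getp <- function(p, nm) if (nm == "ca_pyrenoid") p$ca[["pyrenoid"]] else p[[nm]]
  setp <- function(p, nm, v) {
    if (nm == "ca_pyrenoid") p$ca[["pyrenoid"]] <- v else p[[nm]] <- v
    p
  }
  theta0 <- log(pmax(vapply(free, function(nm) getp(params, nm), 0), 1e-25))
  obsv <- c(observed$net_o2, observed$u_co2, observed$u_hco3)
  sc <- pmax(abs(obsv), 1e-20)
  residfun <- function(theta) {
    p <- params
    for (i in seq_along(free)) p <- setp(p, free[i], exp(theta[i]))
    ss <- tryCatch(solve_steady_state(p), error = function(e) NULL)
    if (is.null(ss)) return(rep(10, 3))
    o <- ccm_observables(ss)
    (c(o$net_o2, o$u_co2, o$u_hco3) - obsv) / sc
  }
  fit <- minpack.lm::nls.lm(par = theta0, fn = residfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-12, ptol = 1e-10))
  p <- params
  for (i in seq_along(free)) p <- setp(p, free[i], exp(fit$par[i]))
  ss <- solve_steady_state(p)
  structure(list(params = p, steady = ss, residuals = fit$fvec,
                 converged = fit$info %in% 1:4,
                 estimates = stats::setNames(exp(fit$par), free)),
            class = "ccm_calibration")
}

#' @export
coef.ccm_calibration <- function(object, ...) object$estimates

#' @export
print.ccm_calibration <- function(x, ...) {
  cat("CCM calibration", if (x$converged) "(converged)" else
    "(NOT converged)", "\n")
  for (nm in names(x$estimates))
    cat(sprintf("  %-10s %.4g\n", nm, x$estimates[[nm]]))
  cat(sprintf("  max relative misfit %.3g\n", max(abs(x$residuals))))
  invisible(x)
}

#' Flux map as a diagram-ready edge list
#'
#' @param ss a `"ccm_steady"`.
#' @return data.frame with columns `from`, `to`, `species`, `flux`
#'   (mol cell^-1 s^-1, net in the `from` -> `to` direction).
#' @export
flux_edge_list <- function(ss) {
  f <- ss$fluxes
  data.frame(
    from = c("bulk", "surface", "cytosol", "pyrenoid", "bulk", "surface",
             "surface", "cytosol", "cytosol", "stroma", "mitochondria",
             "pyrenoid"),
    to = c("surface", "cytosol", "stroma", "stroma", "surface", "cytosol",
           "cytosol", "stroma", "stroma", "pyrenoid", "cytosol", "rubisco"),
    species = c("CO2", "CO2", "CO2", "CO2", "HCO3", "HCO3(active)",
                "HCO3(passive)", "HCO3(pump)", "HCO3(passive)", "HCO3",
                "CO2", "CO2(fixation)"),
    flux = c(f$co2_bulk_surface, f$co2_surface_cytosol, f$co2_cytosol_stroma,
             f$co2_pyrenoid_stroma, f$hco3_bulk_surface,
             f$hco3_uptake_plasmalemma, f$hco3_passive_plasmalemma,
             f$hco3_pump_envelope, f$hco3_passive_envelope,
             f$hco3_stroma_pyrenoid, f$respiration, f$fixation),
    stringsAsFactors = FALSE)
}
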