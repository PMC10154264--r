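#' Scenario specification for synthetic MIMS experiments
#'
#' Describes a dark-light-dark chamber experiment (optionally a stepwise DIC
#' titration) with known ground truth, for generating study-shaped traces.
#'
#' @param conditions a [seawater_conditions()] object.
#' @param ccm a [ccm_params()] object; in `rate_model = "ccm"` the light
#'   rates of each cycle come from [solve_steady_state()] at that cycle's
#'   bulk DIC.
#' @param rate_model `"ccm"` (default) or `"mm"`; `"mm"` uses a direct
#'   Michaelis-Menten dependence of net O2 evolution on bulk CO2 with the
#'   ground-truth `mm_vmax` / `mm_k_half` below, which keeps the generating
#'   half-saturation an explicit known truth for recovery tests.
#' @param mm_vmax,mm_k_half MM ground truth for `rate_model = "mm"`:
#'   maximal net O2 evolution (mol cell^-1 s^-1) and half-saturation bulk
#'   CO2 (uM).
#' @param mm_co2_fraction fraction of carbon uptake taken as CO2 in
#'   `"mm"` mode.
#' @param dic_steps_mM DIC level at the start of each dark-light-dark cycle,
#'   mM (one cycle per element). The chamber is reset to this DIC (a
#'   bicarbonate addition) before the cycle.
#' @param dark_s,light_s durations of dark and light segments, seconds.
#' @param dt_s sampling interval, seconds.
#' @param cell_density cells per m^3.
#' @param noise_sd_uM additive Gaussian noise sd per channel, micromolar,
#'   named `o2` and `co2`.
#' @param seed integer seed; mandatory when any noise is non-zero.
#' @return Object of class `"mims_scenario"`.
#' @export
mims_scenario <- function(conditions, ccm = NULL, rate_model = c("ccm", "mm"),
                          mm_vmax = 2e-17, mm_k_half = 1, mm_co2_fraction = 0.8,
                          dic_steps_mM = 2, dark_s = 300, light_s = 600,
                          dt_s = 5, cell_density = 3.5e12,
                          noise_sd_uM = c(o2 = 0, co2 = 0), seed = NULL) {
  rate_model <- match.arg(rate_model)
  stopifnot(inherits(conditions, "seawater_conditions"),
            dark_s > 0, light_s > 0, dt_s > 0, cell_density > 0,
            all(noise_sd_uM >= 0), all(dic_steps_mM > 0))
  if (any(noise_sd_uM > 0) && is.null(seed))
    stop("seed is mandatory for noisy generation")
  if (rate_model == "ccm" && is.null(ccm))
    ccm <- ccm_params(conditions)
  structure(list(conditions = conditions, ccm = ccm, rate_model = rate_model,
                 mm_vmax = mm_vmax, mm_k_half = mm_k_half,
                 mm_co2_fraction = mm_co2_fraction,
                 dic_steps_mM = dic_steps_mM, dark_s = dark_s,
                 light_s = light_s, dt_s = dt_s, cell_density = cell_density,
                 noise_sd_uM = noise_sd_uM, seed = seed),
            class = "mims_scenario")
}

#' Generate a synthetic dark-light-dark MIMS trace
#'
#' Forward-simulates closed-chamber chemistry (uncatalyzed CO2/HCO3-
#' interconversion at clamped pH) plus cellular exchange. In the light the
#' per-cell rates are held at the quasi-steady values implied by the scenario
#' rate model at the cycle's bulk composition; in the dark the cell respires
#' (CO2 source, O2 sink). Additive Gaussian noise is applied per channel
#' under the scenario seed; the noise-free trace and the per-cycle true rates
#' are returned alongside.
#'
#' @param spec a [mims_scenario()].
#' @return list of class `"synth_mims"`: `trace` (a `"mims_trace"`),
#'   `clean` (noise-free trace) and `truth` (per-cycle data.frame of the
#'   generating rates: `net_o2`, `r_dark`, `u_co2`, `u_hco3`, `bulk_co2_uM`,
#'   `dic_mM`).
#' @export
gen_mims_trace <- function(spec) {
  stopifnot(inherits(spec, "mims_scenario"))
  carb <- compute_constants(spec$conditions)
  n <- spec$cell_density
  resp <- if (spec$rate_model == "ccm") spec$ccm$respiration else
    0.25 * spec$mm_vmax
  r2 <- carb$ratio_co3_hco3
  time0 <- 0
  rows <- list(); truth <- list()
  o2_0 <- 0.25   # mol/m^3 (~250 uM, air-equilibrated)
  o2 <- o2_0
  for (k in seq_along(spec$dic_steps_mM)) {
    dic <- spec$dic_steps_mM[k]
    sp <- speciate_dic(dic, carb)
    C <- sp[["co2"]]; B <- sp[["hco3"]]
    mm_mode <- spec$rate_model == "mm"
    if (!mm_mode) {
      p <- spec$ccm; p$dic_mM <- dic
      ss <- solve_steady_state(p)
      obs <- ccm_observables(ss)
      net_o2 <- obs$net_o2; u_co2 <- obs$u_co2; u_hco3 <- obs$u_hco3
    }
    for (segname in c(sprintf("dark%da", k), sprintf("light%d", k),
                      sprintf("dark%db", k))) {
      light <- grepl("light", segname)
      dur <- if (light) spec$light_s else spec$dark_s
      tseg <- seq(0, dur, by = spec$dt_s)
      rhs <- function(t, y, p) {
        if (light) {
          if (mm_mode) {
            # rates respond instantaneously to the current bulk CO2
            uo <- spec$mm_vmax * (y[1] * 1e3) / (spec$mm_k_half + y[1] * 1e3)
            uc <- spec$mm_co2_fraction * uo
          } else {
            uo <- net_o2; uc <- u_co2
          }
          ub <- uo - uc
        } else {
          uc <- -resp; ub <- 0; uo <- -resp
        }
        list(c(C = carb$kr * y[2] - carb$kf * y[1] - n * uc,
               B = carb$kf * y[1] - carb$kr * y[2] - n * ub,
               O = n * uo))
      }
      sol <- deSolve::lsoda(c(C = C, B = B, O = o2), tseg, rhs, NULL,
                            rtol = 1e-10, atol = 1e-14)
      m <- as.data.frame(sol)
      rows[[length(rows) + 1]] <- data.frame(
        time_s = time0 + m$time, o2_uM = m$C * 0 + m$O * 1e3,
        co2_uM = m$C * 1e3, segment = segname)
      if (light) {
        # ground truth at the quasi-steady tail (final 60% of the segment)
        tail_i <- m$time >= 0.4 * dur
        Cbar <- mean(m$C[tail_i])
        if (mm_mode) {
          net_o2 <- spec$mm_vmax * (Cbar * 1e3) / (spec$mm_k_half + Cbar * 1e3)
          u_co2 <- spec$mm_co2_fraction * net_o2
          u_hco3 <- net_o2 - u_co2
        }
        truth[[k]] <- data.frame(cycle = k, dic_mM = dic, net_o2 = net_o2,
                                 r_dark = -resp, u_co2 = u_co2,
                                 u_hco3 = u_hco3, bulk_co2_uM = Cbar * 1e3)
      }
      last <- nrow(m)
      C <- m$C[last]; B <- m$B[last]; o2 <- m$O[last]
      time0 <- time0 + dur + spec$dt_s
    }
  }
  df <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  mk <- function(o2v, co2v) mims_trace(df$time_s, o2v, co2v,
                                       segment = df$segment,
                                       cell_density = n,
                                       conditions = spec$conditions)
  clean <- mk(df$o2_uM, df$co2_uM)
  if (any(spec$noise_sd_uM > 0)) {
    set.seed(spec$seed)
    o2n <- df$o2_uM + stats::rnorm(nrow(df), 0, spec$noise_sd_uM[["o2"]])
    co2n <- pmax(df$co2_uM +
                   stats::rnorm(nrow(df), 0, spec$noise_sd_uM[["co2"]]), 0)
    noisy <- mk(pmax(o2n, 0), co2n)
  } else noisy <- clean
  structure(list(trace = noisy, clean = clean, truth = truth),
            class = "synth_mims")
}

#' Scenario for a synthetic 18O-exchange assay
#'
#' @param conditions a [seawater_conditions()] object.
#' @param params true [exchange_params()] (its `cell_density` applies after
#'   cell addition).
#' @param t_add cell addition time, seconds (default 300: a cell-free phase
#'   long enough to pin the uncatalyzed rates).
#' @param t_end assay end, seconds (default 1800, a ~30 min assay).
#' @param n_samples number of evenly spaced samples.
#' @param dic_mM,frac18O labeled bicarbonate spike, see [exchange_init()].
#' @param noise_sd_uM additive Gaussian sd per isotopologue channel, uM.
#' @param noise_mult multiplicative Gaussian noise fraction (e.g. 0.02).
#' @param seed integer seed; mandatory when any noise is non-zero.
#' @return Object of class `"exchange_scenario"`.
#' @export
exchange_scenario <- function(conditions, params, t_add = 300, t_end = 1800,
                              n_samples = 300, dic_mM = 2, frac18O = 0.98,
                              noise_sd_uM = 0, noise_mult = 0, seed = NULL) {
  stopifnot(inherits(conditions, "seawater_conditions"),
            inherits(params, "exchange_params"),
            t_add > 0, t_end > t_add, n_samples >= 10,
            noise_sd_uM >= 0, noise_mult >= 0)
  if ((noise_sd_uM > 0 || noise_mult > 0) && is.null(seed))
    stop("seed is mandatory for noisy generation")
  structure(list(conditions = conditions, params = params, t_add = t_add,
                 t_end = t_end, n_samples = n_samples, dic_mM = dic_mM,
                 frac18O = frac18O, noise_sd_uM = noise_sd_uM,
                 noise_mult = noise_mult, seed = seed),
            class = "exchange_scenario")
}

#' Generate a synthetic 18O-exchange isotopologue trace
#'
#' Cell-free chemistry before `t_add`, full exchange model after; sampled
#' onto an even grid and noised (additive and/or multiplicative Gaussian)
#' under the scenario seed.
#'
#' @param spec an [exchange_scenario()].
#' @return list of class `"synth_exchange"`: `trace` (`"mims_trace"` whose
#'   isotopologue columns carry the assay), `clean`, `sim` (the full
#'   `"exchange_sim"`), `truth` (the generating [exchange_params()] and
#'   initial state).
#' @export
gen_exchange_trace <- function(spec) {
  stopifnot(inherits(spec, "exchange_scenario"))
  carb <- compute_constants(spec$conditions)
  init <- exchange_init(spec$dic_mM, spec$frac18O)
  times <- seq(0, spec$t_end, length.out = spec$n_samples)
  p <- spec$params
  sim <- exchange_forward(p$fc, p$fb, p$ca_intracellular, p$ca_extracellular,
                          p$cell_density, p$cell_volume, init, carb, times,
                          spec$t_add)
  seg <- ifelse(sim$time < spec$t_add, "precell", "postcell")
  c45 <- sim$ce45 * 1e3; c47 <- sim$ce47 * 1e3; c49 <- sim$ce49 * 1e3
  mk <- function(a, b, d) mims_trace(sim$time, rep(250, nrow(sim)), a, b, d,
                                     segment = seg,
                                     cell_density = p$cell_density,
                                     conditions = spec$conditions)
  clean <- mk(c45, c47, c49)
  if (spec$noise_sd_uM > 0 || spec$noise_mult > 0) {
    set.seed(spec$seed)
    noise <- function(y) pmax(y * (1 + stats::rnorm(length(y), 0,
                                                    spec$noise_mult)) +
                                stats::rnorm(length(y), 0, spec$noise_sd_uM),
                              0)
    noisy <- mk(noise(c45), noise(c47), noise(c49))
  } else noisy <- clean
  structure(list(trace = noisy, clean = clean, sim = sim,
                 truth = list(params = p, init = init, t_add = spec$t_add)),
            class = "synth_exchange")
}
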