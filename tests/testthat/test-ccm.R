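test_that("a dead cell equilibrates every compartment to bulk speciation", {
  cond <- cond_at(18)
  p <- ccm_params(cond, ca = c(surface = 0, cytosol = 0, stroma = 0,
                               pyrenoid = 0),
                  vmax_plm = 0, vmax_env = 0, kcatC = 0, respiration = 0)
  ss <- solve_steady_state(p)
  sp <- speciate_dic(2, cond)
  expect_equal(unname(ss$state[c(1, 3, 5, 7)]), rep(sp[["co2"]], 4),
               tolerance = 1e-9)
  expect_equal(unname(ss$state[c(2, 4, 6, 8)]), rep(sp[["hco3"]], 4),
               tolerance = 1e-9)
  expect_lt(max(abs(unlist(ss$fluxes))), 1e-25)
})

test_that("node balances close at every converged steady state", {
  for (tc in c(10, 18, 25)) {
    ss <- solve_steady_state(ccm_preset(tc))
    scale <- max(abs(unlist(ss$fluxes)))
    expect_lt(max(abs(ss$residuals)) / scale, 1e-9)
    expect_true(all(ss$state > 0))
    expect_gt(ss$fluxes$fixation, 0)
  }
})

test_that("root solver agrees with the time-integration route", {
  for (p in random_ccm_params(5)) {
    ss <- solve_steady_state(p)
    ti <- ccm_integrate(p)
    expect_lt(max(abs(ss$state - ti$state) / abs(ss$state)), 1e-6)
  }
})

test_that("the chloroplast mass-balance identity holds exactly", {
  for (p in c(list(ccm_preset(10), ccm_preset(18), ccm_preset(25)),
              random_ccm_params(3, seed = 303))) {
    m <- derived_metrics(solve_steady_state(p))
    expect_lt(abs(m$identity_gap), 1e-9)
  }
})

test_that("a closed chloroplast fixes every pumped bicarbonate", {
  p <- ccm_preset(18)
  p$fc[["stroma_pyrenoid"]] <- 0   # no CO2 escape from the pyrenoid
  # negligible stroma volume: no interconversion en route to the pyrenoid
  p$geometry <- ccm_geometry(frac_cytosol = 0.5, frac_stroma = 1e-4,
                             frac_pyrenoid = 0.02)
  # the pump must stay below RuBisCO capacity or no steady state exists
  p$vmax_env <- 1.2e-17
  m <- derived_metrics(solve_steady_state(p))
  expect_equal(m$leak_per_pump, 0)
  expect_equal(m$pump_per_fixation, 1 + m$stromal_interconv_per_fixation,
               tolerance = 1e-9)
  expect_equal(m$pump_per_fixation, 1, tolerance = 1e-3)
})

test_that("the calibrated warm state matches the reported compartment pattern", {
  ss <- solve_steady_state(ccm_preset(25))
  st <- ss$state
  expect_gt(st[["hco3_stroma"]], 20)           # ~30 mM chloroplast pool
  expect_lt(st[["hco3_stroma"]], 40)
  expect_gt(st[["hco3_cytosol"]], 0.4)         # ~0.7 mM cytosol pool
  expect_lt(st[["hco3_cytosol"]], 1.1)
  m <- derived_metrics(ss)
  expect_gt(m$hco3_gradient_fold, 25)          # ~40-fold gradient
  expect_lt(m$hco3_gradient_fold, 60)
})

test_that("a stronger envelope pump never lowers chloroplast bicarbonate", {
  p <- ccm_preset(18)
  b1 <- solve_steady_state(p)$state[["hco3_stroma"]]
  p$vmax_env <- 1.5 * p$vmax_env
  b2 <- solve_steady_state(p)$state[["hco3_stroma"]]
  expect_gte(b2, b1)
})

test_that("calibration recovers self-generated transporter capacities", {
  p <- ccm_preset(18)
  obs <- ccm_observables(solve_steady_state(p))
  start <- p; start$vmax_plm <- 1e-18; start$vmax_env <- 1e-17
  cal <- calibrate(start, obs)
  expect_equal(coef(cal)[["vmax_plm"]], p$vmax_plm, tolerance = 0.02)
  expect_equal(coef(cal)[["vmax_env"]], p$vmax_env, tolerance = 0.02)
  # 5% observation noise: recovery within 15%
  set.seed(17)
  obs_n <- lapply(obs[c("net_o2", "u_co2", "u_hco3")],
                  function(x) x * (1 + stats::rnorm(1, 0, 0.05)))
  cal_n <- suppressWarnings(calibrate(start, obs_n))
  expect_equal(coef(cal_n)[["vmax_plm"]], p$vmax_plm, tolerance = 0.15)
  expect_equal(coef(cal_n)[["vmax_env"]], p$vmax_env, tolerance = 0.15)
})

test_that("zero observed bicarbonate uptake drives the plasmalemma pump to zero", {
  p <- ccm_preset(18)
  obs <- ccm_observables(solve_steady_state(p))
  obs$u_co2 <- obs$u_co2 + obs$u_hco3
  obs$u_hco3 <- 0
  cal <- suppressWarnings(calibrate(p, obs))
  expect_lt(coef(cal)[["vmax_plm"]], 1e-20)
})

test_that("rising carbon demand shifts supply toward bulk bicarbonate uptake", {
  obs18 <- ccm_observables(solve_steady_state(ccm_preset(18)))
  obs25 <- ccm_observables(solve_steady_state(ccm_preset(25)))
  start18 <- ccm_preset(18); start18$vmax_plm <- 1e-18; start18$vmax_env <- 2e-17
  start25 <- ccm_preset(25); start25$vmax_plm <- 1e-18; start25$vmax_env <- 2e-17
  cal18 <- calibrate(start18, obs18)
  cal25 <- calibrate(start25, obs25)
  f18 <- cal18$steady$fluxes; f25 <- cal25$steady$fluxes
  demand_ratio <- obs25$net_o2 / obs18$net_o2
  plm_ratio <- f25$hco3_uptake_plasmalemma / f18$hco3_uptake_plasmalemma
  pump_ratio <- f25$hco3_pump_envelope / f18$hco3_pump_envelope
  expect_gt(plm_ratio, demand_ratio)   # bulk HCO3 uptake rises fastest
  expect_lt(pump_ratio, plm_ratio)     # the chloroplast pump saturates
})

test_that("flux edge list mirrors the flux map", {
  ss <- solve_steady_state(ccm_preset(18))
  el <- flux_edge_list(ss)
  expect_equal(nrow(el), 12)
  expect_equal(el$flux[el$species == "CO2(fixation)"], ss$fluxes$fixation)
})
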