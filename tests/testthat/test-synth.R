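test_that("generation is deterministic under a fixed seed", {
  spec <- mims_scenario(cond_at(18), noise_sd_uM = c(o2 = 0.5, co2 = 0.05),
                        seed = 21)
  g1 <- gen_mims_trace(spec)
  g2 <- gen_mims_trace(spec)
  expect_identical(g1$trace, g2$trace)
  expect_error(mims_scenario(cond_at(18),
                             noise_sd_uM = c(o2 = 0.5, co2 = 0)),
               "seed")
  e <- exchange_scenario(cond_at(18), exchange_preset(18), noise_mult = 0.02,
                         seed = 4)
  expect_identical(gen_exchange_trace(e)$trace, gen_exchange_trace(e)$trace)
})

test_that("noise-free traces return the forward model and its true rates", {
  g <- gen_mims_trace(mims_scenario(cond_at(18)))
  expect_identical(g$trace, g$clean)
  sr <- segment_rate(g$trace, "light1", "o2")
  expect_equal(sr$rate, g$truth$net_o2, tolerance = 1e-9)
  rd <- segment_rate(g$trace, "dark1b", "o2")
  expect_equal(rd$rate, g$truth$r_dark, tolerance = 1e-6)
})

test_that("a DIC titration recovers the generating half-saturation downstream", {
  spec <- mims_scenario(cond_at(18), rate_model = "mm", mm_vmax = 2e-17,
                        mm_k_half = 1, dic_steps_mM = dic_titration_mM,
                        noise_sd_uM = c(o2 = 0.6, co2 = 0.05), seed = 11)
  g <- gen_mims_trace(spec)
  rates <- vapply(seq_along(dic_titration_mM), function(k)
    segment_rate(g$trace, sprintf("light%d", k), "o2")$rate, 0)
  fm <- fit_mm(g$truth$bulk_co2_uM, rates)
  expect_lt(abs(fm$k_half - 1), 0.25)
  expect_equal(fm$vmax, 2e-17, tolerance = 0.15)
})

test_that("doubling the generating CO2 permeability doubles the fitted one", {
  carb <- carb_at(18)
  fit_of <- function(fc, seed) {
    p <- exchange_params(fc, 2.5e-18, 2000, 0, 3.5e12, 2.87e-17)
    g <- gen_exchange_trace(exchange_scenario(cond_at(18), p,
                                              noise_mult = 0.02, seed = seed))
    coef(estimate_params(g$trace, carb,
                         fixed = list(cell_volume = 2.87e-17, t_add = 300,
                                      init = exchange_init(2, 0.98))))[["fc"]]
  }
  ratio <- fit_of(4e-15, 8) / fit_of(2e-15, 8)
  expect_equal(ratio, 2, tolerance = 0.1)
})

test_that("a warming series with rising true fc yields rising fitted fc", {
  fits <- vapply(c(10, 18, 25), function(tc) {
    truth <- exchange_preset(tc)
    g <- gen_exchange_trace(exchange_scenario(cond_at(tc), truth))
    coef(estimate_params(g$trace, carb_at(tc),
                         fixed = list(cell_volume = truth$cell_volume,
                                      t_add = 300,
                                      init = exchange_init(2, 0.98))))[["fc"]]
  }, 0)
  expect_true(all(diff(fits) > 0))
})
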