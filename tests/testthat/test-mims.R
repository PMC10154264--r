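make_linear_trace <- function(slope_uM_s = -0.02, n = 121, dens = 3.5e12,
                              noise = 0, seed = NULL) {
  t <- seq(0, 600, length.out = n)
  o2 <- 250 + slope_uM_s * t
  if (noise > 0) { set.seed(seed); o2 <- o2 + stats::rnorm(n, 0, noise) }
  mims_trace(t, o2, co2_45 = rep(15, n), segment = rep("light1", n),
             cell_density = dens, conditions = cond_at(18))
}

test_that("trace construction validates its inputs", {
  expect_error(mims_trace(c(1, 1, 2), c(1, 2, 3), c(1, 2, 3),
                          segment = rep("d", 3), cell_density = 1,
                          conditions = cond_at(18)), "increasing")
  expect_error(make_linear_trace(slope_uM_s = -1), "negative")
  tr <- make_linear_trace()
  expect_s3_class(tr, "mims_trace")
  expect_output(print(tr), "MIMS trace")
})

test_that("trace files round-trip through delimited text", {
  tr <- make_linear_trace()
  path <- tempfile(fileext = ".tsv")
  write_mims_trace(tr, path)
  tr2 <- read_mims_trace(path)
  expect_equal(as.data.frame(tr2), as.data.frame(tr), tolerance = 1e-9)
  expect_equal(attr(tr2, "cell_density"), attr(tr, "cell_density"))
  expect_equal(attr(tr2, "conditions")$pH, 8.10)
})

test_that("segment rates convert slopes to per-cell rates", {
  dens <- 3.5e12
  tr <- make_linear_trace(slope_uM_s = -0.02, dens = dens)
  sr <- segment_rate(tr, "light1", "o2")
  expect_equal(sr$rate, -0.02 * 1e-3 / dens, tolerance = 1e-12)
  # noisy: estimate within 3 standard errors of truth
  trn <- make_linear_trace(slope_uM_s = -0.02, noise = 0.5, seed = 31)
  srn <- segment_rate(trn, "light1", "o2")
  expect_lt(abs(srn$rate - sr$rate), 3 * srn$se)
  # respiring dark segment has a negative O2 rate
  dark <- mims_trace(0:100, 250 - 0.01 * (0:100), co2_45 = rep(15, 101),
                     segment = rep("dark1", 101), cell_density = dens,
                     conditions = cond_at(18))
  expect_lt(segment_rate(dark, "dark1", "o2")$rate, 0)
  expect_error(segment_rate(tr, "absent", "o2"), "not found")
})

test_that("daily net O2 follows the 16:8 diel weighting", {
  expect_equal(daily_net_o2(0, 0), 0)
  expect_equal(daily_net_o2(3.0e-17, -1.5e-17), 1.5e-17)
  p <- 2e-17
  expect_equal(daily_net_o2(p, -2 * p), 0)  # balance point of net growth
  expect_warning(daily_net_o2(-1e-18, -1e-18), "sign")
})

test_that("cytosolic CO2 follows the diffusive balance and flags inconsistency", {
  expect_equal(cytosolic_co2(12, 0, 2.5e-15)$co2_cyt_uM, 12)
  fc <- 2.5e-15
  expect_equal(cytosolic_co2(10, fc * 8e-3, fc)$co2_cyt_uM, 2)
  expect_warning(res <- cytosolic_co2(10, fc * 10.5e-3, fc), "negative")
  expect_lt(res$co2_cyt_uM, 0)   # flagged, not clipped
  expect_error(cytosolic_co2(10, 1e-18, 0), "positive")
  # monotone decreasing in uptake, increasing in fc
  expect_gt(cytosolic_co2(10, 1e-18, 2 * fc)$co2_cyt_uM,
            cytosolic_co2(10, 1e-18, fc)$co2_cyt_uM)
})

test_that("gross O2 adds back respiration", {
  expect_equal(gross_o2(1.5e-17, -3e-18), 1.8e-17)
})

test_that("Michaelis-Menten fitting is exact on exact data and robust to noise", {
  co <- c(0.3, 0.7, 1.5, 3, 6, 12)
  f <- fit_mm(co, 5 * co / (1 + co))
  expect_equal(f$vmax, 5, tolerance = 1e-6)
  expect_equal(f$k_half, 1, tolerance = 1e-6)
  expect_error(fit_mm(rep(2, 5), rep(1, 5)), "degenerate")
  expect_error(fit_mm(co[1:3], co[1:3]), "4 points")
  set.seed(12)
  co8 <- c(0.2, 0.5, 1, 2, 4, 8, 12, 16)
  y <- 5 * co8 / (1 + co8) + stats::rnorm(8, 0, 0.25)  # sd = 5% of vmax
  fn <- fit_mm(co8, y)
  expect_lt(abs(fn$k_half - 1) / 1, 0.25)
})

test_that("Ci uptake partitioning recovers generating uptake rates", {
  carb <- carb_at(18)
  g <- gen_mims_trace(mims_scenario(cond_at(18)))
  part <- partition_ci_uptake(g$trace, carb, dic_mM = 2)
  expect_equal(part$u_co2, g$truth$u_co2, tolerance = 0.05)
  expect_equal(part$u_hco3, g$truth$u_hco3, tolerance = 0.05)
  # conservation by construction
  expect_equal(part$u_co2 + part$u_hco3, part$total_c_uptake)
  # HCO3-only uptake: the CO2 channel follows pure chemistry
  gb <- gen_mims_trace(mims_scenario(cond_at(18), rate_model = "mm",
                                     mm_vmax = 1.5e-17, mm_k_half = 1,
                                     mm_co2_fraction = 0))
  pb <- partition_ci_uptake(gb$trace, carb_at(18), dic_mM = 2)
  expect_lt(abs(pb$u_co2) / pb$total_c_uptake, 0.02)
  expect_equal(pb$u_hco3, pb$total_c_uptake, tolerance = 0.02)
})

test_that("a warm high-bicarbonate scenario shows a reduced CO2 supply share", {
  g <- gen_mims_trace(mims_scenario(cond_at(25), ccm = ccm_preset(25)))
  p <- partition_ci_uptake(g$trace, carb_at(25), dic_mM = 2)
  expect_gt(p$co2_fraction, 0.4)
  expect_lt(p$co2_fraction, 0.6)
})
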