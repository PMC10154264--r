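test_that("Arcus fit recovers generating constants and degenerates gracefully", {
  # constant rates: the representable solution a = b = 0, c = ln k0
  f0 <- fit_arcus(c(270, 300, 330), rep(2.5, 3))
  expect_equal(unname(coef(f0)), c(0, 0, log(2.5)), tolerance = 1e-9)
  expect_equal(eval_arcus(f0, 285), 2.5, tolerance = 1e-9)
  # round trip against known constants at the assay temperatures
  truth <- c(a = 4.2, b = -9000, c = 10.5)
  temps <- c(279.15, 285.15, 291.15, 298.15)
  rates <- exp(truth["a"] * log(temps) + truth["b"] / temps + truth["c"])
  fr <- fit_arcus(temps, rates)
  expect_equal(unname(coef(fr)), unname(truth), tolerance = 1e-6)
  # identity member
  expect_equal(eval_arcus(list(a = 0, b = 0, c = 0,
                               temperature_range = c(1, 1000)), 291), 1)
  expect_error(fit_arcus(c(280, 290), c(1, 2)), "3 points")
  expect_error(fit_arcus(c(280, 280, 290), c(1, 1, 2)), "duplicate")
  expect_error(fit_arcus(c(280, 290, 300), c(1, -1, 2)), "positive")
  expect_error(eval_arcus(f0, -5), "positive")
})

test_that("three-point Arcus fit through the assay endpoints is exact", {
  # measured endpoints plus the packaged interpolated midpoint
  tab <- rubisco_params()
  temps <- tab$temperature_C + 273.15
  f <- fit_arcus(temps, tab$kcatC_s)
  expect_equal(eval_arcus(f, 283.15), 0.9, tolerance = 1e-9)
  expect_equal(eval_arcus(f, 298.15), 3.3, tolerance = 1e-9)
  # monotone data: interior evaluations lie between neighbouring inputs
  dense <- eval_arcus(f, seq(283.15, 298.15, by = 0.05))
  expect_true(all(dense >= 0.9 - 1e-9 & dense <= 3.3 + 1e-9))
})

test_that("saturation arithmetic reproduces the reported percentages", {
  expect_equal(round(100 * saturation(3.0e-17, 3.3, 1.24e-17)), 73)
  expect_equal(round(100 * saturation(0.90e-17, 0.9, 1.24e-17)), 81)
  expect_equal(saturation(2e-17, 2, 1e-17), 1.0)
  expect_error(saturation(3e-17, 1, 1e-17), "exceeds capacity")
})

test_that("Michaelis-Menten inversion gives CO2 at RuBisCO", {
  s25 <- saturation(3.0e-17, 3.3, 1.24e-17)
  expect_equal(round(co2_at_rubisco(55, s25)), 151)
  expect_equal(co2_at_rubisco(40, 0.5), 40)  # half saturation definition
  s10 <- saturation(0.90e-17, 0.9, 1.24e-17)
  expect_equal(round(co2_at_rubisco(22, s10)), 92)
  # round trip for arbitrary C, KC
  set.seed(5)
  for (i in 1:10) {
    C <- stats::runif(1, 0.1, 500); KC <- stats::runif(1, 1, 100)
    expect_equal(co2_at_rubisco(KC, C / (C + KC)), C, tolerance = 1e-9)
  }
  expect_error(co2_at_rubisco(55, 1), "inside")
  expect_error(co2_at_rubisco(55, 0), "inside")
})

test_that("abundance estimation matches its definition and the reported minimum", {
  expect_equal(estimate_abundance(2.0e-17, 2.0, 0.8), 1.25e-17)
  expect_equal(estimate_abundance(2.0e-17, 2.0, 1.0), 1.0e-17)
  bounds <- c(estimate_abundance(0.90e-17, 0.9, 1),
              estimate_abundance(3.0e-17, 3.3, 1))
  expect_equal(signif(mean(bounds), 1), 1e-17)
  # saturation * kcat * abundance == gross by construction
  ab <- estimate_abundance(2.4e-17, 3.1, 0.77)
  expect_equal(saturation(2.4e-17, 3.1, ab) * 3.1 * ab, 2.4e-17,
               tolerance = 1e-12)
})

test_that("packaged kinetic table and interpolation are consistent", {
  tab <- rubisco_params()
  expect_setequal(tab$temperature_C, c(10, 18, 25))
  expect_equal(tab$KCair_uM[tab$temperature_C == 25] /
                 tab$KCair_uM[tab$temperature_C == 10], 2.5)
  ki <- rubisco_interp(18)
  expect_equal(ki$kcatC_s, tab$kcatC_s[tab$temperature_C == 18],
               tolerance = 1e-3)
  expect_equal(ki$KCair_uM, tab$KCair_uM[tab$temperature_C == 18],
               tolerance = 1e-2)
  expect_warning(rubisco_interp(30), "extrapolat")
})
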