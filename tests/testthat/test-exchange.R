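test_that("cell-free chemistry loses 18O at the uncatalyzed dehydration rate", {
  carb <- carb_at(18)
  p <- exchange_params(0, 0, 0, 0, cell_density = 0, cell_volume = 2.87e-17)
  s <- simulate_exchange(p, exchange_init(2, 0.98), carb, seq(0, 600, 1))
  c13 <- total_13c(s)
  expect_lt(max(abs(c13 - c13[1])) / c13[1], 1e-6)
  o18 <- total_18o(s)
  expect_true(all(diff(o18) <= 1e-12))
  # d(18O)/dt == -kr * (HCO3 18O atoms) / 3: one of three oxygens is lost to
  # water per dehydration event
  i <- 300
  dt <- s$time[i + 1] - s$time[i - 1]
  lhs <- (o18[i + 1] - o18[i - 1]) / dt
  expect_equal(lhs, -carb$kr * s$lbe[i] / 3, tolerance = 1e-3)
  # mass 49 decays monotonically once dehydration dominates
  tail49 <- s$ce49[s$time > 200]
  expect_true(all(diff(tail49) < 0))
})

test_that("labeled carbon is conserved for arbitrary parameter draws", {
  carb <- carb_at(18)
  set.seed(99)
  for (i in 1:3) {
    p <- exchange_params(fc = 10^stats::runif(1, -16, -14),
                         fb = 10^stats::runif(1, -19, -17),
                         ca_intracellular = 10^stats::runif(1, 2, 4),
                         ca_extracellular = 0,
                         cell_density = 3.5e12, cell_volume = 2.87e-17)
    s <- simulate_exchange(p, exchange_init(2, 0.98), carb, seq(0, 900, 3))
    c13 <- total_13c(s)
    expect_lt(max(abs(c13 - c13[1])) / c13[1], 1e-6)
    expect_true(all(diff(total_18o(s)) <= 1e-12))
    expect_true(all(as.matrix(s[, -1]) > -1e-10))
  }
})

test_that("more intracellular CA means faster 18O loss once cells are present", {
  carb <- carb_at(18)
  mk <- function(ca) {
    p <- exchange_params(2.5e-15, 2.5e-18, ca, 0, 3.5e12, 2.87e-17)
    s <- simulate_exchange(p, exchange_init(2, 0.98), carb, seq(0, 900, 3))
    total_18o(s)[length(s$time)]
  }
  expect_lt(mk(4000), mk(2000))
})

test_that("parameter estimation recovers the generating parameters from clean data", {
  cond <- cond_at(18); carb <- carb_at(18)
  truth <- exchange_preset(18)
  g <- gen_exchange_trace(exchange_scenario(cond, truth))
  fit <- estimate_params(g$trace, carb,
                         fixed = list(cell_volume = truth$cell_volume,
                                      t_add = 300,
                                      init = exchange_init(2, 0.98)))
  est <- coef(fit)
  expect_equal(est[["fc"]], truth$fc, tolerance = 0.01)
  expect_equal(est[["fb"]], truth$fb, tolerance = 0.01)
  expect_equal(est[["ca_intracellular"]], truth$ca_intracellular,
               tolerance = 0.01)
  # bicarbonate permeability three orders below fc stays three orders below
  expect_lt(est[["fb"]] / est[["fc"]], 1e-2)
  expect_true(is.finite(fit$condition_number))
  expect_output(print(fit), "fc")
})

test_that("a cell-free trace leaves the cellular parameters unidentified and flagged", {
  cond <- cond_at(18); carb <- carb_at(18)
  p0 <- exchange_params(2.5e-15, 2.5e-18, 2000, 0, cell_density = 0,
                        cell_volume = 2.87e-17)
  g <- gen_exchange_trace(exchange_scenario(cond, p0, n_samples = 60))
  fit <- estimate_params(g$trace, carb,
                         fixed = list(cell_volume = 2.87e-17, t_add = 300,
                                      init = exchange_init(2, 0.98),
                                      cell_density = 0))
  # the uncatalyzed chemistry alone explains the trace
  expect_lt(fit$resid_norm, 1e-4)
  expect_true(any(grepl("weakly identified", fit$flags)))
})

test_that("solver rejects invalid inputs", {
  carb <- carb_at(18)
  p <- exchange_params(2.5e-15, 2.5e-18, 100, 0, 3.5e12, 2.87e-17)
  expect_error(simulate_exchange(p, exchange_init(2), carb, c(0, 0, 10)),
               "increasing")
  bad <- exchange_init(2); bad[["be"]] <- -1
  expect_error(simulate_exchange(p, bad, carb, c(0, 10)), "negative")
  expect_warning(exchange_params(1e-15, 1e-16, 10, 0, 1e12, 1e-17),
                 "permeability")
})
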