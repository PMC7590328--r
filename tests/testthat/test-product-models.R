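test_that("rate laws reproduce hand-computed values and limit cases", {
  lp <- ref_lp()
  expect_equal(luedeking_piret_rate(1, 0, product_params("luedeking_piret",
                                                         m = 0.5, n = 0.0099)),
               0.0099)
  expect_equal(luedeking_piret_rate(0, 0, lp), 0)
  expect_equal(luedeking_piret_rate(3.79, 0.37,
                                    product_params("luedeking_piret",
                                                   m = 0.1620, n = 0.0099)),
               0.1620 * 0.37 + 0.0099 * 3.79)

  mont <- ref_mont()
  expect_equal(monteagudo_rate(2, 0, P = mont$P_max, mont), 0)
  expect_equal(monteagudo_rate(2.5, 0.1, P = 0, mont),
               luedeking_piret_rate(2.5, 0.1,
                                    product_params("luedeking_piret",
                                                   m = mont$m, n = mont$n)))
  expect_equal(monteagudo_rate(3.79, 0, P = 116.544 / 2, mont),
               0.0042 * 3.79 * 0.5)

  bal <- ref_bal()
  expect_equal(balannec_rate(2, 0, HL = bal$HL_inh, bal), 0)
  expect_equal(balannec_rate(2, 0.1, HL = 0, bal),
               luedeking_piret_rate(2, 0.1,
                                    product_params("luedeking_piret",
                                                   m = bal$m, n = bal$n)))
  expect_equal(balannec_rate(2, 0.1, HL = 21.4864 / 2, bal),
               0.0348 * 0.1 + 0.0153 * 2 * 0.5)
})

test_that("rate laws reject out-of-domain states", {
  expect_error(luedeking_piret_rate(-1, 0, ref_lp()), "X")
  expect_error(monteagudo_rate(1, 0, P = 117, ref_mont()), "P")
  expect_error(monteagudo_rate(1, 0, P = -0.1, ref_mont()), "P")
  expect_error(balannec_rate(1, 0, HL = 22, ref_bal()), "HL")
  expect_error(product_params("luedeking_piret", m = -1, n = 0), "m")
  expect_error(product_params("monteagudo", m = 0, n = 0), "P_max")
  expect_error(product_params("luedeking_piret", m = 0, n = 0, P_max = 5),
               "P_max")
})

test_that("the undissociated fraction follows the Henderson-Hasselbalch partition", {
  expect_equal(undissociated_fraction(8, pH = 3.86, pKa = 3.86), 4)
  expect_equal(undissociated_fraction(8, pH = -3, pKa = 3.86), 8,
               tolerance = 1e-6)
  expect_equal(undissociated_fraction(12, pH = 3.71, pKa = 3.86),
               12 / (1 + 10^(3.71 - 3.86)))
  # monotone decreasing in pH, bounded by the total
  pHs <- seq(2, 8, 0.25)
  hl <- undissociated_fraction(5, pHs)
  expect_true(all(diff(hl) < 0))
  expect_true(all(hl > 0 & hl <= 5))
})

test_that("integration matches closed forms", {
  g <- ref_gompertz()
  bio <- biomass_trajectory(g)
  tg <- seq(0, 48, 2)

  # n = 0: pure growth association, P - P0 = m * (X(t) - X(0))
  pp <- product_params("luedeking_piret", m = 0.2, n = 0)
  out <- integrate_product(pp, bio, tg, P0 = 1)
  expect_equal(out$acidity, 1 + 0.2 * (growth_curve(tg, g) - growth_curve(0, g)),
               tolerance = 1e-9)

  # m = 0 with constant biomass: linear accumulation
  pp <- product_params("luedeking_piret", m = 0, n = 0.01)
  out <- integrate_product(pp, 2.5, tg, P0 = 0.5)
  expect_equal(out$acidity, 0.5 + 0.01 * 2.5 * tg, tolerance = 1e-9)

  # total-product inhibition with constant biomass: separable ODE solution
  pm <- product_params("monteagudo", m = 0, n = 0.0042, P_max = 116.544)
  tg2 <- seq(0, 400, 10)
  out <- integrate_product(pm, 3.79, tg2, P0 = 2)
  closed <- 116.544 - (116.544 - 2) * exp(-0.0042 * 3.79 * tg2 / 116.544)
  expect_equal(out$acidity, closed, tolerance = 1e-6)
})

test_that("inhibition models reduce to Luedeking-Piret as the constants grow", {
  g <- ref_gompertz()
  bio <- biomass_trajectory(g)
  tg <- seq(0, 384, 6)
  base <- integrate_product(product_params("luedeking_piret", m = 0.162,
                                           n = 0.0099), bio, tg, P0 = 0)
  big_p <- integrate_product(product_params("monteagudo", m = 0.162, n = 0.0099,
                                            P_max = 1e9), bio, tg, P0 = 0)
  expect_lt(max(abs(big_p$acidity - base$acidity)), 1e-4)

  env <- acid_environment(function(t) rep(4, length(t)))
  big_h <- integrate_product(product_params("balannec", m = 0.162, n = 0.0099,
                                            HL_inh = 1e9), bio, tg, P0 = 0,
                             env = env)
  expect_lt(max(abs(big_h$acidity - base$acidity)), 1e-4)
})

test_that("integration is step-size converged and matches an independent solver", {
  skip_if_not_installed("deSolve")
  g <- ref_gompertz()
  bio <- biomass_trajectory(g)
  tg <- seq(0, 384, 24)
  pp <- product_params("monteagudo", m = 0.1104, n = 0.0042, P_max = 116.544)

  a <- integrate_product(pp, bio, tg, P0 = 0.95, step = 0.1)
  b <- integrate_product(pp, bio, tg, P0 = 0.95, step = 0.05)
  expect_lt(abs(a$acidity[length(tg)] - b$acidity[length(tg)]), 1e-8)

  ode_rhs <- function(t, y, parms) {
    list(pp$m * bio$rate(t) + pp$n * bio$value(t) * (1 - y[1] / pp$P_max))
  }
  ref <- deSolve::ode(c(P = 0.95), tg, ode_rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(a$acidity, unname(ref[, "P"]), tolerance = 1e-7)
})

test_that("with constant biomass the inhibited product approaches P_max", {
  pm <- ref_mont()
  out <- integrate_product(pm, 3.79, t_grid = c(0, 200000), P0 = 0, step = 10)
  expect_equal(out$acidity[2], pm$P_max, tolerance = 1e-3)
})

test_that("integrate_product validates its inputs", {
  pp <- ref_lp()
  expect_error(integrate_product(pp, 1, c(0, 2, 1)), "increasing")
  expect_error(integrate_product(pp, 1, c(0, 1, 2), P0 = -1), "P0")
  expect_error(integrate_product(ref_bal(), 1, c(0, 1, 2)), "acid_environment")
})
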