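test_that("noiseless growth data return the generating parameters", {
  d_g <- growth_series(ref_gompertz(), seq(0, 48, 2))
  f_g <- fit_growth(d_g, "gompertz")
  expect_true(f_g$converged)
  expect_lt(max(rel_err(f_g$estimates, c(3.79, 0.37, 4.84))), 1e-4)

  d_l <- growth_series(ref_logistic(), seq(0, 72, 2))
  f_l <- fit_growth(d_l, "logistic")
  expect_true(f_l$converged)
  expect_lt(max(rel_err(f_l$estimates, c(3.77, 0.186, 10.30))), 1e-4)
})

test_that("a constant series yields a flagged degenerate fit, not an error", {
  d <- tibble::tibble(time = seq(0, 48, 8), cfu = rep(1e6, 7))
  f <- fit_growth(d, "gompertz")
  expect_s3_class(f, "growth_fit")
  expect_true(!f$converged || f$estimates[["A"]] < 1e-6)
  expect_true(length(f$warnings) > 0)
  expect_error(fit_growth(d[1:3, ], "gompertz"), "5")
})

test_that("the fit window stops before a sustained count decline", {
  # two consecutive >10% drops start after index 6
  cfu <- c(1, 50, 2500, 5000, 5100, 5050, 4000, 3000, 2500) * 1e4
  expect_equal(growth_fit_window(cfu), 1:6)
  # single transient dip does not end the window
  cfu2 <- c(1, 50, 2500, 5000, 4000, 5000, 5100, 5050, 5000) * 1e4
  expect_equal(growth_fit_window(cfu2), 1:9)
  # rule floored at the minimum number of points a fit needs
  cfu3 <- c(1, 5000, 4000, 3000, 2000, 1500) * 1e4
  expect_equal(growth_fit_window(cfu3), 1:5)
})

test_that("automatic growth initialization is sane on noiseless data", {
  d <- growth_series(ref_gompertz(), seq(0, 48, 1))
  init <- auto_init_growth(d, "gompertz")
  expect_lt(rel_err(init$A, 3.79), 0.05)
  # the steepest secant slope cannot exceed the true tangent slope by much
  expect_lt(init$mu_m, 0.37 * 1.2)
  # appending identical plateau points leaves the max-based init unchanged
  d2 <- dplyr::bind_rows(d, tibble::tibble(time = c(60, 72),
                                           cfu = rep(d$cfu[nrow(d)], 2)))
  init2 <- auto_init_growth(d2, "gompertz")
  expect_equal(init2$A, init$A)
  expect_equal(init2$mu_m, init$mu_m)
  expect_equal(init2$lambda, init$lambda)
  expect_error(auto_init_growth(tibble::tibble(time = 1:5, cfu = rep(1e5, 5))),
               "equal")
})

test_that("noiseless product data return the generating coefficients", {
  g <- ref_gompertz()
  d <- product_series(ref_lp(), biomass_trajectory(g), seq(0, 384, 6))
  f <- fit_product(d, g, "luedeking_piret")
  expect_true(f$converged)
  expect_lt(rel_err(f$estimates[["m"]], 0.1620), 1e-3)
  expect_lt(rel_err(f$estimates[["n"]], 0.0099), 1e-3)
  # the reported RSS is the plain residual sum of squares on the window
  expect_equal(f$gof$rss,
               rss(f$predicted$observed, f$predicted$predicted))
})

test_that("a zero-production series drives both coefficients to their bound", {
  g <- ref_gompertz()
  tg <- seq(0, 96, 6)
  d <- tibble::tibble(time = tg, acidity = rep(0.5, length(tg)))
  f <- fit_product(d, g, "luedeking_piret",
                   init = product_params("luedeking_piret", m = 0.01,
                                         n = 0.001))
  expect_lt(f$estimates[["m"]], 1e-4)
  expect_lt(f$estimates[["n"]], 1e-4)
  expect_lt(f$gof$rss, 1e-8)
})

test_that("monteagudo parameters are recoverable when inhibition is expressed", {
  g <- ref_gompertz()
  d <- product_series(ref_mont(), biomass_trajectory(g), seq(0, 720, 6))
  f <- fit_product(d, g, "monteagudo")
  expect_true(f$converged)
  expect_lt(rel_err(f$estimates[["m"]], 0.1104), 1e-2)
  expect_lt(rel_err(f$estimates[["n"]], 0.0042), 1e-2)
  expect_lt(rel_err(f$estimates[["P_max"]], 116.544), 1e-2)
  expect_length(f$warnings, 0)
})

test_that("automatic product initialization lands within an order of magnitude", {
  g <- ref_gompertz()
  d <- product_series(ref_lp(), biomass_trajectory(g), seq(0, 384, 6))
  init <- auto_init_product(d, g, "luedeking_piret")
  expect_gt(init$m, 0.1620 / 10); expect_lt(init$m, 0.1620 * 10)
  expect_gt(init$n, 0.0099 / 10); expect_lt(init$n, 0.0099 * 10)

  # growth-associated only: n0 collapses to its floor
  d_m <- product_series(product_params("luedeking_piret", m = 0.2, n = 0),
                        biomass_trajectory(g), seq(0, 384, 6))
  expect_lt(auto_init_product(d_m, g, "luedeking_piret")$n, 1e-4)
  # non-growth-associated only: m0 collapses to its floor
  d_n <- product_series(product_params("luedeking_piret", m = 0, n = 0.01),
                        biomass_trajectory(g), seq(0, 384, 6))
  expect_lt(auto_init_product(d_n, g, "luedeking_piret")$m, 0.01)
})

test_that("refitting from the solution is idempotent", {
  d <- growth_series(ref_gompertz(), seq(0, 48, 2))
  f1 <- fit_growth(d, "gompertz")
  f2 <- fit_growth(d, "gompertz",
                   init = growth_params("gompertz", f1$estimates[["A"]],
                                        f1$estimates[["mu_m"]],
                                        f1$estimates[["lambda"]]))
  expect_equal(f2$estimates, f1$estimates, tolerance = 1e-8)
})

test_that("fit_product insists on required channels and a converged growth fit", {
  g <- ref_gompertz()
  d <- product_series(ref_lp(), biomass_trajectory(g), seq(0, 96, 6))
  expect_error(fit_product(d, g, "balannec"), "pH")
  bad_growth <- fit_growth(tibble::tibble(time = seq(0, 48, 8),
                                          cfu = rep(1e6, 7)), "gompertz")
  if (!bad_growth$converged) {
    expect_error(fit_product(d, bad_growth, "luedeking_piret"), "converge")
  }
  expect_error(fit_product(dplyr::select(d, -acidity), g, "luedeking_piret"),
               "acidity")
})

test_that("tidy and glance expose estimates and fit statistics", {
  d <- growth_series(ref_gompertz(), seq(0, 48, 2))
  f <- fit_growth(d, "gompertz")
  td <- tidy(f)
  expect_equal(td$term, c("A", "mu_m", "lambda"))
  expect_equal(td$estimate, unname(f$estimates))
  gl <- glance(f)
  expect_equal(gl$model, "gompertz")
  expect_equal(gl$rss, f$gof$rss)
  expect_true(gl$converged)
  expect_s3_class(autoplot(f), "ggplot")
})
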