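test_that("each statistic reproduces its hand-computed value", {
  expect_equal(r2_uncentered(c(1, 2), c(1, 2)), 1)
  expect_equal(r2_uncentered(c(1, 2), c(2, 4)), 1)  # scale blindness
  expect_equal(r2_uncentered(c(1, 0), c(0, 1)), 0)

  expect_equal(r2_conventional(c(0, 1, 2), c(0, 1, 2)), 1)
  obs <- c(1, 3, 5)
  expect_equal(r2_conventional(obs, rep(mean(obs), 3)), 0)
  expect_equal(r2_conventional(c(0, 1, 2), c(0, 0, 0)), 1 - 5 / 2)

  expect_equal(chi2_reduced(c(2, 1, 3), c(1, 2, 2), n_params = 1), 1.5)
  expect_equal(chi2_reduced(c(1, 2, 3), c(1, 2, 3), n_params = 1), 0)

  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(25 / 2))
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)

  expect_equal(rss(c(1, 2), c(0, 0)), 5)
  expect_equal(rss(c(1, 2), c(1, 2)), 0)

  expect_equal(as.numeric(mape(10, 9)), 10)
  expect_equal(as.numeric(mape(c(1, 2), c(1, 2))), 0)
})

test_that("undefined statistics raise and zero observations are excluded from MAPE", {
  expect_error(r2_uncentered(c(0, 0), c(1, 2)), "zero-norm")
  expect_error(r2_conventional(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(chi2_reduced(c(1, 2), c(1, 2), n_params = 2),
               "degrees of freedom")
  expect_error(suppressMessages(mape(c(0, 0), c(1, 2))), "zero")
  m <- suppressMessages(mape(c(0, 10), c(5, 9)))
  expect_equal(as.numeric(m), 10)
  expect_equal(attr(m, "n_excluded"), 1L)
})

test_that("algebraic identities hold to machine precision on random vectors", {
  withr::local_seed(7)
  for (i in 1:20) {
    N <- sample(5:40, 1)
    obs <- rnorm(N, 5, 2)
    pred <- obs + rnorm(N, 0, 0.5)
    np <- sample(1:3, 1)
    expect_equal(chi2_reduced(obs, pred, np) * (N - np), rss(obs, pred),
                 tolerance = 1e-13)
    expect_equal(rss(obs, pred), N * rmse(obs, pred)^2, tolerance = 1e-13)
    # scaling residuals scales RMSE linearly
    expect_equal(rmse(obs, obs + 3 * (pred - obs)), 3 * rmse(obs, pred),
                 tolerance = 1e-12)
  }
})

test_that("uncentered R2 is scale-invariant in pred and all stats are permutation-equivariant", {
  withr::local_seed(11)
  obs <- rgamma(15, 3); pred <- obs * 1.2 + rnorm(15, 0, 0.1)
  expect_equal(r2_uncentered(obs, pred), r2_uncentered(obs, 37.5 * pred),
               tolerance = 1e-12)
  expect_equal(r2_uncentered(obs, 2.5 * obs), 1, tolerance = 1e-13)
  perm <- sample(15)
  expect_equal(r2_uncentered(obs[perm], pred[perm]), r2_uncentered(obs, pred))
  expect_equal(rss(obs[perm], pred[perm]), rss(obs, pred))
  expect_equal(rmse(obs[perm], pred[perm]), rmse(obs, pred))
  expect_equal(as.numeric(mape(obs[perm], pred[perm])),
               as.numeric(mape(obs, pred)))
  expect_equal(chi2_reduced(obs[perm], pred[perm], 2),
               chi2_reduced(obs, pred, 2))
})

test_that("gof_stats bundles the battery and degrades to NA where undefined", {
  obs <- c(1, 2, 3, 4); pred <- c(1.1, 1.9, 3.2, 3.8)
  g <- gof_stats(obs, pred, n_params = 2)
  expect_equal(g$rss, rss(obs, pred))
  expect_equal(g$chi2_reduced, chi2_reduced(obs, pred, 2))
  expect_equal(g$n_points, 4)
  g0 <- gof_stats(c(0, 0, 0), c(0.1, 0, 0), n_params = 1)
  expect_true(is.na(g0$r2_uncentered))
  expect_true(is.na(g0$r2_conventional))
  expect_equal(g0$rss, 0.01)
})

test_that("model ranking follows the ordered criteria with stable ties", {
  # primary key: uncentered R2 (values from competing growth fits)
  a <- fake_fit(0.9173, 0.3572, 0.4095, 25, 1.1759, model = "gompertz")
  b <- fake_fit(0.9143, 0.3874, 0.4168, 26, 1.2199, model = "logistic")
  rk <- rank_models(list(gompertz = a, logistic = b))
  expect_equal(rk$model, c("gompertz", "logistic"))
  rk2 <- rank_models(list(logistic = b, gompertz = a))
  expect_equal(rk2$model, c("gompertz", "logistic"))

  # R2 tie broken by the lower reduced chi-square
  c1 <- fake_fit(0.99, 0.3595, 0.5, 10, 1.44, model = "monteagudo")
  c2 <- fake_fit(0.99, 2.1346, 0.4, 9, 1.20, model = "balannec")
  expect_equal(rank_models(list(balannec = c2, monteagudo = c1))$model,
               c("monteagudo", "balannec"))

  # fully tied stats preserve input order
  d1 <- fake_fit(0.9, 1, 1, 1, 1, model = "first")
  d2 <- fake_fit(0.9, 1, 1, 1, 1, model = "second")
  expect_equal(rank_models(list(first = d1, second = d2))$model,
               c("first", "second"))

  # fits on different windows cannot be compared
  e <- fake_fit(0.9, 1, 1, 1, 1, window = 1:7)
  expect_error(rank_models(list(a = d1, b = e)), "window")
})
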