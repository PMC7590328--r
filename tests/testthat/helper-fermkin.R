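# Reference parameter sets (published gundruk fermentation fits) used as
# generating truth throughout the suite, and small series builders.

ref_gompertz <- function() growth_params("gompertz", A = 3.79, mu_m = 0.37,
                                         lambda = 4.84)
ref_logistic <- function() growth_params("logistic", A = 3.77, mu_m = 0.186,
                                         lambda = 10.30)
ref_lp <- function() product_params("luedeking_piret", m = 0.1620, n = 0.0099)
ref_mont <- function() product_params("monteagudo", m = 0.1104, n = 0.0042,
                                      P_max = 116.544)
ref_bal <- function() product_params("balannec", m = 0.0348, n = 0.0153,
                                     HL_inh = 21.4864)

# noiseless count series on a time grid from a growth parameter set
growth_series <- function(p, t, N0 = 6.03e4) {
  tibble::tibble(time = t, cfu = N0 * 10^growth_curve(t, p))
}

# noiseless acidity series integrated over a biomass source
product_series <- function(pp, bio, t, P0 = 0, env = NULL) {
  integrate_product(pp, bio, t, P0 = P0, env = env)
}

# minimal fit-like object for ranking tests
fake_fit <- function(r2, chi2, rmse_val, mape_val, rss_val, model = "fake",
                     window = 1:5) {
  fermkin:::new_ferm_fit(
    "growth_fit", model, "growth", params = NULL,
    estimates = c(A = 1), units = c(A = ""),
    gof = tibble::tibble(r2_uncentered = r2, r2_conventional = r2,
                         chi2_reduced = chi2, rmse = rmse_val, rss = rss_val,
                         mape = mape_val, n_points = length(window),
                         n_params = 3L),
    predicted = tibble::tibble(time = numeric(), observed = numeric(),
                               predicted = numeric()),
    window = as.integer(window), converged = TRUE, n_iter = 1L
  )
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
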