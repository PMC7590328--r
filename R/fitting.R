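# Bounded nonlinear least-squares estimation of growth and product
# parameters from sampled fermentation trajectories.

check_series <- function(data, need, min_n = 5L) {
  if (!is.data.frame(data)) stop("`data` must be a data frame.", call. = FALSE)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop(sprintf("`data` is missing required column(s): %s.",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(data$time) || any(!is.finite(data$time)) ||
      any(diff(data$time) <= 0)) {
    stop("`time` must be finite and strictly increasing.", call. = FALSE)
  }
  if (nrow(data) < min_n) {
    stop(sprintf("need at least %d points, got %d.", min_n, nrow(data)),
         call. = FALSE)
  }
  if ("cfu" %in% need &&
      (any(!is.finite(data$cfu)) || any(data$cfu <= 0))) {
    stop("`cfu` must be finite and > 0.", call. = FALSE)
  }
  if ("acidity" %in% need &&
      (any(!is.finite(data$acidity)) || any(data$acidity < 0))) {
    stop("`acidity` must be finite and >= 0.", call. = FALSE)
  }
  invisible(data)
}

#' Growth-fit window: up to the first sustained count decline
#'
#' The sigmoidal growth models cannot represent the death phase, so the
#' fit window runs from the first sample through the last index before
#' two consecutive viable-count decreases of more than 10 percent each.
#' When that rule would leave fewer than `min_points` samples (for
#' example with coarse daily sampling of a fast fermentation) the window
#' is extended to the first `min_points` samples, the minimum any fit
#' requires.
#'
#' @param cfu Vector of viable counts (cfu/g).
#' @param min_points Minimum window length (default 5).
#' @return An integer index vector `1:k`.
#' @export
growth_fit_window <- function(cfu, min_points = 5L) {
  n <- length(cfu)
  if (n < 3L) return(seq_len(n))
  dec <- cfu[-1] < 0.9 * cfu[-n]
  two <- which(dec[-length(dec)] & dec[-1])
  end <- if (length(two)) two[1] else n
  seq_len(min(max(end, min_points), n))
}

# raw (unvalidated) model curves for the optimizer hot loop
growth_curve_fun <- function(model) {
  if (model == "gompertz") {
    function(t, A, mu, lam) {
      A * exp(-exp(.clamp(mu * exp(1) / A * (lam - t) + 1)))
    }
  } else {
    function(t, A, mu, lam) {
      A / (1 + exp(.clamp(2 + 4 * mu / A * (lam - t))))
    }
  }
}

#' Automatic starting values for a growth fit
#'
#' Heuristics on the observed log10(N/N0) curve: `A0` is the maximum
#' observed log-ratio; `mu_m0` the steepest secant slope; `lambda0` the
#' time-axis intercept of that steepest secant, floored at zero.
#'
#' @param data Data frame with columns `time` and `cfu`.
#' @param model Growth model the initialization is for.
#' @param window Optional integer index window (default: all rows).
#' @return A [growth_params()] object.
#' @export
auto_init_growth <- function(data, model = c("gompertz", "logistic"),
                             window = NULL) {
  model <- match.arg(model)
  check_series(data, c("time", "cfu"), min_n = 5L)
  w <- window %||% seq_len(nrow(data))
  t <- data$time[w]
  y <- log10(data$cfu[w] / data$cfu[w[1]])
  if (diff(range(y)) == 0) {
    stop("cannot initialize: observations are all equal.", call. = FALSE)
  }
  A0 <- max(y)
  if (A0 <= 0) {
    stop("cannot initialize: counts never rise above the initial value.",
         call. = FALSE)
  }
  slopes <- diff(y) / diff(t)
  i <- which.max(slopes)
  mu0 <- max(slopes[i], 1e-6)
  t_mid <- (t[i] + t[i + 1]) / 2
  y_mid <- (y[i] + y[i + 1]) / 2
  lam0 <- max(0, t_mid - y_mid / mu0)
  growth_params(model, A = A0, mu_m = mu0, lambda = lam0)
}

new_ferm_fit <- function(subclass, model, type, params, estimates, units, gof,
                         predicted, window, converged, n_iter, message = "",
                         warnings = character(), extra = list()) {
  structure(
    c(list(model = model, type = type, params = params,
           estimates = estimates, units = units, gof = gof,
           predicted = predicted, window = window, converged = converged,
           n_iter = n_iter, message = message, warnings = warnings),
      extra),
    class = c(subclass, "ferm_fit")
  )
}

#' @export
print.ferm_fit <- function(x, ...) {
  cat(sprintf("<%s fit> model: %s (%s)\n", x$type, x$model,
              if (x$converged) "converged" else "NOT converged"))
  est <- sprintf("%s = %.6g %s", names(x$estimates), x$estimates, x$units)
  cat("  ", paste(est, collapse = ", "), "\n", sep = "")
  cat(sprintf("  R2 = %.4f, chi2 = %.4g, RMSE = %.4g, RSS = %.4g, MAPE = %.4g%%\n",
              x$gof$r2_uncentered, x$gof$chi2_reduced, x$gof$rmse,
              x$gof$rss, x$gof$mape))
  cat(sprintf("  n = %d points in fit window, %d iterations\n",
              x$gof$n_points, x$n_iter))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Fit a primary growth model to viable-count data
#'
#' Bounded Levenberg-Marquardt least squares (via
#' [minpack.lm::nls.lm()]) of the Modified Gompertz or Logistic curve to
#' the observed log10(N/N0), where N0 is the first count in the fit
#' window. Because the observable is the ratio to the first sample, the
#' model prediction is referenced to the first sampling time,
#' `X(t) - X(t[1])`: the Logistic curve is nonzero at time zero and
#' ignoring that offset would bias its parameters.
#' All parameters are bounded below at zero (numerically 1e-9);
#' the optimizer runs at most `max_iter` iterations with a cost
#' tolerance of 1e-10. Non-convergence is reported through the
#' `converged` flag, never as an error. A series whose counts never
#' change yields a degenerate flagged fit with `A` at its lower bound.
#'
#' @param data Data frame with columns `time` (strictly increasing) and
#'   `cfu` (> 0); at least 5 rows.
#' @param model `"gompertz"` or `"logistic"`.
#' @param window Integer index window, or `NULL` for the automatic rule
#'   of [growth_fit_window()].
#' @param init A [growth_params()] starting point, or `NULL` for
#'   [auto_init_growth()].
#' @param lower,upper Optional bounds, length-3 vectors ordered
#'   `(A, mu_m, lambda)`.
#' @param max_iter Maximum optimizer iterations.
#' @param time_unit Time unit carried into the fitted parameters.
#' @return A `growth_fit` object (also class `ferm_fit`) with elements
#'   `estimates`, `params`, `gof`, `predicted`, `window`, `converged`,
#'   `n_iter`.
#' @examples
#' truth <- growth_params("gompertz", A = 3.79, mu_m = 0.37, lambda = 4.84)
#' d <- tibble::tibble(time = seq(0, 48, 2),
#'                     cfu = 6.03e4 * 10^growth_curve(time, truth))
#' fit <- fit_growth(d, "gompertz")
#' tidy(fit)
#' @export
fit_growth <- function(data, model = c("gompertz", "logistic"), window = NULL,
                       init = NULL, lower = NULL, upper = NULL,
                       max_iter = 500L, time_unit = "hr") {
  model <- match.arg(model)
  check_series(data, c("time", "cfu"), min_n = 5L)
  w <- window %||% growth_fit_window(data$cfu)
  if (length(w) < 5L) stop("fit window must cover at least 5 points.",
                           call. = FALSE)
  if (any(w < 1L) || any(w > nrow(data))) {
    stop("`window` indices out of range.", call. = FALSE)
  }
  t <- data$time[w]
  N0 <- data$cfu[w[1]]
  y <- log10(data$cfu[w] / N0)

  warnings <- character()
  if (is.null(init)) {
    init <- tryCatch(auto_init_growth(data, model, window = w),
                     error = function(e) {
                       warnings <<- c(warnings, conditionMessage(e))
                       growth_params(model, A = 1e-8, mu_m = 1e-8, lambda = 0)
                     })
  }
  curve_fun <- growth_curve_fun(model)
  # the observable is the log ratio to the first sample, so the model
  # prediction is X(t) - X(t[1]); for the Gompertz X(t[1]) is ~0, for the
  # Logistic it is A/(1+e^2+...) > 0 and ignoring it would bias the fit
  model_y <- function(par) {
    cf <- curve_fun(t, par[1], par[2], par[3])
    cf - cf[1]
  }
  fn <- function(par) model_y(par) - y
  res <- minpack.lm::nls.lm(
    par = c(A = init$A, mu_m = init$mu_m, lambda = init$lambda),
    lower = lower %||% c(1e-9, 1e-9, 0),
    upper = upper %||% rep(Inf, 3),
    fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-10,
                                         ptol = 1e-10)
  )
  est <- res$par
  pred <- model_y(est)
  params <- growth_params(model, A = max(est[["A"]], 1e-12),
                          mu_m = max(est[["mu_m"]], 1e-12),
                          lambda = est[["lambda"]], time_unit = time_unit)
  new_ferm_fit(
    "growth_fit", model, "growth", params,
    estimates = est,
    units = c(A = "log10 ratio", mu_m = paste0("1/", time_unit),
              lambda = time_unit),
    gof = gof_stats(y, pred, n_params = 3L),
    predicted = tibble::tibble(time = t, observed = y, predicted = pred),
    window = as.integer(w),
    converged = res$info %in% 1:4,
    n_iter = res$niter,
    message = res$message,
    warnings = warnings,
    extra = list(N0 = N0, time_unit = time_unit, data = tibble::as_tibble(data))
  )
}

#' @rdname biomass_trajectory
#' @export
biomass_trajectory.growth_fit <- function(x, ...) {
  biomass_trajectory(x$params)
}

#' Automatic starting values for a product fit
#'
#' `m0` and `n0` come from jointly regressing the product increments on
#' the biomass increments and on biomass-weighted time increments (the
#' two terms of the uninhibited rate law); if that design is singular,
#' `n0` falls back to the late-phase product slope divided by the
#' plateau biomass. The inhibition constant starts at ten times the
#' largest observed product (or undissociated-acid) concentration. All
#' are floored at small positive values.
#'
#' @param data Data frame with `time`, `acidity` (g/L) and, for the
#'   `balannec` model, `pH`.
#' @param growth Biomass source: a `growth_fit`, [growth_params()],
#'   [biomass_trajectory()], or a constant.
#' @param model Product model to initialize for.
#' @param pKa Dissociation constant used for the undissociated fraction
#'   (`balannec` only).
#' @return A [product_params()] object.
#' @export
auto_init_product <- function(data,
                              growth,
                              model = c("luedeking_piret", "monteagudo",
                                        "balannec"),
                              pKa = 3.86) {
  model <- match.arg(model)
  need <- c("time", "acidity", if (model == "balannec") "pH")
  check_series(data, need, min_n = 5L)
  bio <- biomass_trajectory(growth)
  t <- data$time
  P <- data$acidity
  X <- bio$value(t)
  dP <- diff(P); dX <- diff(X); dt <- diff(t)
  Xmid <- (X[-1] + X[-length(X)]) / 2
  # increments of the uninhibited rate law: dP ~ m dX + n Xbar dt; a joint
  # regression separates the two terms, which a marginal regression of dP
  # on dX cannot (the n-term leaks into m0 at coarse sampling)
  m0 <- NA_real_; n0 <- NA_real_
  des <- cbind(dX, Xmid * dt)
  if (qr(des)$rank == 2L) {
    cf <- qr.coef(qr(des), dP)
    m0 <- cf[1]; n0 <- cf[2]
  }
  if (!is.finite(m0)) m0 <- 0
  if (!is.finite(n0)) {
    late <- X >= 0.95 * max(X)
    n0 <- if (sum(late) >= 3) {
      stats::coef(stats::lm(P[late] ~ t[late]))[2] / max(X)
    } else {
      (dP[length(dP)] / dt[length(dP)]) / max(X)
    }
  }
  m0 <- max(m0, 1e-6, na.rm = TRUE)
  n0 <- max(n0, 1e-6, na.rm = TRUE)
  switch(model,
    luedeking_piret = product_params(model, m = m0, n = n0),
    monteagudo = product_params(model, m = m0, n = n0,
                                P_max = 10 * max(P, 1e-3)),
    balannec = {
      HL <- undissociated_fraction(P, data$pH, pKa)
      product_params(model, m = m0, n = n0, HL_inh = 10 * max(HL, 1e-3))
    }
  )
}

#' Fit a product-formation model to acidity data
#'
#' Minimizes the residual sum of squares between measured lactic acid
#' concentrations (g/L) and the rate law integrated over the biomass
#' trajectory, by bounded Levenberg-Marquardt least squares. The initial
#' concentration `P0` is fixed at the first measurement. Inhibition
#' constants are estimated on the log10 scale (they span orders of
#' magnitude and are bounded below by the largest observed concentration
#' of the inhibiting species); if doubling or halving the fitted
#' constant changes the RSS by less than a relative 1e-6 the result
#' carries a poor-identifiability warning. For the `balannec` model the
#' measured pH samples are interpolated piecewise-linearly.
#'
#' @inheritParams auto_init_product
#' @param init A [product_params()] starting point, or `NULL` for
#'   [auto_init_product()].
#' @param max_iter Maximum optimizer iterations.
#' @param step Internal integration step override (see
#'   [integrate_product()]).
#' @param time_unit Time unit label for reporting.
#' @return A `product_fit` object (also class `ferm_fit`).
#' @export
fit_product <- function(data, growth,
                        model = c("luedeking_piret", "monteagudo", "balannec"),
                        init = NULL, pKa = 3.86, max_iter = 500L, step = NULL,
                        time_unit = "hr") {
  model <- match.arg(model)
  need <- c("time", "acidity", if (model == "balannec") "pH")
  check_series(data, need, min_n = 5L)
  if (inherits(growth, "ferm_fit") && !growth$converged) {
    stop("`growth` fit did not converge; refusing to build the biomass ",
         "trajectory from it.", call. = FALSE)
  }
  bio <- biomass_trajectory(growth)
  t <- data$time
  P_obs <- data$acidity
  P0 <- P_obs[1]
  env <- if (model == "balannec") {
    acid_environment(data.frame(time = t, pH = data$pH), pKa = pKa)
  }
  if (is.null(init)) init <- auto_init_product(data, bio, model, pKa = pKa)
  check_product_model(init, model)

  K_floor <- switch(model,
    luedeking_piret = NULL,
    monteagudo = max(P_obs),
    balannec = max(undissociated_fraction(P_obs, data$pH, pKa))
  )
  has_K <- model != "luedeking_piret"
  par0 <- c(m = init$m, n = init$n)
  if (has_K) {
    K0 <- max(if (model == "monteagudo") init$P_max else init$HL_inh,
              K_floor * (1 + 1e-9))
    par0 <- c(par0, lK = log10(K0))
  }
  make_params <- function(par) {
    switch(model,
      luedeking_piret = product_params(model, m = par[["m"]], n = par[["n"]]),
      monteagudo = product_params(model, m = par[["m"]], n = par[["n"]],
                                  P_max = 10^par[["lK"]]),
      balannec = product_params(model, m = par[["m"]], n = par[["n"]],
                                HL_inh = 10^par[["lK"]])
    )
  }
  predict_P <- function(par) {
    integrate_core(make_params(par), bio, t, P0, env = env, step = step)
  }
  fn <- function(par) predict_P(par) - P_obs
  res <- minpack.lm::nls.lm(
    par = par0,
    lower = c(0, 0, if (has_K) log10(K_floor))[seq_along(par0)],
    upper = rep(Inf, length(par0)),
    fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-10,
                                         ptol = 1e-10)
  )
  par_hat <- res$par
  pred <- predict_P(par_hat)
  params <- make_params(par_hat)
  warnings <- character()
  if (has_K) {
    # identifiability probe: RSS response to a 2x change in the constant
    rss_hat <- sum((pred - P_obs)^2)
    probe <- function(lK) {
      p2 <- par_hat; p2[["lK"]] <- max(lK, log10(K_floor))
      sum((predict_P(p2) - P_obs)^2)
    }
    d_up <- abs(probe(par_hat[["lK"]] + log10(2)) - rss_hat)
    d_dn <- abs(probe(par_hat[["lK"]] - log10(2)) - rss_hat)
    if (max(d_up, d_dn) / max(rss_hat, .Machine$double.eps) < 1e-6) {
      warnings <- c(warnings, paste0(
        "inhibition constant is poorly identified: a 2x change leaves the ",
        "RSS essentially unchanged."))
    }
  }
  est <- c(m = par_hat[["m"]], n = par_hat[["n"]])
  units <- c(m = "g/L per X", n = paste0("g/L per X per ", time_unit))
  if (model == "monteagudo") {
    est <- c(est, P_max = 10^par_hat[["lK"]])
    units <- c(units, P_max = "g/L")
  } else if (model == "balannec") {
    est <- c(est, HL_inh = 10^par_hat[["lK"]])
    units <- c(units, HL_inh = "g/L")
  }
  new_ferm_fit(
    "product_fit", model, "product", params,
    estimates = est,
    units = units,
    gof = gof_stats(P_obs, pred, n_params = length(par0)),
    predicted = tibble::tibble(time = t, observed = P_obs, predicted = pred),
    window = seq_along(t),
    converged = res$info %in% 1:4,
    n_iter = res$niter,
    message = res$message,
    warnings = warnings,
    extra = list(P0 = P0, pKa = if (model == "balannec") pKa else NULL,
                 time_unit = time_unit, data = tibble::as_tibble(data))
  )
}
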