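# Primary growth models on the log10(N/N0) response scale.

#' Parameters of a primary growth model
#'
#' Container for the three parameters shared by the Modified Gompertz and
#' Logistic sigmoids as used in predictive microbiology: the asymptotic
#' log10 increase in population `A`, the maximum specific growth rate
#' `mu_m` (the literal maximum slope of log10(N/N0) versus time), and the
#' lag period `lambda` (time-axis intercept of the tangent at the point of
#' maximum slope).
#'
#' @param model Either `"gompertz"` (Modified Gompertz, Zwietering
#'   parameterization) or `"logistic"`.
#' @param A Asymptotic log10 population increase (dimensionless, > 0).
#' @param mu_m Maximum specific growth rate, in `1/time_unit` (> 0).
#' @param lambda Lag period, in `time_unit` (>= 0).
#' @param time_unit Unit of the time axis the parameters refer to; carried
#'   as metadata and never converted. Defaults to `"hr"`.
#'
#' @return An object of class `growth_params`.
#' @examples
#' p <- growth_params("gompertz", A = 3.79, mu_m = 0.37, lambda = 4.84)
#' growth_curve(c(0, 12, 48), p)
#' @export
growth_params <- function(model = c("gompertz", "logistic"), A, mu_m, lambda,
                          time_unit = "hr") {
  model <- match.arg(model)
  check_scalar(A, "A", lower = 0, strict = TRUE)
  check_scalar(mu_m, "mu_m", lower = 0, strict = TRUE)
  check_scalar(lambda, "lambda", lower = 0, strict = FALSE)
  structure(
    list(model = model, A = A, mu_m = mu_m, lambda = lambda,
         time_unit = time_unit),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "<growth_params> %s: A = %.4g, mu_m = %.4g 1/%s, lambda = %.4g %s\n",
    x$model, x$A, x$mu_m, x$time_unit, x$lambda, x$time_unit))
  invisible(x)
}

check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number.", name), call. = FALSE)
  }
  bad <- if (strict) x <= lower else x < lower
  if (bad) {
    stop(sprintf("`%s` must be %s %s.", name, if (strict) ">" else ">=", lower),
         call. = FALSE)
  }
  invisible(x)
}

check_time <- function(t) {
  if (!is.numeric(t) || length(t) == 0L || any(!is.finite(t))) {
    stop("`t` must be finite numeric (no NA/Inf).", call. = FALSE)
  }
  invisible(t)
}

# overflow guard on double-exponential arguments
.clamp <- function(x, lim = 700) pmin(pmax(x, -lim), lim)

#' Modified Gompertz growth curve (Zwietering form)
#'
#' Evaluates `y(t) = A * exp(-exp((mu_m * e / A) * (lambda - t) + 1))`,
#' the log10 ratio of viable count to the initial count. In this
#' parameterization `mu_m` is exactly the maximum slope and `lambda` the
#' lag time; `y(lambda) = A * exp(-e)`.
#'
#' @param t Time, same unit as the parameters; any finite value (negative
#'   allowed).
#' @param p A [growth_params()] object with `model = "gompertz"`.
#' @return log10(N/N0), in (0, A).
#' @export
gompertz_log_ratio <- function(t, p) {
  check_growth_model(p, "gompertz")
  check_time(t)
  k <- p$mu_m * exp(1) / p$A
  g <- .clamp(k * (p$lambda - t) + 1)
  p$A * exp(-exp(g))
}

#' Time derivative of the Modified Gompertz curve
#'
#' Analytic `d/dt log10(N/N0)`. Positive everywhere; its global maximum
#' over `t` equals `mu_m`.
#'
#' @inheritParams gompertz_log_ratio
#' @return Growth rate in 1/time units.
#' @export
gompertz_rate <- function(t, p) {
  check_growth_model(p, "gompertz")
  check_time(t)
  k <- p$mu_m * exp(1) / p$A
  g <- .clamp(k * (p$lambda - t) + 1)
  # y' = A * k * exp(g - exp(g)); exp(g) may overflow to Inf -> rate 0
  p$A * k * exp(.clamp(g - exp(g), 745))
}

#' Logistic growth curve on the log10 ratio scale
#'
#' Evaluates `y(t) = A / (1 + exp(2 + (4 mu_m / A) * (lambda - t)))`.
#' `mu_m` is the maximum slope (at the inflection point) and
#' `y(lambda) = A / (1 + e^2)`.
#'
#' @inheritParams gompertz_log_ratio
#' @param p A [growth_params()] object with `model = "logistic"`.
#' @export
logistic_log_ratio <- function(t, p) {
  check_growth_model(p, "logistic")
  check_time(t)
  z <- .clamp(2 + (4 * p$mu_m / p$A) * (p$lambda - t))
  p$A / (1 + exp(z))
}

#' Time derivative of the Logistic curve
#'
#' @inheritParams logistic_log_ratio
#' @return Growth rate in 1/time units; maximum equals `mu_m`.
#' @export
logistic_rate <- function(t, p) {
  check_growth_model(p, "logistic")
  check_time(t)
  z <- 2 + (4 * p$mu_m / p$A) * (p$lambda - t)
  # y' = 4 mu_m e^z / (1+e^z)^2 = mu_m / cosh(z/2)^2, stable for large |z|
  r <- p$mu_m / cosh(.clamp(z / 2, 360))^2
  r[!is.finite(r)] <- 0
  r
}

check_growth_model <- function(p, model) {
  if (!inherits(p, "growth_params")) {
    stop("`p` must be a growth_params object.", call. = FALSE)
  }
  if (p$model != model) {
    stop(sprintf("`p$model` is '%s', expected '%s'.", p$model, model),
         call. = FALSE)
  }
  invisible(p)
}

#' Evaluate a growth model or its rate by parameter object
#'
#' Dispatch helpers that pick the Modified Gompertz or Logistic form from
#' `p$model`, so downstream code (fitting, simulation, product
#' integration) is model-agnostic.
#'
#' @inheritParams gompertz_log_ratio
#' @return `growth_curve()` returns log10(N/N0); `growth_rate()` its
#'   analytic time derivative.
#' @export
growth_curve <- function(t, p) {
  if (!inherits(p, "growth_params")) {
    stop("`p` must be a growth_params object.", call. = FALSE)
  }
  switch(p$model,
    gompertz = gompertz_log_ratio(t, p),
    logistic = logistic_log_ratio(t, p)
  )
}

#' @rdname growth_curve
#' @export
growth_rate <- function(t, p) {
  if (!inherits(p, "growth_params")) {
    stop("`p` must be a growth_params object.", call. = FALSE)
  }
  switch(p$model,
    gompertz = gompertz_rate(t, p),
    logistic = logistic_rate(t, p)
  )
}
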