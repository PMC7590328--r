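# Product-formation rate laws coupled to a biomass trajectory, the
# undissociated-acid partition, and deterministic RK4 integration.

#' Parameters of a product-formation rate law
#'
#' The three rate laws share the Luedeking-Piret structure
#' `dP/dt = m dX/dt + n X`, with `X` the relative cell population
#' log10(N/N0):
#'
#' * `luedeking_piret`: no inhibition term.
#' * `monteagudo`: the non-growth-associated term is scaled by
#'   `(1 - P / P_max)` so production ceases as total lactic acid
#'   approaches the inhibitory concentration `P_max`.
#' * `balannec`: the non-growth-associated term is scaled by
#'   `(1 - HL / HL_inh)` where `HL` is the undissociated lactic acid
#'   concentration, the actual inhibitor at uncontrolled pH.
#'
#' @param model One of `"luedeking_piret"`, `"monteagudo"`, `"balannec"`.
#' @param m Growth-associated coefficient, g/L per unit X (>= 0).
#' @param n Non-growth-associated coefficient, g/L per unit X per time
#'   unit (>= 0).
#' @param P_max Inhibitory total lactic acid concentration, g/L
#'   (`monteagudo` only, > 0).
#' @param HL_inh Inhibitory undissociated lactic acid concentration, g/L
#'   (`balannec` only, > 0).
#'
#' @return An object of class `product_params`.
#' @examples
#' product_params("monteagudo", m = 0.1104, n = 0.0042, P_max = 116.544)
#' @export
product_params <- function(model = c("luedeking_piret", "monteagudo", "balannec"),
                           m, n, P_max = NULL, HL_inh = NULL) {
  model <- match.arg(model)
  check_scalar(m, "m", lower = 0)
  check_scalar(n, "n", lower = 0)
  if (model == "monteagudo") {
    if (is.null(P_max)) stop("`P_max` is required for the monteagudo model.",
                             call. = FALSE)
    check_scalar(P_max, "P_max", lower = 0, strict = TRUE)
  } else if (!is.null(P_max)) {
    stop(sprintf("`P_max` must not be set for the %s model.", model),
         call. = FALSE)
  }
  if (model == "balannec") {
    if (is.null(HL_inh)) stop("`HL_inh` is required for the balannec model.",
                              call. = FALSE)
    check_scalar(HL_inh, "HL_inh", lower = 0, strict = TRUE)
  } else if (!is.null(HL_inh)) {
    stop(sprintf("`HL_inh` must not be set for the %s model.", model),
         call. = FALSE)
  }
  structure(list(model = model, m = m, n = n, P_max = P_max, HL_inh = HL_inh),
            class = "product_params")
}

#' @export
print.product_params <- function(x, ...) {
  extra <- switch(x$model,
    monteagudo = sprintf(", P_max = %.4g g/L", x$P_max),
    balannec = sprintf(", HL_inh = %.4g g/L", x$HL_inh),
    "")
  cat(sprintf("<product_params> %s: m = %.4g, n = %.4g%s\n",
              x$model, x$m, x$n, extra))
  invisible(x)
}

check_product_model <- function(p, model) {
  if (!inherits(p, "product_params")) {
    stop("`p` must be a product_params object.", call. = FALSE)
  }
  if (p$model != model) {
    stop(sprintf("`p$model` is '%s', expected '%s'.", p$model, model),
         call. = FALSE)
  }
  invisible(p)
}

check_nonneg_vec <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be finite and >= 0.", name), call. = FALSE)
  }
  invisible(x)
}

#' Luedeking-Piret production rate
#'
#' `dP/dt = m * dX/dt + n * X`, the classic mixed growth-/non-growth-
#' associated form.
#'
#' @param X Relative cell population log10(N/N0), >= 0. Vectorized.
#' @param dXdt Its time derivative.
#' @param p A [product_params()] object of the matching model.
#' @return Production rate in g/L per time unit.
#' @export
luedeking_piret_rate <- function(X, dXdt, p) {
  check_product_model(p, "luedeking_piret")
  check_nonneg_vec(X, "X")
  p$m * dXdt + p$n * X
}

#' Production rate with total-product inhibition
#'
#' `dP/dt = m * dX/dt + n * X * (1 - P / P_max)`; reduces to the
#' Luedeking-Piret rate at `P = 0` and its non-growth-associated term
#' vanishes at `P = P_max`.
#'
#' @inheritParams luedeking_piret_rate
#' @param P Current total lactic acid concentration, g/L, in
#'   `[0, P_max]`.
#' @export
monteagudo_rate <- function(X, dXdt, P, p) {
  check_product_model(p, "monteagudo")
  check_nonneg_vec(X, "X")
  if (any(!is.finite(P)) || any(P < 0) || any(P > p$P_max)) {
    stop("`P` must lie in [0, P_max].", call. = FALSE)
  }
  p$m * dXdt + p$n * X * (1 - P / p$P_max)
}

#' Production rate with undissociated-acid inhibition
#'
#' `dP/dt = m * dX/dt + n * X * (1 - HL / HL_inh)` where `HL` is the
#' undissociated lactic acid concentration (see
#' [undissociated_fraction()]); reduces to the Luedeking-Piret rate as
#' `HL_inh` grows large.
#'
#' @inheritParams luedeking_piret_rate
#' @param HL Undissociated lactic acid concentration, g/L, in
#'   `[0, HL_inh]`.
#' @export
balannec_rate <- function(X, dXdt, HL, p) {
  check_product_model(p, "balannec")
  check_nonneg_vec(X, "X")
  if (any(!is.finite(HL)) || any(HL < 0) || any(HL > p$HL_inh)) {
    stop("`HL` must lie in [0, HL_inh].", call. = FALSE)
  }
  p$m * dXdt + p$n * X * (1 - HL / p$HL_inh)
}

#' Undissociated fraction of a monoprotic acid
#'
#' Henderson-Hasselbalch partition of total acid into its protonated
#' form: `HL = P_total / (1 + 10^(pH - pKa))`. At `pH = pKa` half the
#' acid is undissociated; well below the pKa essentially all of it is.
#'
#' @param P_total Total acid concentration, g/L (>= 0). Vectorized.
#' @param pH Medium pH.
#' @param pKa Acid dissociation constant; defaults to 3.86 (lactic acid,
#'   25 C).
#' @return Undissociated concentration in g/L, in `[0, P_total]`.
#' @export
undissociated_fraction <- function(P_total, pH, pKa = 3.86) {
  check_nonneg_vec(P_total, "P_total")
  P_total / (1 + 10^(pH - pKa))
}

#' Biomass trajectory for product-formation models
#'
#' Wraps a source of relative cell population X(t) = log10(N/N0) as a
#' pair of callables (value and rate) used by [integrate_product()] and
#' [fit_product()]. Methods exist for:
#'
#' * `growth_params`: analytic curve and derivative.
#' * `growth_fit` (from [fit_growth()]): the fitted curve.
#' * `data.frame` with columns `time` and `X`: piecewise-linear
#'   interpolation, with the piecewise-constant slope as the rate.
#' * a single number: constant biomass with zero rate (stationary
#'   phase).
#'
#' @param x Source object.
#' @param ... Unused.
#' @return An object of class `biomass_trajectory` with elements
#'   `value(t)` and `rate(t)`.
#' @export
biomass_trajectory <- function(x, ...) UseMethod("biomass_trajectory")

new_biomass_trajectory <- function(value, rate, source) {
  structure(list(value = value, rate = rate, source = source),
            class = "biomass_trajectory")
}

#' @rdname biomass_trajectory
#' @export
biomass_trajectory.growth_params <- function(x, ...) {
  force(x)
  new_biomass_trajectory(
    value = function(t) growth_curve(t, x),
    rate = function(t) growth_rate(t, x),
    source = paste0("model:", x$model)
  )
}

#' @rdname biomass_trajectory
#' @export
biomass_trajectory.biomass_trajectory <- function(x, ...) x

#' @rdname biomass_trajectory
#' @export
biomass_trajectory.numeric <- function(x, ...) {
  check_scalar(x, "X", lower = 0)
  new_biomass_trajectory(
    value = function(t) rep(x, length(t)),
    rate = function(t) rep(0, length(t)),
    source = "constant"
  )
}

#' @rdname biomass_trajectory
#' @export
biomass_trajectory.data.frame <- function(x, ...) {
  if (!all(c("time", "X") %in% names(x))) {
    stop("data frame biomass needs columns `time` and `X`.", call. = FALSE)
  }
  if (any(diff(x$time) <= 0)) {
    stop("`time` must be strictly increasing.", call. = FALSE)
  }
  check_nonneg_vec(x$X, "X")
  val <- stats::approxfun(x$time, x$X, rule = 2)
  slopes <- diff(x$X) / diff(x$time)
  # derivative of the linear interpolant: constant on each interval,
  # 0 outside the data range (rule-2 extrapolation is flat)
  n <- length(x$time)
  rate <- stats::approxfun(x$time, c(slopes, 0), method = "constant",
                           yleft = 0, yright = 0, f = 0)
  new_biomass_trajectory(value = val, rate = rate, source = "tabulated")
}

#' Acid environment: a pH trajectory and a pKa
#'
#' Describes the pH history needed by the undissociated-acid inhibition
#' model. `pH` may be a function of time or a data frame with columns
#' `time` and `pH` (piecewise-linearly interpolated, flat beyond the
#' data range).
#'
#' @param pH Function of time, or data frame with `time`, `pH` columns.
#' @param pKa Acid dissociation constant (default 3.86, lactic acid).
#' @return An object of class `acid_environment` with elements `pH(t)`
#'   and `pKa`.
#' @export
acid_environment <- function(pH, pKa = 3.86) {
  check_scalar(pKa, "pKa", lower = 0, strict = TRUE)
  if (is.function(pH)) {
    fn <- pH
  } else if (is.data.frame(pH)) {
    if (!all(c("time", "pH") %in% names(pH))) {
      stop("data frame `pH` needs columns `time` and `pH`.", call. = FALSE)
    }
    if (any(!is.finite(pH$pH)) || any(pH$pH <= 0) || any(pH$pH >= 14)) {
      stop("`pH` values must lie in (0, 14).", call. = FALSE)
    }
    fn <- stats::approxfun(pH$time, pH$pH, rule = 2)
  } else {
    stop("`pH` must be a function of time or a data frame.", call. = FALSE)
  }
  structure(list(pH = fn, pKa = pKa), class = "acid_environment")
}

# Fixed-step classic RK4 for the scalar product ODE. Substeps subdivide
# each grid interval evenly so grid points are hit exactly; biomass and
# pH values at all stage times are precomputed (vectorized) before the
# scalar loop. `ph_of_p`, used by the synthetic generator, makes pH a
# function of the current product concentration instead of time.
integrate_core <- function(p, bio, t_grid, P0, env = NULL, step = NULL,
                           ph_of_p = NULL) {
  m <- p$m; n <- p$n; model <- p$model
  h_target <- step %||% min(0.1, min(diff(t_grid)) / 10)
  n_sub <- pmax(1L, as.integer(ceiling(diff(t_grid) / h_target - 1e-9)))
  # node times for every substep, grid index of each node
  starts <- rep(t_grid[-length(t_grid)], n_sub)
  hs <- rep(diff(t_grid) / n_sub, n_sub)
  offs <- unlist(lapply(n_sub, function(k) seq_len(k) - 1L), use.names = FALSE)
  t0 <- starts + offs * hs
  t1 <- t0 + hs
  tm <- t0 + hs / 2

  X0 <- bio$value(t0); X1 <- bio$value(t1); Xm <- bio$value(tm)
  dX0 <- bio$rate(t0); dX1 <- bio$rate(t1); dXm <- bio$rate(tm)

  use_ph_t <- FALSE
  if (model == "balannec" && is.null(ph_of_p)) {
    # denominator of the Henderson-Hasselbalch partition at stage times
    D0 <- 1 + 10^(env$pH(t0) - env$pKa)
    D1 <- 1 + 10^(env$pH(t1) - env$pKa)
    Dm <- 1 + 10^(env$pH(tm) - env$pKa)
    use_ph_t <- TRUE
  }

  inhib <- function(P, D) {
    if (model == "luedeking_piret") return(1)
    if (model == "monteagudo") return(max(0, 1 - P / p$P_max))
    # balannec: D is the partition denominator at this stage
    max(0, 1 - (P / D) / p$HL_inh)
  }
  stage_D <- function(P, Dt) {
    if (model != "balannec") return(NA_real_)
    if (!is.null(ph_of_p)) 1 + 10^(ph_of_p(P) - (env$pKa %||% 3.86)) else Dt
  }

  cuts <- cumsum(n_sub)          # substep index after which a grid node is hit
  out <- numeric(length(t_grid))
  out[1] <- P0
  P <- P0
  gi <- 2L
  for (i in seq_along(t0)) {
    h <- hs[i]
    k1 <- m * dX0[i] + n * X0[i] * inhib(P, stage_D(P, if (use_ph_t) D0[i] else NA))
    P2 <- P + h / 2 * k1
    k2 <- m * dXm[i] + n * Xm[i] * inhib(P2, stage_D(P2, if (use_ph_t) Dm[i] else NA))
    P3 <- P + h / 2 * k2
    k3 <- m * dXm[i] + n * Xm[i] * inhib(P3, stage_D(P3, if (use_ph_t) Dm[i] else NA))
    P4 <- P + h * k3
    k4 <- m * dX1[i] + n * X1[i] * inhib(P4, stage_D(P4, if (use_ph_t) D1[i] else NA))
    P <- P + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i == cuts[gi - 1L]) {
      out[gi] <- P
      gi <- gi + 1L
    }
  }
  out
}

#' Integrate a product-formation rate law over time
#'
#' Turns a rate law into predicted lactic acid concentrations at the
#' requested sampling times by classic fixed-step fourth-order
#' Runge-Kutta integration. The internal step is
#' `min(0.1 time-unit, grid spacing / 10)` unless overridden; each grid
#' interval is subdivided evenly so sampling times are hit exactly. If
#' rounding carries `P` marginally past `P_max` (or `HL` past `HL_inh`)
#' the bracketed inhibition term is floored at zero rather than raising
#' an error, keeping the ODE well-posed at the boundary.
#'
#' @param p A [product_params()] object.
#' @param bio A [biomass_trajectory()] (or anything coercible by it).
#' @param t_grid Strictly increasing sampling times.
#' @param P0 Initial product concentration, g/L (>= 0).
#' @param env An [acid_environment()]; required for the `balannec`
#'   model, ignored otherwise.
#' @param step Optional internal step override (time units).
#' @return A tibble with columns `time` and `acidity` (g/L).
#' @examples
#' bio <- biomass_trajectory(growth_params("gompertz", 3.79, 0.37, 4.84))
#' pp <- product_params("luedeking_piret", m = 0.162, n = 0.0099)
#' integrate_product(pp, bio, t_grid = seq(0, 48, 6), P0 = 0.95)
#' @export
integrate_product <- function(p, bio, t_grid, P0 = 0, env = NULL, step = NULL) {
  if (!inherits(p, "product_params")) {
    stop("`p` must be a product_params object.", call. = FALSE)
  }
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0)) {
    stop("`t_grid` must be strictly increasing with >= 2 points.",
         call. = FALSE)
  }
  check_scalar(P0, "P0", lower = 0)
  if (p$model == "balannec") {
    if (!inherits(env, "acid_environment")) {
      stop("the balannec model requires `env`, an acid_environment.",
           call. = FALSE)
    }
  } else {
    env <- NULL
  }
  bio <- biomass_trajectory(bio)
  P <- integrate_core(p, bio, t_grid, P0, env = env, step = step)
  tibble::tibble(time = t_grid, acidity = P)
}
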