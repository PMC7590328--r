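# Seeded generator of gundruk-like fermentation trajectories: sigmoidal
# growth with an optional death phase, product formation by one of the
# rate laws, pH coupled to acid accumulation, channel-specific noise.

#' Configuration of a synthetic fermentation experiment
#'
#' Bundles everything [simulate_fermentation()] needs: the generating
#' growth and product parameter sets, the initial count and acidity, an
#' optional post-peak log-linear count decline (the death phase the
#' growth models deliberately do not represent), a two-parameter
#' exponential-saturation coupling of pH to acid with an optional late
#' upward ramp, the sampling grid, and channel noise levels.
#'
#' @param growth A [growth_params()] generating truth.
#' @param N0 Initial viable count, cfu/g.
#' @param decline_rate Post-peak death rate on the log10 scale,
#'   1/time (0 disables the death phase).
#' @param decline_start Time at which the decline begins (required when
#'   `decline_rate > 0`).
#' @param plateau Log10-ratio floor the declining count levels off at
#'   (default 0: never below the initial count).
#' @param product A [product_params()] generating truth.
#' @param P0 Initial lactic acid concentration, g/L.
#' @param pH0,pH_min Initial and asymptotic pH of the coupling
#'   `pH = pH_min + (pH0 - pH_min) * exp(-k_pH * (P - P0))`.
#' @param k_pH Coupling strength of pH to accumulated acid, L/g.
#' @param late_rise Small late pH increase (pH units) ramped linearly
#'   from `late_rise_start` to the end of sampling; 0 disables it.
#' @param late_rise_start Start time of the late ramp.
#' @param pKa Dissociation constant used when the generating product
#'   model is `balannec`.
#' @param t_start,t_end,interval Sampling grid (time units).
#' @param count_cv Lognormal coefficient of variation of the
#'   multiplicative plate-count noise.
#' @param acid_sd,pH_sd Gaussian additive noise, g/L and pH units.
#' @param seed Default RNG seed for [simulate_fermentation()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(growth = growth_params("gompertz", A = 3.79,
                                              mu_m = 0.37, lambda = 4.84),
                       N0 = 6.03e4,
                       decline_rate = 0, decline_start = NULL, plateau = 0,
                       product = product_params("luedeking_piret",
                                                m = 0.1620, n = 0.0099),
                       P0 = 0.95,
                       pH0 = 6.59, pH_min = 3.71, k_pH = 0.6,
                       late_rise = 0, late_rise_start = NULL,
                       pKa = 3.86,
                       t_start = 0, t_end = 96, interval = 2,
                       count_cv = 0, acid_sd = 0, pH_sd = 0,
                       seed = 1L) {
  if (!inherits(growth, "growth_params")) {
    stop("`growth` must be a growth_params object.", call. = FALSE)
  }
  if (!inherits(product, "product_params")) {
    stop("`product` must be a product_params object.", call. = FALSE)
  }
  check_scalar(N0, "N0", lower = 0, strict = TRUE)
  check_scalar(decline_rate, "decline_rate", lower = 0)
  if (decline_rate > 0) {
    check_scalar(decline_start, "decline_start", lower = 0)
  }
  check_scalar(plateau, "plateau", lower = 0)
  check_scalar(P0, "P0", lower = 0)
  check_scalar(pH0, "pH0", lower = 0, strict = TRUE)
  check_scalar(pH_min, "pH_min", lower = 0, strict = TRUE)
  if (pH_min > pH0) stop("`pH_min` must not exceed `pH0`.", call. = FALSE)
  check_scalar(k_pH, "k_pH", lower = 0)
  check_scalar(late_rise, "late_rise", lower = 0)
  if (late_rise > 0) check_scalar(late_rise_start, "late_rise_start", lower = 0)
  check_scalar(pKa, "pKa", lower = 0, strict = TRUE)
  check_scalar(interval, "interval", lower = 0, strict = TRUE)
  if (t_end <= t_start) stop("`t_end` must exceed `t_start`.", call. = FALSE)
  check_scalar(count_cv, "count_cv", lower = 0)
  check_scalar(acid_sd, "acid_sd", lower = 0)
  check_scalar(pH_sd, "pH_sd", lower = 0)
  check_scalar(seed, "seed", lower = -Inf)
  structure(
    list(growth = growth, N0 = N0, decline_rate = decline_rate,
         decline_start = decline_start, plateau = plateau, product = product,
         P0 = P0, pH0 = pH0, pH_min = pH_min, k_pH = k_pH,
         late_rise = late_rise, late_rise_start = late_rise_start, pKa = pKa,
         t_start = t_start, t_end = t_end, interval = interval,
         count_cv = count_cv, acid_sd = acid_sd, pH_sd = pH_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a sampled fermentation trajectory
#'
#' Produces one experiment's series at the configured sampling times:
#'
#' * counts: `N0 * 10^X(t)` from the growth model, with an optional
#'   post-peak log-linear decline floored at `plateau`, times mean-one
#'   lognormal noise;
#' * acidity: the configured product rate law integrated over the
#'   (monotone) growth curve with the shared RK4 integrator, plus
#'   Gaussian noise, floored at 0;
#' * pH: exponential-saturation coupling to the noiseless acid curve,
#'   plus the optional late ramp (clipped to `[pH_min, pH0]`), plus
#'   Gaussian noise.
#'
#' A noiseless run (all noise terms 0, `decline_rate = 0`) reproduces
#' [growth_curve()] and [integrate_product()] outputs exactly at the
#' sample times, which is the pipeline's central oracle. Output is
#' deterministic given the seed; the caller's RNG state is untouched.
#'
#' @param config A [sim_config()].
#' @param seed Seed override (defaults to `config$seed`).
#' @return A tibble with columns `time`, `cfu`, `acidity`, `pH` and the
#'   effective config in attribute `"config"`.
#' @export
simulate_fermentation <- function(config, seed = NULL) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be a sim_config object.", call. = FALSE)
  }
  seed <- as.integer(seed %||% config$seed)
  t <- seq(config$t_start, config$t_end, by = config$interval)
  X <- growth_curve(t, config$growth)

  X_cfu <- X
  if (config$decline_rate > 0) {
    ds <- config$decline_start
    after <- t > ds
    X_cfu[after] <- pmax(X[after] - config$decline_rate * (t[after] - ds),
                         config$plateau)
  }
  cfu_true <- config$N0 * 10^X_cfu

  bio <- biomass_trajectory(config$growth)
  ph_of_p <- if (config$product$model == "balannec") {
    function(P) {
      min(max(config$pH_min +
                (config$pH0 - config$pH_min) * exp(-config$k_pH * (P - config$P0)),
              config$pH_min), config$pH0)
    }
  }
  P <- integrate_core(config$product, bio, t, config$P0,
                      env = list(pKa = config$pKa), ph_of_p = ph_of_p)

  pH_true <- pmin(pmax(config$pH_min +
                         (config$pH0 - config$pH_min) *
                           exp(-config$k_pH * (P - config$P0)),
                       config$pH_min), config$pH0)
  if (config$late_rise > 0) {
    span <- max(config$t_end - config$late_rise_start, 1e-12)
    ramp <- config$late_rise * pmax(0, t - config$late_rise_start) / span
    pH_true <- pmin(pH_true + ramp, config$pH0)
  }

  n <- length(t)
  withr::with_seed(seed, {
    sdlog <- sqrt(log1p(config$count_cv^2))
    cfu <- cfu_true * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    acidity <- pmax(P + stats::rnorm(n, 0, config$acid_sd), 0)
    pH <- pmin(pmax(pH_true + stats::rnorm(n, 0, config$pH_sd), 0.01), 13.99)
  })

  out <- tibble::tibble(time = t, cfu = cfu, acidity = acidity, pH = pH)
  attr(out, "config") <- config
  attr(out, "seed") <- seed
  out
}

#' Gundruk-like default scenario
#'
#' A configuration whose noiseless trajectory reproduces the hallmark
#' numbers of a spontaneous gundruk fermentation sampled daily for 16
#' days: counts rising from 6.03e4 cfu/g to about 9.6e8 cfu/g within
#' the first days, then declining to a plateau of about 6.3e7 cfu/g;
#' titratable acidity rising from 0.95 g/L (0.095 percent w/v) to a
#' plateau near 12 g/L (1.2 percent) by around day 12; pH falling from
#' 6.59 toward 3.71 with a slight late rise. The acid plateau comes from
#' total-product inhibition with `P_max = 12` g/L. With `noise = TRUE`
#' (default) realistic channel noise is added: 10 percent plate-count
#' CV, 0.15 g/L titration error, 0.05 pH units.
#'
#' @param noise Logical; `FALSE` returns the same scenario with all
#'   noise terms zero.
#' @return A [sim_config()].
#' @examples
#' head(simulate_fermentation(gundruk_scenario(noise = FALSE)))
#' @export
gundruk_scenario <- function(noise = TRUE) {
  sim_config(
    growth = growth_params("gompertz", A = log10(9.55e8 / 6.03e4),
                           mu_m = 0.15, lambda = 24),
    N0 = 6.03e4,
    decline_rate = 0.0122, decline_start = 96,
    plateau = log10(6.31e7 / 6.03e4),
    product = product_params("monteagudo", m = 0.1104, n = 0.0595,
                             P_max = 12.0),
    P0 = 0.95,
    pH0 = 6.59, pH_min = 3.71, k_pH = 0.6,
    late_rise = 0.1, late_rise_start = 216,
    t_start = 0, t_end = 384, interval = 24,
    count_cv = if (noise) 0.10 else 0,
    acid_sd = if (noise) 0.15 else 0,
    pH_sd = if (noise) 0.05 else 0,
    seed = 1L
  )
}

#' Simulate a batch of replicate fermentations
#'
#' Replicate `i` (1-based) uses seed `base_seed + i - 1`, so a batch of
#' one reproduces [simulate_fermentation()] at `base_seed` exactly and
#' the mapping from `(config, i)` to a series is deterministic.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates (>= 0).
#' @param base_seed Seed of the first replicate.
#' @return A list of `n_reps` series tibbles.
#' @export
replicate_batch <- function(config, n_reps, base_seed = config$seed) {
  check_scalar(n_reps, "n_reps", lower = 0)
  lapply(seq_len(n_reps), function(i) {
    simulate_fermentation(config, seed = base_seed + i - 1)
  })
}
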