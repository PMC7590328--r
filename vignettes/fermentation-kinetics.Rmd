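---
title: "Methods: growth and lactic acid production kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth and lactic acid production kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermkin)
```

# The problem

Spontaneous vegetable fermentations such as *gundruk* are driven by
lactic acid bacteria (LAB) whose viable counts rise sigmoidally, peak,
and then decline as the medium acidifies, while titratable acidity rises
to a plateau and pH falls. fermkin fits primary growth models and
product-formation rate laws to such trajectories, quantifies the fits
with a common statistics battery, and selects among competing models.

# Growth models

Both models act on the dimensionless response `X(t) = log10(N(t)/N0)`,
never on raw counts — plate counts span five orders of magnitude and
least squares on the raw scale would be dominated by the plateau.

The Modified Gompertz is used in the Zwietering parameterization

$$X(t) = A\,\exp\!\Big(-\exp\big(\tfrac{\mu_m e}{A}(\lambda - t) + 1\big)\Big),$$

and the Logistic as

$$X(t) = \frac{A}{1 + \exp\big(2 + \tfrac{4\mu_m}{A}(\lambda - t)\big)}.$$

In both, `A` (log10 ratio) is the asymptote, `µm` (1/time) is exactly
the maximum slope, and `λ` (time) is the time-axis intercept of the
tangent at the steepest point. We adopt the Zwietering form for the
Gompertz deliberately: it is the standard parameterization in predictive
microbiology, it makes `µm` the literal maximum slope (a property the
test suite asserts numerically), and it is consistent with the `2 +` and
`4µm/A` constants of the logistic companion form. Analytic derivatives
of both curves are provided because the product models consume `dX/dt`.

Two numerical guards matter. The double-exponential argument is clamped
to ±700 before exponentiation so extreme times underflow gracefully to 0
or `A` instead of producing `NaN`; and the logistic rate is evaluated as
`µm / cosh(z/2)²`, which is stable where the naive
`e^z/(1+e^z)²` form overflows.

**Units are metadata.** Parameters carry a `time_unit` label (default
hours) and the package never converts units. Published parameter sets
for fast fermentations sometimes mix hour-scale rate constants with
day-scale sampling; fermkin stays agnostic — the numbers are
interpreted in whatever unit the time axis of the data actually has.

# Product-formation models

All three rate laws share the Luedeking–Piret structure: production is
partly proportional to the growth rate (`m`, growth-associated, g/L per
unit `X`) and partly to the standing biomass (`n`, non-growth-associated,
g/L per unit `X` per time). Here `X` is the *relative cell population*
`log10(N/N0)` from the fitted growth model — not dry mass — so `m` and
`n` are interpretable only relative to that scale, which is exactly how
the corresponding literature values are reported.

End-product inhibition enters through the `n`-term only:

* total-product inhibition: `n X (1 − P/P_max)` — production stalls as
  lactic acid approaches `P_max`;
* undissociated-acid inhibition: `n X (1 − [HL]/(HL)_inh)` where
  `[HL] = P/(1 + 10^{pH − pKa})` is the protonated fraction. The pKa
  defaults to 3.86 (lactic acid at 25 °C) and is configurable; the
  partition is the single monoprotic Henderson–Hasselbalch equilibrium,
  no further dissociation chemistry.

## Integration

Predicted concentrations come from classic fixed-step fourth-order
Runge–Kutta. The right-hand sides are smooth and non-stiff, so a
fixed-step explicit scheme is accurate, fast, and — important for
testing — bit-reproducible. The internal step is
`min(0.1 time-unit, grid spacing/10)`, with each sampling interval
subdivided evenly so sample times are hit exactly; halving the step
changes the endpoint by under 1e-8 g/L on the default scenario, and the
test suite cross-checks the trajectories against an adaptive multistep
solver (deSolve's `lsoda`) at tolerance 1e-7. If rounding carries `P`
marginally past `P_max` (or `[HL]` past `(HL)_inh`) the bracketed term
is floored at 0 instead of erroring, keeping the ODE well-posed at its
boundary. During fitting of the undissociated-acid model the measured pH
samples are interpolated piecewise-linearly (flat extrapolation): the
simplest defensible choice, adding no parameters.

# Estimation

Growth and product parameters are estimated separately (no joint fit,
no weighting, no interval estimates — deliberately out of scope) by
bounded Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nls.lm`, max 500 iterations, cost tolerance 1e-10), all
parameters bounded below at zero. Non-convergence is a flagged result,
not an exception.

**Response referencing.** The observable is the log ratio to the first
sample, `log10(cfu_i/cfu_1)`, so the model prediction is referenced the
same way: `X(t_i) − X(t_1)`. The Gompertz is essentially zero at typical
first sampling times, but the logistic starts at `A/(1+e^{2+4µm λ/A}) > 0`;
ignoring that offset visibly biases logistic estimates (the difference
between exact recovery and percent-level errors in the recovery tests).

**Fit window.** Neither sigmoid can represent the death phase, so the
growth fit runs from the first sample through the last index before two
consecutive viable-count decreases of more than 10 % each
(`growth_fit_window()`). When the rule would leave fewer than the five
points any fit requires — e.g. daily sampling of a fermentation whose
growth completes within days — the window is extended to the first five
samples. The synthetic generator's death phase exists precisely to
exercise this rule.

**Starting values.** Growth: `A0` = max observed log ratio, `µm0` =
steepest secant slope, `λ0` = that secant's time-axis intercept floored
at 0. Product: `m0` and `n0` from a joint regression of product
increments on `(ΔX, X̄Δt)` — a marginal regression of ΔP on ΔX lets the
`n`-term leak into `m0` at coarse sampling — and the inhibition constant
starts at 10× the largest observed concentration of the inhibiting
species.

**Inhibition constants** are fitted as log10 values, bounded below by
the largest observed `P` (or `[HL]`): they span orders of magnitude and
are only weakly identified when the data end far from saturation. After
fitting, the package probes the RSS at half and twice the fitted
constant; if the relative change is below 1e-6 the fit carries an
explicit poor-identifiability warning rather than a silently meaningless
estimate.

# Goodness of fit and model selection

Six statistics are computed per fit: uncentered R²
(`(Σ obs·pred)²/(Σ obs² Σ pred²)`), conventional R² (`1 − RSS/TSS`),
reduced χ² (`RSS/(N−n)`), RMSE, RSS, and MAPE (standard percentage
form; zero-observation points are excluded with a logged count — the
only widely accepted convention, as the percentage is undefined there).
Selection uses the ordered rule: highest uncentered R², ties within
1e-6 broken by χ², then RMSE, then MAPE, then RSS; fully tied fits keep
input order, and fits on different windows are incomparable by
construction. The uncentered R² is scale-blind — it equals 1 for any
prediction *proportional* to the observations — so the conventional R²
is always reported beside it as the guard; the selection key remains the
uncentered form for comparability with the fermentation-kinetics
literature that uses it.

# The synthetic generator

`sim_config()`/`simulate_fermentation()` emulate the statistical
structure the analysis assumes:

* counts `N0·10^{X(t)}` with optional post-peak log-linear decline to a
  plateau floor (generator-only: the fitted models exclude it via the
  window rule), and mean-one lognormal noise — multiplicative, matching
  plate-count error structure;
* acidity from the configured rate law integrated with the same RK4
  code path the fitter uses, so a noiseless run reproduces
  `integrate_product()` bit-for-bit (the pipeline's central oracle:
  noiseless simulate → fit returns the generating parameters);
* pH coupled to accumulated acid by exponential saturation
  `pH = pH_min + (pH0 − pH_min)·exp(−k(P − P0))` plus an optional small
  late linear rise, clipped to `[pH_min, pH0]`, with additive Gaussian
  noise. Two parameters is the simplest shape matching the observed
  "falls, bottoms out, rises slightly" pattern; it is phenomenological,
  not a buffering model.

`gundruk_scenario()` packages defaults that reproduce the hallmark
numbers of a spontaneous gundruk fermentation sampled every 24 h for 16
days: counts from 6.03×10⁴ cfu/g to a ~9.6×10⁸ peak within the first
days, declining to a ~6.3×10⁷ plateau; acidity from 0.95 g/L (0.095 %
w/v; percent is converted to g/L by ×10 at ingest) to a ~12 g/L plateau
near day 12, produced by total-product inhibition with `P_max = 12 g/L`;
pH 6.59 → 3.71 with a late +0.1 rise. The growth parameters behind that
trajectory (`A = 4.20`, `µm = 0.15 hr⁻¹`, `λ = 24 hr`, decline
0.0122 log10/hr from 96 h) were chosen once to match those endpoint
values and timings; noise defaults (count CV 10 %, acidity SD 0.15 g/L,
pH SD 0.05) are typical bench magnitudes for plating, titration and pH
electrodes. Replicate `i` of a batch is seeded `base_seed + i − 1`, so
the mapping from configuration and index to series is deterministic and
a batch of one reproduces a single run exactly.

What the generator does **not** emulate — and therefore what passing
tests cannot certify about real data: species succession (the
heterofermentative-to-homofermentative shift of natural fermentations),
substrate depletion, temperature effects, autocorrelated measurement
drift, or irregular sampling. Recovery results on synthetic data bound
what the estimator can do when the model family is correct; they say
nothing about model misspecification on real trajectories.

# Problem sizes and determinism

The recovery experiments use the grids on which the published parameter
sets are identifiable: 2-h sampling over 48 h (Gompertz) and 72 h
(Logistic) for growth; 6-h sampling over 384 h (Luedeking–Piret) and
720 h (both inhibition models, so inhibition is actually expressed in
the data) for products; 50 replicates for the noise-robustness check of
`µm` at 0.05 log10 noise. All randomness flows through explicit seeds;
the fits themselves are deterministic.

# Known limitations

* Separate (not joint) growth/product estimation propagates growth-fit
  error into product coefficients.
* No uncertainty quantification (CIs, bootstrap, profiles).
* The death phase is excluded, not modelled (no Baranyi/Richards or
  secondary models).
* `P_max`/`(HL)_inh` are structurally hard to identify from data that
  stop far below saturation; the conditioning warning flags, but cannot
  fix, that.
* The logistic lag `λ` trades off against its nonzero initial value on
  short series; recovery is exact on the tested grids but short windows
  will inflate its variance.
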