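---
title: "Estimating body-weight variability from smart-scale data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating body-weight variability from smart-scale data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwvtools)
library(dplyr)
```

Body-weight variability (BWV) -- the magnitude of day-to-day fluctuation of
body weight around its overall trend -- has emerged as a marker of interest
in obesity and cardiometabolic research. Wi-Fi-connected smart scales make
near-daily weight series available, but those series arrive dirty (implausible
spikes from shared scales or mis-entries) and gappy (self-weighing lapses).
`bwvtools` implements a complete processing pipeline for such data and, more
importantly, a *simulation-validation harness* that quantifies what cleaning,
missingness and imputation do to BWV estimates.

This vignette explains the models and the design decisions. Everything
quantitative stated here is computed by the package's test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## Data model

A weight series is a tibble on a consecutive daily grid: `participant_id`,
`date`, `day` (1-based day number), `weight` (kg, `NA` where no measurement
exists). Irregular weigh-in records are regularized with `to_daily_grid()`;
same-day repeats are averaged (an order-independent choice; repeat weigh-ins
minutes apart carry no extra information at daily resolution).

## Cleaning

`clean_series()` removes physiologically implausible values rather than
adjusting them. Two rule families apply:

* absolute bounds, default 25--250 kg;
* a rate bound on the change between successive observations, default
  `2 kg + 0.35 kg x gap-days`. The 2 kg intercept covers short-term
  hydration/gut-content/clothing fluctuation; the 0.35 kg/day slope is wide
  enough to cover sustained loss at very-low-calorie-diet rates and gain at
  intentional-overfeeding rates.

A value is removed only when it violates the rate bound against **both** its
previous and next retained observations (one neighbour at the edges): a lone
spike, not the surrounding trend, is the implausible datum. Removal iterates
-- worst offender first, then recheck -- until a fixed point, which makes
cleaning idempotent. All limits are user-configurable; the defaults are this
package's own calibration, chosen once, and tests treat them as
configuration, not truth.

## Simulating missingness

Two amputation mechanisms with known ground truth:

* `ampute_mcar()` removes exactly `round(fraction x n_obs)` observed values
  uniformly at random (round-half-to-even). The fraction applies to observed
  measurements, not grid days, so "80% missing" means 80% of the available
  weights are gone.
* `ampute_rpm()` transfers a donor mask's observed/missing pattern onto the
  target, recycling the donor when lengths differ (recycling preserves the
  run-length structure, which is the point of pattern-based amputation).
  `generate_rpm_donor()` builds bursty donors from a 2-state Markov process
  with a target stationary missing fraction and mean lapse length (default
  7 days), emulating the bursts of real self-weighing lapses.

## Imputation

Ten methods, one contract (`impute_series()`): observed values are never
modified, the output has no missing values, and `imputed` flags exactly the
input gaps. Leading/trailing gaps -- which two-sided interpolants cannot
bracket -- are filled with the nearest observed value and remain flagged so
downstream analyses can drop edges.

* **linear / spline / stine** -- straight-line, natural cubic spline, and
  Stineman's rational interpolation. Stineman slopes come from the parabola
  through each consecutive point triple with a rational correction that
  cannot overshoot: monotone data give a monotone interpolant, unlike the
  spline.
* **ewma** -- distance-weighted mean of up to `k = 4` observed values per
  side with weights `2^(-days)`; both the window and the decay base are
  configurable because the exponential base is a convention, not a law.
* **smks** -- a structural time-series model (local linear trend plus a
  weekly seasonal component when the grid spans at least 8 weeks) fitted by
  maximum likelihood; missing entries take the Kalman *smoother*'s
  expectation, i.e. they condition on the entire sample. Optimizer failure
  falls back level-by-level to simpler structures.
* **assrks** -- ARIMA orders p, q in 0..2, d in 0..1 searched by AICc on the
  observed-data likelihood, represented in state space and Kalman-smoothed.
* **tsclean** -- a period-7 strength-of-seasonality test (threshold 0.64,
  the usual variance-ratio convention, configurable) routes to either robust
  seasonal-trend decomposition followed by interpolation of the seasonally
  adjusted series, or Friedman's super smoother followed by interpolation.
* **knn / rf / pmm** -- multivariate methods restricted to the two predictors
  available without participant burden: day number and ISO day of week.
  kNN averages the `k = 10` nearest observed days in standardized covariate
  space with `exp(-d)` weights; rf is a seeded iterative (missForest-style)
  random-forest loop; pmm draws regression parameters, matches each missing
  day's prediction to its 5 nearest observed predictions and copies one
  donor's observed weight, so imputed values are always real observed values.
  PMM produces a single completed trajectory: with one incomplete variable,
  chained equations are degenerate and downstream consumes one series.

## BWV estimation

Both statistics are built on *relative residuals*, `(w - trend) / w`, making
them invariant to overall body size (doubling every weight changes nothing).

* **Linear (RMSE) method**: `bwv_rmse()` returns
  `100 x sqrt(mean(r^2))` around the OLS line of weight on day. It is the
  classical epidemiological measure, but a curvilinear trajectory inflates
  it because trend curvature leaks into the residuals.
* **Nonlinear mean deviation (NLMD)**: `bwv_nlmd()` returns
  `100 x mean(|r|)` around a LOESS trend (locally quadratic, tricube
  weights). The absolute value is essential: the plain mean of residuals
  from any least-squares-type fit is ~0, and it is the mean absolute
  deviation that measures variability. On pure Gaussian relative noise of
  SD sigma, NLMD converges to `100 x sigma x sqrt(2/pi)` (the folded-normal
  mean) -- a property the test suite verifies to within 5% at n = 365.

### The adaptive span

A LOESS span is a *fraction of available points*, so a fixed span fits ever
tighter as data accumulate, and BWV estimated at 80% missingness would not be
comparable with the full-data estimate. The span is therefore a nonincreasing
linear function of the observation count, clamped to [0.2, 0.9]:

```{r}
default_span_rule()
```

These coefficients are produced by `calibrate_span()` on the package's
default synthetic cohort (`scripts/calibrate_span.R` regenerates them): for
each missingness level it searches the span minimizing the drift of the
cohort-mean NLMD relative to the full-data mean (computed at span 0.33 --
roughly a third of a year of daily data, wide enough to leave weekly
fluctuation in the residual), then fits span against observation count with
the slope constrained nonpositive. They are calibrated defaults of this
package, not external constants.

## The synthetic cohort

Real smart-scale cohorts are access-restricted, so `generate_cohort()` makes
the study population used by every stochastic test: by default 50
participants, 365 days, baseline weight ~ Normal(81.9, 15.4) kg, each day
observed independently with probability 336/365 (so ~336 measurements per
participant). Each trajectory is

```
weight(t) = (trend(t) + seasonal(t)) * (1 + eps(t)),   eps ~ N(0, 0.005)
```

* `trend`: one of three shapes per participant -- linear ramp, quadratic
  bowl, or loss-plateau-regain spline -- with annual excursion up to +/-5%
  of baseline (drawn per participant);
* `seasonal`: a weekend-peaking weekly cycle of amplitude 0.3% of body
  weight, ramping down over the working week (weekend gain with weekday
  compensation);
* multiplicative noise of 0.5% -- the order of true day-to-day human weight
  fluctuation -- because daily fluctuation scales with body size and the BWV
  statistics are relative.

The generator records its ground truth (`trend`, `seasonal`, `weight_true`
columns) and the analytic expectations of both BWV statistics
(`truth_stats_of()`), enabling parameter-recovery tests.

What the generator does **not** emulate: autocorrelated noise (real
hydration and glycogen effects persist across days), holiday/seasonal
calendar effects, informative missingness (lapses that correlate with weight
gain), and measurement heaping. Consequences of the first point are visible
in the validation experiment below and matter when reading its results.

## The validation experiment

`run_experiment()` wires the whole design together: for each participant x
mechanism x level x replicate it amputes, scores every configured imputation
method against the known values at the amputed positions (`rmse_pct` on the
percent scale, `mae_kg`, `mape_pct` -- evaluated *only* at amputed positions,
so levels are comparable), and computes both BWV statistics on the amputed
and on each imputed series against the full-data reference. The default
design is 50 participants x 20 replicates; `scaled = TRUE` shrinks to 10
participants x 5 replicates (the problem size used by the package's own
stochastic tests, chosen to keep Monte-Carlo error well below the effects
being asserted).

Reproducible findings on the synthetic cohort (all recomputed by the test
suite and acceptance script):

* BWV computed on *missing* data barely moves: the mean disagreement with
  full-data estimates stays within a few percent even at 80% missingness,
  for both estimators.
* BWV computed on *imputed* data is strongly biased -- tens of percent of
  underestimation for the smoothing imputers, growing with missingness and
  larger for NLMD than for the linear method. Smoothers fill gaps with the
  conditional mean, which erases precisely the variability that BWV
  measures. If the goal is BWV, leave data missing.
* The spline *over*estimates BWV: its cubic segments overshoot between noisy
  anchors.

Two findings are known to differ from what heavier-tailed, autocorrelated
real data show, and both trace to the generator's independent daily noise:
ARIMA state-space smoothing (assrks) performs about as well as structural
smoothing here (on real data long-gap mean reversion hurts it), and the
Stineman and PMM imputers *inflate* variability slightly (positive BWV bias)
rather than damping it. The package asserts the real-data orderings in its
acceptance suite and documents these divergences rather than adjusting the
generator to hide them.

## Numerical choices and degenerate inputs

* "Exact recovery" tolerances: 1e-9 kg for closed-form interpolants, 1e-3 kg
  for likelihood-fitted smoothers (optimizer-limited).
* Constant (zero-variance) series short-circuit the Kalman imputers -- the
  likelihood surface is degenerate there -- and return the constant.
* `stats::loess` defines the neighbourhood as `floor(span * n)` points; the
  package documents and tests against that convention.
* Amputation counts use round-half-to-even; seeded operations restore the
  caller's RNG state.
* Cleaning, amputation and imputation all refuse to leave fewer than 2
  observations; trend fitting requires 3 (linear) or 10 (LOESS) points;
  spans yielding a neighbourhood under 4 points are rejected.
* Span calibration with a flat objective (e.g. constant cohorts) returns the
  default rule with a warning instead of a spurious fit.

## Limitations

The validation quantifies *estimation* error under missingness for this
data-generating process; it cannot certify imputation rankings on real
cohorts whose noise is autocorrelated and whose missingness is informative.
The cleaning limits are plausibility stand-ins and should be reviewed per
study. NLMD depends on the span rule; a cohort very unlike the synthetic one
(e.g. far shorter follow-up) warrants re-running `calibrate_span()` on its
own near-complete series.
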