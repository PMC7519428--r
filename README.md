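# bwvtools

Body-weight variability from high-frequency smart-scale data.

Wi-Fi-connected scales yield near-daily body-weight series over months or
years. Researchers who want to quantify **body-weight variability (BWV)** —
the fluctuation around the overall weight trend, a candidate risk marker for
obesity, diabetes and cardiovascular outcomes — face three practical
problems: implausible values (shared scales, mis-entries), missing days
(self-weighing lapses), and the question of whether to impute before
estimating variability. `bwvtools` is for biostatisticians and
epidemiologists working with such data. It provides:

* **cleaning** by physiological-plausibility limits (absolute bounds plus a
  per-gap rate-of-change bound, both configurable);
* **amputation** — simulation of missingness with known ground truth, either
  completely at random (MCAR) or by imposing bursty real-pattern
  (donor-mask) missingness;
* **ten imputation methods** under one contract (linear / natural-spline /
  Stineman interpolation, exponentially weighted moving average, structural
  model + Kalman smoothing, ARIMA state space + Kalman smoothing, seasonal
  decomposition / super-smoother interpolation, k-nearest neighbours,
  iterative random forest, predictive mean matching);
* **two BWV estimators**; and
* a **simulation-validation experiment** quantifying imputation error and
  BWV-estimation error at 20–80% missingness on a synthetic cohort with
  known truth.

## The statistics

Both estimators work on relative residuals `r_t = (w_t − trend_t) / w_t`, so
they are in percent of body weight and invariant to body size:

* **Linear (RMSE) method** — the classical measure:
  `BWV = 100 · sqrt(mean(r_t²))` around the OLS line of weight on day.
* **Nonlinear mean deviation (NLMD)** —
  `BWV = 100 · mean(|r_t|)` around a locally quadratic (LOESS) trend whose
  span is an *adaptive, nonincreasing linear function of the number of
  observations*, calibrated so the estimate stays put as data go missing.
  On Gaussian relative noise of SD σ it converges to `100·σ·√(2/π)`.

The headline validation finding: **to estimate BWV, leave missing data
missing.** BWV computed on amputed series disagrees with the full-data value
by only a few percent even at 80% missingness, while BWV computed on imputed
series is biased by tens of percent (underestimation for smoothing methods —
they replace variability with conditional means; overestimation for the
cubic spline, which overshoots).

## Worked example

```r
library(bwvtools)

# a small synthetic cohort with known ground truth
cohort <- generate_cohort(synthetic_params(n_participants = 5, seed = 2024))
series <- split_cohort(cohort)[["P001"]]

estimate_bwv(series)
#> # A tibble: 2 × 5
#>   participant_id method value_pct n_obs span_used
#>   <chr>          <chr>      <dbl> <int>     <dbl>
#> 1 P001           rmse       0.493   334    NA
#> 2 P001           nlmd       0.394   334     0.251

# remove 80% of the observations, then re-estimate: NLMD barely moves
amputed <- ampute_mcar(series, fraction = 0.8, seed = 42)
bwv_nlmd(amputed)
#> # A tibble: 1 × 4
#>   method value_pct n_obs span_used
#>   <chr>      <dbl> <int>     <dbl>
#> 1 nlmd       0.354    67     0.884

# impute with the best-performing method and score it against the truth
imputed <- impute_series(amputed, "smks")
imputation_error(series, imputed)
#> # A tibble: 1 × 5
#>   method rmse_pct mae_kg mape_pct n_eval
#>   <chr>     <dbl>  <dbl>    <dbl>  <int>
#> 1 smks      0.507  0.300    0.414    267

# but BWV on the imputed series collapses: smoothing erased the variability
bwv_nlmd(imputed[, c("participant_id", "date", "day", "weight")])
#> # A tibble: 1 × 4
#>   method value_pct n_obs span_used
#>   <chr>      <dbl> <int>     <dbl>
#> 1 nlmd       0.128   365       0.2
```

Reading the numbers: this participant's true day-to-day variability is about
0.39% of body weight. With 80% of weights removed the NLMD estimate is 0.35%
(−10%), whereas after imputation — even by the most accurate method, whose
per-value error is only ~0.3 kg — the estimate drops to 0.13%, a ~67%
underestimation.

The full experiment across participants, replicates, mechanisms, levels and
methods is one call:

```r
ex <- run_experiment(cohort, experiment_config(scaled = TRUE, seed = 1))
ex$imputation_summary     # imputation fidelity by method x mechanism x level
ex$missing_only_summary   # BWV error without imputation
autoplot(ex, "bwv_nlmd")  # boxplots of per-dataset NLMD errors
```

A command-line interface over the same functions ships in `inst/cli/bwv`
(subcommands `simulate`, `clean`, `ampute`, `impute`, `estimate`,
`experiment`).

## Documentation

See the vignette `vignettes/body-weight-variability.Rmd` for the models,
parameter choices, calibration details, degenerate-input behaviour and known
limitations of the synthetic cohort.
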