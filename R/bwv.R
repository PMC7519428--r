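#' Fit a linear trend to a weight series
#'
#' Ordinary least squares of weight on day number over the observed days.
#'
#' @param series A single-participant weight-series tibble (>= 3 obs).
#' @return A `bwv_trend` object: tibble of observed days with `weight` and
#'   `trend` columns plus fit metadata; see [tidy.bwv_trend()].
#' @export
fit_linear_trend <- function(series) {
  check_single_series(series, min_obs = 3L)
  obs <- filter(series, !is.na(.data$weight))
  fit <- lm(weight ~ day, data = obs)
  new_bwv_trend(
    obs, fitted = unname(predict(fit)), kind = "linear",
    span = NA_real_, degree = 1L,
    coef = coef(fit)
  )
}

#' Adaptive LOESS span from the number of observations
#'
#' The LOESS span is a fraction of the *available* observations, so a fixed
#' span fits tighter as data accumulate. To keep the variability estimate
#' comparable across missingness levels the span is made a (nonincreasing)
#' linear function of the observation count, clamped to its bounds.
#'
#' @param rule A [span_rule()].
#' @param n_obs Number of observed values.
#' @return The span, a single number inside the rule's bounds.
#' @export
adaptive_span <- function(rule, n_obs) {
  if (!inherits(rule, "span_rule")) abort("`rule` must be a span_rule.")
  n_obs <- check_count(n_obs, "n_obs", min = 1L)
  min(max(rule$intercept + rule$slope * n_obs, rule$span_min), rule$span_max)
}

#' Span rule constructor
#'
#' @param intercept Span at zero observations.
#' @param slope Change in span per additional observation; must be <= 0.
#' @param span_min,span_max Clamping bounds, 0 < min <= max <= 1.
#' @return A `span_rule` object.
#' @seealso [default_span_rule()], [calibrate_span()]
#' @export
span_rule <- function(intercept, slope, span_min = 0.2, span_max = 0.9) {
  check_scalar_number(intercept, "intercept")
  check_scalar_number(slope, "slope", upper = 0)
  check_scalar_number(span_min, "span_min", lower = 0, upper = 1, strict = FALSE)
  check_scalar_number(span_max, "span_max", lower = span_min, upper = 1)
  if (span_min <= 0) abort("`span_min` must be > 0.")
  structure(
    list(intercept = intercept, slope = slope,
         span_min = span_min, span_max = span_max),
    class = "span_rule"
  )
}

#' @export
print.span_rule <- function(x, ...) {
  cat(sprintf(
    "Span rule: span(n) = clamp(%.4g %+.4g * n, [%g, %g])\n",
    x$intercept, x$slope, x$span_min, x$span_max
  ))
  invisible(x)
}

#' Default adaptive-span rule
#'
#' Calibrated on the package's default synthetic cohort with
#' [calibrate_span()] (see `scripts/calibrate_span.R` in the source
#' repository to regenerate): the spans minimizing the drift of the mean
#' NLMD between full data and each missingness level, fitted linearly
#' against the observation count.
#'
#' @return A `span_rule` object.
#' @export
default_span_rule <- function() {
  span_rule(
    intercept = .bwv_default_rule$intercept,
    slope = .bwv_default_rule$slope,
    span_min = .bwv_default_rule$span_min,
    span_max = .bwv_default_rule$span_max
  )
}

# Frozen output of scripts/calibrate_span.R (master seed 20240101).
.bwv_default_rule <- list(
  intercept = 1.042774, slope = -0.00236954, span_min = 0.2, span_max = 0.9
)

#' Fit a LOESS trend to a weight series
#'
#' Local quadratic regression (degree 2) with tricube weights over a
#' neighbourhood of the nearest `floor(span * n_obs)` observed points,
#' evaluated at every observed day. The neighbourhood is defined on the
#' observed points, not the grid, so the span is a fraction of the
#' available data.
#'
#' @param series A single-participant weight-series tibble (>= 10 obs).
#' @param span LOESS span in (0, 1].
#' @return A `bwv_trend` object.
#' @export
fit_loess_trend <- function(series, span) {
  check_single_series(series, min_obs = 10L)
  check_scalar_number(span, "span", lower = 0, upper = 1, strict = FALSE)
  if (span <= 0) abort("`span` must be in (0, 1].")
  obs <- filter(series, !is.na(.data$weight))
  if (floor(span * nrow(obs)) < 4) {
    abort("LOESS neighbourhood would have fewer than 4 points; increase the span.")
  }
  fit <- loess(
    weight ~ day, data = obs, span = span, degree = 2,
    family = "gaussian",
    control = loess.control(surface = "direct")
  )
  new_bwv_trend(
    obs, fitted = unname(predict(fit)), kind = "loess",
    span = span, degree = 2L, coef = NULL
  )
}

new_bwv_trend <- function(obs, fitted, kind, span, degree, coef = NULL) {
  structure(
    list(
      data = tibble(
        participant_id = obs$participant_id,
        date = obs$date,
        day = obs$day,
        weight = obs$weight,
        trend = fitted
      ),
      kind = kind, span = span, degree = degree, coef = coef
    ),
    class = "bwv_trend"
  )
}

#' @export
print.bwv_trend <- function(x, ...) {
  cat(sprintf(
    "<bwv_trend> %s trend%s over %d observed days\n",
    x$kind,
    if (x$kind == "loess") sprintf(" (span %.3f, degree %d)", x$span, x$degree) else "",
    nrow(x$data)
  ))
  invisible(x)
}

#' Relative residuals around a fitted trend
#'
#' The centered weight (observed minus trend) divided by the observed
#' weight at each day, making downstream variability statistics invariant
#' to overall body size.
#'
#' @param series A single-participant weight-series tibble.
#' @param trend A `bwv_trend` fitted to the same series.
#' @return A tibble (`day`, `weight`, `trend`, `rel_resid`).
#' @export
relative_residuals <- function(series, trend) {
  check_single_series(series)
  if (!inherits(trend, "bwv_trend")) abort("`trend` must be a bwv_trend.")
  obs <- filter(series, !is.na(.data$weight))
  if (!identical(obs$day, trend$data$day)) {
    abort("`trend` was not fitted to the observed days of `series`.")
  }
  if (any(obs$weight <= 0)) abort("Weights must be positive.")
  trend_vals <- trend$data$trend
  tibble(
    day = obs$day,
    weight = obs$weight,
    trend = trend_vals,
    rel_resid = (obs$weight - trend_vals) / obs$weight
  )
}

#' Linear (RMSE) body-weight variability
#'
#' The classical linear BWV statistic: 100 times the root mean square of
#' the relative residuals around the OLS linear trend. An exactly linear
#' weight trajectory scores 0; the statistic is unchanged when all weights
#' are multiplied by a positive constant.
#'
#' @param series A single-participant weight-series tibble (>= 3 obs).
#' @return A one-row tibble: `method`, `value_pct`, `n_obs`, `span_used`.
#' @export
bwv_rmse <- function(series) {
  trend <- fit_linear_trend(series)
  r <- relative_residuals(series, trend)$rel_resid
  tibble(
    method = "rmse",
    value_pct = 100 * sqrt(mean(r^2)),
    n_obs = length(r),
    span_used = NA_real_
  )
}

#' Nonlinear mean deviation (NLMD) body-weight variability
#'
#' The nonlinear BWV statistic: 100 times the mean absolute relative
#' residual around the adaptive-span LOESS trend (degree 2). The absolute
#' value is what turns centered residuals -- whose plain mean is ~0 for any
#' least-squares-type fit -- into a mean relative deviation from the trend.
#'
#' @param series A single-participant weight-series tibble (>= 10 obs).
#' @param rule A [span_rule()]; defaults to the calibrated
#'   [default_span_rule()].
#' @return A one-row tibble: `method`, `value_pct`, `n_obs`, `span_used`.
#' @export
bwv_nlmd <- function(series, rule = default_span_rule()) {
  check_single_series(series, min_obs = 10L)
  span <- adaptive_span(rule, n_obs(series))
  trend <- fit_loess_trend(series, span)
  r <- relative_residuals(series, trend)$rel_resid
  tibble(
    method = "nlmd",
    value_pct = 100 * mean(abs(r)),
    n_obs = length(r),
    span_used = span
  )
}

#' Both BWV statistics for every participant of a cohort
#'
#' @param cohort A weight-series tibble (any number of participants).
#' @param methods Subset of `c("rmse", "nlmd")`.
#' @param rule Span rule for NLMD.
#' @return A tibble with one row per participant and method.
#' @export
estimate_bwv <- function(cohort, methods = c("rmse", "nlmd"),
                         rule = default_span_rule()) {
  methods <- match.arg(methods, c("rmse", "nlmd"), several.ok = TRUE)
  purrr::map(split_cohort(cohort), function(s) {
    bind_rows(
      if ("rmse" %in% methods) bwv_rmse(s),
      if ("nlmd" %in% methods) bwv_nlmd(s, rule = rule)
    ) %>%
      mutate(participant_id = s$participant_id[1], .before = 1)
  }) %>%
    bind_rows()
}
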