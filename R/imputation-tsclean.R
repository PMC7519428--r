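#' Seasonal-decomposition / super-smoother imputation
#'
#' First tests for weekly (period-7) seasonality via the strength-of-
#' seasonality ratio of a robust seasonal-trend (STL) decomposition. If the
#' series is seasonal, the observed values are seasonally adjusted, the
#' adjusted series is linearly interpolated, and the seasonal component is
#' added back. Otherwise Friedman's variable-span super smoother supplies
#' the trend and the smoothed residual-adjusted series is linearly
#' interpolated. The branch decision is deterministic.
#'
#' @param series A single-participant weight-series tibble; at least 14
#'   observations for the seasonal branch, 4 otherwise.
#' @param seasonal_threshold Declare seasonality when
#'   `1 - var(remainder) / var(seasonal + remainder)` exceeds this value.
#'   Default 0.64, the usual strength-of-seasonality convention.
#' @return Completed series tibble with `imputed` flags; the branch taken is
#'   recorded in the `"branch"` attribute (`"seasonal"` / `"nonseasonal"`).
#' @export
impute_tsclean <- function(series, seasonal_threshold = 0.64) {
  check_single_series(series, min_obs = 4L)
  check_scalar_number(seasonal_threshold, "seasonal_threshold", lower = 0, upper = 1)
  w <- series$weight
  n <- length(w)
  obs <- which(!is.na(w))

  branch <- "nonseasonal"
  filled <- w
  if (n_obs(series) >= 14 && n >= 3 * 7) {
    dec <- tryCatch(stl_decompose_period7(series), error = function(e) NULL)
    if (!is.null(dec)) {
      strength <- max(
        0,
        1 - var(dec$remainder[obs]) /
          var(dec$seasonal[obs] + dec$remainder[obs])
      )
      if (is.finite(strength) && strength > seasonal_threshold) {
        branch <- "seasonal"
        adj <- w - dec$seasonal # seasonally adjusted, NA at gaps
        interp <- approx(series$day[obs], adj[obs], xout = series$day,
                         rule = 1)$y
        filled <- interp + dec$seasonal
      }
    }
  }
  if (branch == "nonseasonal") {
    sm <- supsmu(series$day[obs], w[obs])
    trend_obs <- approx(sm$x, sm$y, xout = series$day[obs], rule = 2)$y
    resid_obs <- w[obs] - trend_obs
    trend_all <- approx(series$day[obs], trend_obs, xout = series$day,
                        rule = 1)$y
    resid_all <- approx(series$day[obs], resid_obs, xout = series$day,
                        rule = 1)$y
    filled <- trend_all + resid_all
  }
  out <- finish_imputation(series, filled, "tsclean")
  attr(out, "branch") <- branch
  out
}

# Robust STL with weekly period on the linearly pre-interpolated series
# (STL needs a complete series); returns per-day seasonal and remainder.
stl_decompose_period7 <- function(series) {
  w <- series$weight
  obs <- which(!is.na(w))
  complete <- approx(series$day[obs], w[obs], xout = series$day, rule = 2)$y
  fit <- stl(ts(complete, frequency = 7), s.window = "periodic", robust = TRUE)
  comp <- fit$time.series
  list(
    seasonal = as.numeric(comp[, "seasonal"]),
    remainder = w - as.numeric(comp[, "seasonal"]) - as.numeric(comp[, "trend"]),
    trend = as.numeric(comp[, "trend"])
  )
}
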