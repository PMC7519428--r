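#' Impute missing weights by a named method
#'
#' Unified front end to the ten imputation algorithms. All methods obey the
#' same contract: observed values are never modified, the output contains no
#' missing values, and the `imputed` column flags exactly the days that were
#' missing on input. Leading/trailing missing days, which interpolants
#' cannot bracket, are filled by the nearest observed value (they remain
#' flagged so downstream analyses can exclude edges).
#'
#' @param series A single-participant weight-series tibble.
#' @param method One of `"linear"`, `"spline"`, `"stine"` (interpolants),
#'   `"ewma"` (exponentially weighted moving average), `"smks"` (structural
#'   model + Kalman smoothing), `"assrks"` (ARIMA state space + Kalman
#'   smoothing), `"tsclean"` (seasonal decomposition / super smoother +
#'   interpolation), `"knn"`, `"rf"`, `"pmm"` (multivariate, using day
#'   number and day of week as predictors).
#' @param ... Method-specific arguments passed through: `k` (ewma window
#'   half-width or knn neighbours), `base` (ewma decay base), `donors`
#'   (pmm), `seed` (rf, pmm), `seasonal_threshold` (tsclean).
#' @return The completed series tibble with an added logical `imputed`
#'   column and attribute `"method"`.
#' @seealso [impute_interp()], [impute_ewma()], [impute_kalman_structural()],
#'   [impute_kalman_arima()], [impute_tsclean()], [impute_knn()],
#'   [impute_rf()], [impute_pmm()]
#' @export
impute_series <- function(series, method, ...) {
  method <- match.arg(
    method,
    c("linear", "spline", "stine", "ewma", "smks", "assrks",
      "tsclean", "knn", "rf", "pmm")
  )
  dots <- list(...)
  fn <- switch(
    method,
    linear = ,
    spline = ,
    stine = function(s, ...) impute_interp(s, method = method),
    ewma = impute_ewma,
    smks = impute_kalman_structural,
    assrks = impute_kalman_arima,
    tsclean = impute_tsclean,
    knn = impute_knn,
    rf = impute_rf,
    pmm = impute_pmm
  )
  accepted <- names(formals(switch(
    method,
    linear = , spline = , stine = impute_interp,
    ewma = impute_ewma, smks = impute_kalman_structural,
    assrks = impute_kalman_arima, tsclean = impute_tsclean,
    knn = impute_knn, rf = impute_rf, pmm = impute_pmm
  )))
  dots <- dots[names(dots) %in% setdiff(accepted, "series")]
  do.call(fn, c(list(series), dots))
}

#' All imputation method labels
#' @return Character vector of the ten method names.
#' @export
imputation_methods <- function() {
  c("linear", "spline", "stine", "ewma", "smks", "assrks",
    "tsclean", "knn", "rf", "pmm")
}

# Assemble the output contract: fill vector `filled` (complete), original
# series, method label. Edge missing values are nearest-value carried here
# if the method left them NA.
finish_imputation <- function(series, filled, method) {
  stopifnot(length(filled) == nrow(series))
  miss <- is.na(series$weight)
  filled[!miss] <- series$weight[!miss] # observed values are sacrosanct
  if (any(is.na(filled))) {
    obs <- which(!is.na(filled))
    first_o <- obs[1]
    last_o <- obs[length(obs)]
    if (first_o > 1) filled[seq_len(first_o - 1)] <- filled[first_o]
    if (last_o < length(filled)) {
      filled[(last_o + 1):length(filled)] <- filled[last_o]
    }
    if (any(is.na(filled))) {
      abort(sprintf("Method '%s' left interior values unimputed.", method))
    }
  }
  out <- series
  out$weight <- filled
  out$imputed <- miss
  attr(out, "method") <- method
  out
}

#' Day-number / day-of-week covariates of a series
#'
#' The multivariate imputers use only automatically available predictors:
#' the day number within the series and the ISO day of week (1 = Monday).
#'
#' @param series A weight-series tibble.
#' @return A tibble (`day`, `day_number`, `day_of_week`).
#' @export
covariate_table <- function(series) {
  check_single_series(series)
  tibble(
    day = series$day,
    day_number = series$day,
    day_of_week = iso_dow(series$date)
  )
}
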