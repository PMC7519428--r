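#' Structural-model imputation with Kalman smoothing (SMKS)
#'
#' Fits a structural time-series model by maximum likelihood -- local linear
#' trend plus, when the grid spans at least 8 weeks, a weekly (period-7)
#' seasonal component -- and replaces every missing entry by the smoothed
#' state expectation. The smoother conditions on the entire sample, so long
#' gaps are bridged by the model's trend and seasonality rather than locally.
#' If the optimizer fails, the model falls back to a local level.
#'
#' @param series A single-participant weight-series tibble (>= 10 obs).
#' @return Completed series tibble with `imputed` flags.
#' @export
impute_kalman_structural <- function(series) {
  check_single_series(series, min_obs = 10L)
  w <- series$weight
  n <- length(w)
  # the state-space filter needs an observed first value: fit on the window
  # from first to last observation; edges are carried by the contract
  rng <- range(which(!is.na(w)))
  win <- seq(rng[1], rng[2])
  if (sd(w, na.rm = TRUE) < 1e-10) { # degenerate state: constant series
    return(finish_imputation(series, rep(mean(w, na.rm = TRUE), n), "smks"))
  }
  use_seasonal <- length(win) >= 56
  filled <- NULL
  fit_fill <- function(type) {
    y <- ts(w[win], frequency = if (type == "BSM") 7 else 1)
    fit <- suppressWarnings(StructTS(y, type = type))
    sm <- tsSmooth(fit)
    est <- if (type == "BSM") sm[, "level"] + sm[, "sea"] else sm[, "level"]
    as.numeric(est)
  }
  types <- c(if (use_seasonal) "BSM", "trend", "level")
  for (type in types) {
    filled <- tryCatch(fit_fill(type), error = function(e) NULL)
    if (!is.null(filled) && all(is.finite(filled))) break
    filled <- NULL
  }
  if (is.null(filled)) {
    abort("Structural-model imputation failed for every candidate model.")
  }
  full <- rep(NA_real_, n)
  full[win] <- filled
  finish_imputation(series, full, "smks")
}

#' ARIMA state-space imputation with Kalman smoothing (ASSRKS)
#'
#' Searches ARIMA orders p, q in 0..2 and d in 0..1, fitted by maximum
#' likelihood on the observed values (missing entries enter the likelihood
#' as missing), selects by AICc, and fills missing entries with the Kalman
#' smoother's expectation under the chosen model.
#'
#' @param series A single-participant weight-series tibble (>= 10 obs).
#' @param orders Optional data frame of candidate orders (`p`, `d`, `q`);
#'   defaults to the full p,q in 0..2, d in 0..1 grid.
#' @return Completed series tibble with `imputed` flags; the chosen order is
#'   recorded in the `"arima_order"` attribute.
#' @export
impute_kalman_arima <- function(series, orders = NULL) {
  check_single_series(series, min_obs = 10L)
  if (is.null(orders)) {
    orders <- expand.grid(p = 0:2, d = 0:1, q = 0:2)
  }
  w_all <- series$weight
  rng <- range(which(!is.na(w_all)))
  win <- seq(rng[1], rng[2])
  w <- w_all[win]
  if (sd(w, na.rm = TRUE) < 1e-10) { # constant series: nothing to model
    out <- finish_imputation(
      series, rep(mean(w, na.rm = TRUE), length(w_all)), "assrks"
    )
    attr(out, "arima_order") <- c(0, 0, 0)
    return(out)
  }
  n_eff <- sum(!is.na(w))
  best <- NULL
  best_aicc <- Inf
  for (j in seq_len(nrow(orders))) {
    ord <- c(orders$p[j], orders$d[j], orders$q[j])
    fit <- tryCatch(
      suppressWarnings(arima(w, order = ord, method = "ML")),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    npar <- length(fit$coef) + 1
    aicc <- fit$aic + 2 * npar * (npar + 1) / max(n_eff - npar - 1, 1)
    if (is.finite(aicc) && aicc < best_aicc) {
      best <- fit
      best_aicc <- aicc
      best_ord <- ord
    }
  }
  if (is.null(best)) abort("All candidate ARIMA orders failed to fit.")
  # the mean of a d = 0 model lives outside the state space
  mu <- if ("intercept" %in% names(best$coef)) best$coef[["intercept"]] else 0
  ks <- KalmanSmooth(w - mu, best$model)
  filled <- rep(NA_real_, length(w_all))
  filled[win] <- as.numeric(ks$smooth %*% as.matrix(best$model$Z)) + mu
  out <- finish_imputation(series, filled, "assrks")
  attr(out, "arima_order") <- best_ord
  out
}
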