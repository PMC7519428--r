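# Multivariate imputers: weight regressed on day number and day of week,
# the two predictors available without participant burden.

#' K-nearest-neighbour imputation
#'
#' For each missing day, the `k` observed days nearest in standardized
#' (day number, day of week) space contribute a distance-weighted average
#' with weights `exp(-d)`.
#'
#' @param series A single-participant weight-series tibble.
#' @param k Number of neighbours (default 10); must not exceed the number of
#'   observed values.
#' @return Completed series tibble with `imputed` flags.
#' @export
impute_knn <- function(series, k = 10) {
  check_single_series(series, min_obs = 2L)
  k <- check_count(k, "k", min = 1L)
  if (k > n_obs(series)) {
    abort(sprintf("`k` (%d) exceeds the number of observed values (%d).",
                  k, n_obs(series)))
  }
  cov <- covariate_table(series)
  X <- scale(cbind(cov$day_number, cov$day_of_week))
  X[is.nan(X)] <- 0 # zero-variance column (e.g. sub-week series)
  obs <- which(!is.na(series$weight))
  filled <- series$weight
  for (i in which(is.na(series$weight))) {
    d <- sqrt((X[obs, 1] - X[i, 1])^2 + (X[obs, 2] - X[i, 2])^2)
    nb <- obs[order(d)[seq_len(k)]]
    wt <- exp(-sort(d)[seq_len(k)])
    filled[i] <- sum(wt * series$weight[nb]) / sum(wt)
  }
  finish_imputation(series, filled, "knn")
}

#' Iterative random-forest imputation
#'
#' missForest-style loop: initialize missing entries with the observed mean,
#' then repeatedly fit a random-forest regression of weight on day number
#' and day of week over the observed days and re-predict the missing days,
#' stopping when the relative change in the imputed values rises or after
#' `max_iter` iterations.
#'
#' @param series A single-participant weight-series tibble (>= 20 obs).
#' @param seed Integer seed; the same seed gives bitwise-identical output.
#' @param num_trees Trees per forest (default 100, the usual forest-imputation default).
#' @param max_iter Iteration cap (default 10).
#' @return Completed series tibble with `imputed` flags.
#' @export
impute_rf <- function(series, seed = 1, num_trees = 100, max_iter = 10) {
  check_single_series(series, min_obs = 20L)
  seed <- check_count(seed, "seed", min = 0L)
  cov <- covariate_table(series)
  df <- tibble(
    weight = series$weight,
    day_number = cov$day_number,
    day_of_week = factor(cov$day_of_week, levels = 1:7)
  )
  miss <- which(is.na(df$weight))
  if (length(miss) == 0) return(finish_imputation(series, series$weight, "rf"))
  obs <- which(!is.na(df$weight))
  current <- rep(mean(df$weight[obs]), length(miss))
  last_change <- Inf
  for (iter in seq_len(max_iter)) {
    fit <- ranger::ranger(
      weight ~ day_number + day_of_week,
      data = df[obs, ],
      num.trees = num_trees,
      seed = seed + iter,
      num.threads = 1
    )
    new <- predict(fit, data = df[miss, ], num.threads = 1)$predictions
    change <- sum((new - current)^2) / max(sum(new^2), .Machine$double.eps)
    current <- new
    if (change >= last_change || change == 0) break
    last_change <- change
  }
  filled <- series$weight
  filled[miss] <- current
  finish_imputation(series, filled, "rf")
}

#' Predictive-mean-matching imputation
#'
#' Bayesian linear regression of weight on day number and day-of-week
#' indicators over the observed days; for each missing day the `donors`
#' observed days with predicted values nearest to the missing day's
#' prediction form the candidate pool, and one donor's *observed* weight is
#' copied. Every imputed value is therefore a member of the observed-value
#' set. A single completed trajectory is produced.
#'
#' @param series A single-participant weight-series tibble with at least
#'   `donors + 2` observations.
#' @param donors Candidate-pool size (default 5).
#' @param seed Integer seed for the parameter draw and donor sampling.
#' @return Completed series tibble with `imputed` flags.
#' @export
impute_pmm <- function(series, donors = 5, seed = 1) {
  donors <- check_count(donors, "donors", min = 1L)
  check_single_series(series, min_obs = donors + 2L)
  seed <- check_count(seed, "seed", min = 0L)
  cov <- covariate_table(series)
  dow <- factor(cov$day_of_week, levels = 1:7)
  X <- cbind(1, scale(cov$day_number), model.matrix(~ dow)[, -1, drop = FALSE])
  if (any(is.nan(X))) X[is.nan(X)] <- 0
  # drop all-zero indicator columns (weekdays absent from a short grid)
  X <- X[, colSums(abs(X)) > 0, drop = FALSE]
  obs <- which(!is.na(series$weight))
  miss <- which(is.na(series$weight))
  if (length(miss) == 0) {
    return(finish_imputation(series, series$weight, "pmm"))
  }
  y <- series$weight[obs]
  Xo <- X[obs, , drop = FALSE]
  XtX <- crossprod(Xo)
  # ridge whisper against singular designs, as chained-equation imputers do
  XtX_r <- XtX + diag(ncol(Xo)) * 1e-8 * mean(diag(XtX))
  qrX <- tryCatch(chol(XtX_r), error = function(e) NULL)
  if (is.null(qrX)) abort("Singular design in predictive mean matching.")
  beta_hat <- backsolve(qrX, forwardsolve(t(qrX), crossprod(Xo, y)))
  resid <- y - Xo %*% beta_hat
  df_res <- max(length(obs) - ncol(Xo), 1)
  filled <- series$weight
  with_seed(seed, {
    sigma2 <- sum(resid^2) / rchisq(1, df_res)
    V <- chol2inv(qrX)
    beta_star <- beta_hat +
      t(chol(sigma2 * (V + t(V)) / 2)) %*% rnorm(ncol(Xo))
    yhat_obs <- as.numeric(Xo %*% beta_hat)
    yhat_mis <- as.numeric(X[miss, , drop = FALSE] %*% beta_star)
    for (j in seq_along(miss)) {
      pool <- obs[order(abs(yhat_obs - yhat_mis[j]))[seq_len(donors)]]
      filled[miss[j]] <- series$weight[sample(rep(pool, 2), 1)]
    }
  })
  finish_imputation(series, filled, "pmm")
}
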