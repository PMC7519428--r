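#' Interpolation-based imputation
#'
#' Fills interior gaps by linear interpolation, a natural cubic spline, or
#' Stineman's monotonicity-preserving rational interpolation. All three
#' reproduce an exactly linear series; the spline can overshoot at abrupt
#' changes while the Stineman interpolant does not.
#'
#' @param series A single-participant weight-series tibble; at least 2
#'   observations (4 for `"spline"`).
#' @param method `"linear"`, `"spline"`, or `"stine"`.
#' @return Completed series tibble with `imputed` flags.
#' @export
impute_interp <- function(series, method = c("linear", "spline", "stine")) {
  method <- match.arg(method)
  min_obs <- if (method == "spline") 4L else 2L
  check_single_series(series, min_obs = min_obs)
  x <- series$day
  obs <- !is.na(series$weight)
  xo <- x[obs]
  yo <- series$weight[obs]
  filled <- series$weight
  gap <- !obs & x > min(xo) & x < max(xo)
  if (any(gap)) {
    filled[gap] <- switch(
      method,
      linear = approx(xo, yo, xout = x[gap])$y,
      spline = spline(xo, yo, method = "natural", xout = x[gap])$y,
      stine = stineman_interp(xo, yo, x[gap])
    )
  }
  finish_imputation(series, filled, method)
}

# Stineman (1980) rational interpolation: slopes at knots from the parabola
# through each consecutive point triple, then a rational correction to the
# chord that cannot overshoot; monotone data yield a monotone interpolant.
stineman_interp <- function(x, y, xout) {
  m <- length(x)
  dx <- diff(x)
  dy <- diff(y)
  s <- dy / dx
  yp <- numeric(m)
  if (m == 2) {
    yp[] <- s
  } else {
    i <- 2:(m - 1)
    yp[i] <- (s[i - 1] * dx[i] + s[i] * dx[i - 1]) / (dx[i - 1] + dx[i])
    yp[1] <- 2 * s[1] - yp[2]
    yp[m] <- 2 * s[m - 1] - yp[m - 1]
    # keep endpoint slopes on the secant's side to preserve monotonicity
    yp[1] <- if (s[1] >= 0) max(0, yp[1]) else min(0, yp[1])
    yp[m] <- if (s[m - 1] >= 0) max(0, yp[m]) else min(0, yp[m])
  }
  seg <- findInterval(xout, x, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), m - 1L)
  x1 <- x[seg]; x2 <- x[seg + 1L]
  y1 <- y[seg]; y2 <- y[seg + 1L]
  sl <- s[seg]
  yo <- y1 + sl * (xout - x1)
  dy1 <- (yp[seg] - sl) * (xout - x1)
  dy2 <- (yp[seg + 1L] - sl) * (xout - x2)
  prod <- dy1 * dy2
  corr <- numeric(length(xout))
  pos <- !is.na(prod) & prod > 0
  neg <- !is.na(prod) & prod < 0
  corr[pos] <- prod[pos] / (dy1[pos] + dy2[pos])
  corr[neg] <- prod[neg] * ((xout[neg] - x1[neg]) + (xout[neg] - x2[neg])) /
    ((dy1[neg] - dy2[neg]) * (x2[neg] - x1[neg]))
  yo + corr
}

#' Exponentially weighted moving-average imputation
#'
#' Each missing value is the weighted mean of up to `k` observed values on
#' either side, with weights decaying as `base^(-d)` in the day distance
#' `d`; one-sided at the series edges.
#'
#' @param series A single-participant weight-series tibble (>= 2 obs).
#' @param k Window half-width: observed values used per side. Default 4.
#' @param base Base of the exponential decay. Default 2 (halving per day).
#' @return Completed series tibble with `imputed` flags.
#' @export
impute_ewma <- function(series, k = 4, base = 2) {
  check_single_series(series, min_obs = 2L)
  k <- check_count(k, "k", min = 1L)
  check_scalar_number(base, "base", lower = 1, strict = TRUE)
  x <- series$day
  w <- series$weight
  obs_idx <- which(!is.na(w))
  filled <- w
  for (i in which(is.na(w))) {
    left <- rev(obs_idx[obs_idx < i])
    right <- obs_idx[obs_idx > i]
    nb <- c(head(left, k), head(right, k))
    if (length(nb) == 0) next # edge beyond all observations: carried later
    d <- abs(x[nb] - x[i])
    wt <- base^(-d)
    filled[i] <- sum(wt * w[nb]) / sum(wt)
  }
  finish_imputation(series, filled, "ewma")
}
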