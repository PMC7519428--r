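#' Parameters of the synthetic weight-trajectory generator
#'
#' Defaults emulate a cohort of frequent self-weighers followed for a year:
#' 50 participants, baseline weight Normal(81.9, 15.4) kg, about 336
#' measurements over 365 days, an individual annual trend of up to +/-5% of
#' baseline (linear, curvilinear, or loss-plateau-regain), a small
#' weekend-peaking weekly cycle, and day-to-day multiplicative Gaussian
#' noise of 0.5% -- the order of true human day-to-day weight fluctuation.
#'
#' @param n_participants Cohort size.
#' @param n_days Grid length in days (>= 28).
#' @param baseline_mean_kg,baseline_sd_kg Baseline weight distribution.
#' @param trend_type `"linear"`, `"curvilinear"`, `"plateau_regain"`, or
#'   `"mixture"` (one third each, the default for cohorts).
#' @param trend_amplitude_frac Maximum annual trend excursion as a fraction
#'   of baseline.
#' @param weekly_amp_frac Weekend weight elevation as a fraction of body
#'   weight (peak-to-trough of the weekly cycle).
#' @param noise_rel_sd Relative SD of the multiplicative daily noise.
#' @param obs_prob Independent per-day observation probability (default
#'   336/365).
#' @param seed Master seed.
#' @return A `synthetic_params` list.
#' @export
synthetic_params <- function(n_participants = 50,
                             n_days = 365,
                             baseline_mean_kg = 81.9,
                             baseline_sd_kg = 15.4,
                             trend_type = "mixture",
                             trend_amplitude_frac = 0.05,
                             weekly_amp_frac = 0.003,
                             noise_rel_sd = 0.005,
                             obs_prob = 336 / 365,
                             seed = 20240101) {
  n_participants <- check_count(n_participants, "n_participants", min = 1L)
  n_days <- check_count(n_days, "n_days", min = 28L)
  check_scalar_number(baseline_mean_kg, "baseline_mean_kg", lower = 0, strict = TRUE)
  check_scalar_number(baseline_sd_kg, "baseline_sd_kg", lower = 0)
  trend_type <- match.arg(
    trend_type, c("mixture", "linear", "curvilinear", "plateau_regain")
  )
  check_scalar_number(trend_amplitude_frac, "trend_amplitude_frac", lower = 0, upper = 1)
  check_scalar_number(weekly_amp_frac, "weekly_amp_frac", lower = 0, upper = 1)
  check_scalar_number(noise_rel_sd, "noise_rel_sd", lower = 0, upper = 1)
  check_scalar_number(obs_prob, "obs_prob", lower = 0, upper = 1)
  if (obs_prob <= 0) abort("`obs_prob` must be in (0, 1].")
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(
      n_participants = n_participants, n_days = n_days,
      baseline_mean_kg = baseline_mean_kg, baseline_sd_kg = baseline_sd_kg,
      trend_type = trend_type,
      trend_amplitude_frac = trend_amplitude_frac,
      weekly_amp_frac = weekly_amp_frac,
      noise_rel_sd = noise_rel_sd,
      obs_prob = obs_prob, seed = seed
    ),
    class = "synthetic_params"
  )
}

# Weekly additive cycle shape (Mon..Sun), zero-mean, weekend peak with a
# linear ramp-down over the working week; scaled so peak-to-trough = 1.
weekly_shape <- function() {
  raw <- c(0.8, 0.6, 0.4, 0.2, 0.0, 1.0, 1.0) # Mon..Sun
  (raw - mean(raw)) / (max(raw) - min(raw))
}

trend_curve <- function(trend_type, n_days, amp_frac, u) {
  t01 <- (seq_len(n_days) - 1) / (n_days - 1)
  switch(
    trend_type,
    linear = u * amp_frac * t01,
    curvilinear = u * amp_frac * 4 * t01 * (1 - t01),
    plateau_regain = {
      loss <- abs(u) * amp_frac
      knots_x <- c(0, 0.4, 0.7, 1)
      knots_y <- c(0, -loss, -loss, -loss / 2)
      spline(knots_x, knots_y, xout = t01, method = "natural")$y
    }
  )
}

#' Generate one synthetic participant with known ground truth
#'
#' The daily weight is `(trend + seasonal) * (1 + eps)` with `eps ~
#' N(0, noise_rel_sd)` independently per day; each day is observed with
#' probability `obs_prob`. Columns `weight_true`, `trend` and `seasonal`
#' carry the complete ground truth; the attribute `"truth_stats"` carries
#' the analytic expectations of both BWV statistics.
#'
#' @param params A [synthetic_params()] object.
#' @param participant_seed Integer seed for this participant.
#' @param participant_id Identifier (default derived from the seed).
#' @return A weight-series tibble with extra truth columns.
#' @export
generate_participant <- function(params, participant_seed,
                                 participant_id = sprintf("S%05d", participant_seed %% 100000L)) {
  if (!inherits(params, "synthetic_params")) {
    abort("`params` must come from synthetic_params().")
  }
  participant_seed <- check_count(participant_seed, "participant_seed", min = 0L)
  n <- params$n_days
  with_seed(participant_seed, {
    baseline <- max(rnorm(1, params$baseline_mean_kg, params$baseline_sd_kg), 35)
    trend_type <- if (params$trend_type == "mixture") {
      sample(c("linear", "curvilinear", "plateau_regain"), 1)
    } else {
      params$trend_type
    }
    u <- runif(1, -1, 1)
    dates <- as.Date("2023-01-02") + seq_len(n) - 1 # starts on a Monday
    dow <- iso_dow(dates)
    trend <- baseline * (1 + trend_curve(trend_type, n, params$trend_amplitude_frac, u))
    seasonal <- params$weekly_amp_frac * baseline * weekly_shape()[dow]
    eps <- rnorm(n, 0, params$noise_rel_sd)
    weight_true <- (trend + seasonal) * (1 + eps)
    observed <- runif(n) < params$obs_prob
    out <- tibble(
      participant_id = participant_id,
      date = dates,
      day = seq_len(n),
      weight = ifelse(observed, weight_true, NA_real_),
      weight_true = weight_true,
      trend = trend,
      seasonal = seasonal
    )
    attr(out, "truth_stats") <- truth_stats(trend, seasonal, params$noise_rel_sd)
    attr(out, "trend_type") <- trend_type
    out
  })
}

# Analytic expectations of the BWV statistics for a known decomposition.
# Relative residual around the ideal trend ~ N(c_t, sigma) with
# c_t = seasonal_t / (trend_t + seasonal_t); for the linear statistic the
# deterministic lack-of-fit of the trend to its own OLS line is added.
truth_stats <- function(trend, seasonal, sigma) {
  w_mean <- trend + seasonal
  c_t <- seasonal / w_mean
  mu <- c_t
  # E|N(mu, sigma)| (folded normal mean)
  e_abs <- if (sigma > 0) {
    sigma * sqrt(2 / pi) * exp(-mu^2 / (2 * sigma^2)) +
      mu * (1 - 2 * pnorm(-mu / sigma))
  } else {
    abs(mu)
  }
  day <- seq_along(trend)
  ols <- lsfit(day, w_mean)
  g_t <- ols$residuals / w_mean
  tibble(
    true_nlmd_pct = 100 * mean(e_abs),
    true_rmse_bwv_pct = 100 * sqrt(mean(g_t^2) + sigma^2),
    noise_rel_sd = sigma
  )
}

#' Truth statistics of a synthetic series
#' @param x A series from [generate_participant()].
#' @return One-row tibble of analytic BWV expectations.
#' @export
truth_stats_of <- function(x) {
  st <- attr(x, "truth_stats")
  if (is.null(st)) abort("`x` carries no truth statistics.")
  st
}

#' Generate a synthetic cohort
#'
#' Independent participants with per-participant seeds derived from the
#' master seed; under the `"mixture"` trend type each participant draws one
#' of the three trend shapes.
#'
#' @param params A [synthetic_params()] object.
#' @return A weight-series tibble (all participants stacked) with truth
#'   columns; per-participant truth statistics in the `"truth_stats"`
#'   attribute (one row per participant).
#' @export
generate_cohort <- function(params = synthetic_params()) {
  if (!inherits(params, "synthetic_params")) {
    abort("`params` must come from synthetic_params().")
  }
  seeds <- params$seed + 1000L * seq_len(params$n_participants)
  pieces <- purrr::map2(
    seeds, seq_len(params$n_participants),
    function(s, i) generate_participant(params, s, sprintf("P%03d", i))
  )
  stats <- purrr::map2(pieces, seq_along(pieces), function(p, i) {
    mutate(truth_stats_of(p), participant_id = p$participant_id[1], .before = 1)
  }) %>% bind_rows()
  out <- bind_rows(pieces)
  attr(out, "truth_stats") <- stats
  out
}

#' Generate a bursty (real-pattern-style) missingness donor mask
#'
#' A 2-state Markov observation process whose stationary missing fraction is
#' `fraction` and whose missing runs average `mean_burst` days, emulating
#' the bursty structure of real self-weighing lapses (unlike MCAR, where
#' missing days are scattered).
#'
#' @param n_days Mask length.
#' @param fraction Target missing fraction in (0, 1).
#' @param mean_burst Mean missing-run length in days (default 7).
#' @param seed Integer seed.
#' @return A mask tibble (`day`, `observed`).
#' @export
generate_rpm_donor <- function(n_days, fraction, mean_burst = 7, seed = 1) {
  n_days <- check_count(n_days, "n_days", min = 1L)
  check_scalar_number(fraction, "fraction", lower = 0, upper = 1, strict = TRUE)
  check_scalar_number(mean_burst, "mean_burst", lower = 1)
  p_exit <- 1 / mean_burst # missing -> observed
  p_enter <- p_exit * fraction / (1 - fraction) # observed -> missing
  p_enter <- min(p_enter, 1)
  with_seed(seed, {
    state <- runif(1) >= fraction # TRUE = observed
    obs <- logical(n_days)
    for (i in seq_len(n_days)) {
      obs[i] <- state
      state <- if (state) runif(1) >= p_enter else runif(1) < p_exit
    }
    if (!any(obs)) obs[sample.int(n_days, 1)] <- TRUE
    tibble(day = seq_len(n_days), observed = obs)
  })
}
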