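#' Calibrate the adaptive-span rule against missingness
#'
#' The NLMD statistic should not drift as data go missing. For each
#' missingness level this routine searches the span minimizing the absolute
#' drift of the cohort-mean NLMD on MCAR-amputed series relative to the
#' full-data cohort mean (computed at `base_span`), then fits
#' `span ~ intercept + slope * n_obs` by least squares through the
#' per-level optima plus the full-data anchor, constraining the slope to be
#' nonpositive.
#'
#' @param cohort A weight-series tibble of near-complete series (>= 5
#'   participants).
#' @param levels Missingness fractions to calibrate at.
#' @param seed Master seed for the amputation replicates.
#' @param replicates MCAR replicates per participant and level (default 5).
#' @param base_span Span used for the full-data reference NLMD (default
#'   0.33: a neighbourhood of about a third of a year of daily data, wide
#'   enough to leave weekly fluctuation in the residual).
#' @param span_grid Candidate spans searched at each level.
#' @return A [span_rule()] with attribute `"calibration"` holding the
#'   per-level optima. Degenerate searches (flat objective, e.g. constant
#'   series) return [default_span_rule()] with a warning.
#' @export
calibrate_span <- function(cohort, levels = c(0.2, 0.4, 0.6, 0.8), seed = 1,
                           replicates = 5, base_span = 0.33,
                           span_grid = seq(0.2, 0.9, by = 0.05)) {
  pieces <- split_cohort(cohort)
  if (length(pieces) < 5) abort("Calibration needs at least 5 series.")
  levels <- sort(levels)
  seed <- check_count(seed, "seed", min = 0L)
  replicates <- check_count(replicates, "replicates", min = 1L)

  full_vals <- purrr::map_dbl(pieces, function(s) {
    trend <- fit_loess_trend(s, base_span)
    100 * mean(abs(relative_residuals(s, trend)$rel_resid))
  })
  full_mean <- mean(full_vals)
  n_full <- mean(purrr::map_dbl(pieces, n_obs))

  amputed <- purrr::map(seq_along(levels), function(li) {
    purrr::map(seq_along(pieces), function(pi) {
      purrr::map(seq_len(replicates), function(r) {
        ampute_mcar(pieces[[pi]],
                    fraction = levels[li],
                    seed = seed + 7919L * li + 131L * pi + r)
      })
    })
  })

  objective <- function(li, span) {
    vals <- purrr::map(amputed[[li]], function(reps) {
      purrr::map_dbl(reps, function(s) {
        if (floor(span * n_obs(s)) < 4) return(NA_real_)
        trend <- fit_loess_trend(s, span)
        100 * mean(abs(relative_residuals(s, trend)$rel_resid))
      })
    })
    vals <- unlist(vals)
    if (all(is.na(vals))) return(NA_real_)
    abs(mean(vals, na.rm = TRUE) - full_mean)
  }

  opt <- purrr::map_dfr(seq_along(levels), function(li) {
    obj <- purrr::map_dbl(span_grid, ~ objective(li, .x))
    n_level <- mean(purrr::map_dbl(
      purrr::flatten(amputed[[li]]), n_obs
    ))
    if (all(is.na(obj)) || diff(range(obj, na.rm = TRUE)) < 1e-12) {
      return(tibble(level = levels[li], n_obs = n_level, span = NA_real_))
    }
    tibble(level = levels[li], n_obs = n_level,
           span = span_grid[which.min(obj)])
  })

  if (any(is.na(opt$span))) {
    warn("Degenerate span calibration (flat objective); returning the default rule.")
    return(default_span_rule())
  }

  pts <- bind_rows(opt, tibble(level = 0, n_obs = n_full, span = base_span))
  fit <- lm(span ~ n_obs, data = pts)
  slope <- min(unname(coef(fit)[2]), 0)
  intercept <- if (slope == 0) {
    mean(pts$span)
  } else {
    unname(coef(fit)[1])
  }
  rule <- span_rule(
    intercept = intercept, slope = slope,
    span_min = min(span_grid), span_max = max(span_grid)
  )
  attr(rule, "calibration") <- pts
  rule
}
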