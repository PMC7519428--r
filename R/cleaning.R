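#' Physiological plausibility limits for weight data
#'
#' Builds the limit set used by [clean_series()]: absolute bounds on weight
#' and a per-gap bound on the change between successive observations. The
#' default rate bound allows 2 kg of short-term (hydration, gut content,
#' clothing) fluctuation plus 0.35 kg per day of elapsed gap, which covers
#' sustained loss at very-low-calorie-diet rates and gain at intentional
#' overfeeding rates. All limits are configurable.
#'
#' @param abs_min_kg,abs_max_kg Absolute plausible weight range (kg).
#' @param rate_intercept_kg Allowed change irrespective of gap (kg).
#' @param rate_slope_kg_per_day Additional allowed change per day of gap.
#' @param rate_rules Optional tibble (`gap_days`, `max_abs_change_kg`)
#'   overriding the linear rule; must be sorted by `gap_days` with
#'   nondecreasing bounds. Gaps beyond the table use the last entry's
#'   per-day extrapolation.
#' @return An object of class `plausibility_limits`.
#' @export
plausibility_limits <- function(abs_min_kg = 25, abs_max_kg = 250,
                                rate_intercept_kg = 2.0,
                                rate_slope_kg_per_day = 0.35,
                                rate_rules = NULL) {
  check_scalar_number(abs_min_kg, "abs_min_kg", lower = 0, strict = TRUE)
  check_scalar_number(abs_max_kg, "abs_max_kg", lower = abs_min_kg, strict = TRUE)
  if (is.null(rate_rules)) {
    check_scalar_number(rate_intercept_kg, "rate_intercept_kg", lower = 0)
    check_scalar_number(rate_slope_kg_per_day, "rate_slope_kg_per_day", lower = 0)
    max_change <- function(gap) rate_intercept_kg + rate_slope_kg_per_day * gap
  } else {
    rate_rules <- as_tibble(rate_rules)
    if (!all(c("gap_days", "max_abs_change_kg") %in% names(rate_rules)) ||
        nrow(rate_rules) == 0) {
      abort("`rate_rules` needs columns gap_days and max_abs_change_kg.")
    }
    if (is.unsorted(rate_rules$gap_days, strictly = TRUE) ||
        is.unsorted(rate_rules$max_abs_change_kg)) {
      abort("`rate_rules` must be sorted by gap_days with nondecreasing bounds.")
    }
    per_day <- rate_rules$max_abs_change_kg[nrow(rate_rules)] /
      rate_rules$gap_days[nrow(rate_rules)]
    max_change <- function(gap) {
      i <- findInterval(gap, rate_rules$gap_days)
      ifelse(
        gap > max(rate_rules$gap_days),
        rate_rules$max_abs_change_kg[nrow(rate_rules)] +
          per_day * (gap - max(rate_rules$gap_days)),
        rate_rules$max_abs_change_kg[pmax(i, 1L)]
      )
    }
  }
  structure(
    list(
      abs_min_kg = abs_min_kg, abs_max_kg = abs_max_kg,
      rate_rules = rate_rules,
      rate_intercept_kg = if (is.null(rate_rules)) rate_intercept_kg else NA_real_,
      rate_slope_kg_per_day = if (is.null(rate_rules)) rate_slope_kg_per_day else NA_real_,
      max_change = max_change
    ),
    class = "plausibility_limits"
  )
}

#' @export
print.plausibility_limits <- function(x, ...) {
  cat(sprintf(
    "Plausibility limits: weight in [%g, %g] kg; max |change| over gap g = %s\n",
    x$abs_min_kg, x$abs_max_kg,
    if (is.null(x$rate_rules)) {
      sprintf("%g + %g*g kg", x$rate_intercept_kg, x$rate_slope_kg_per_day)
    } else {
      "tabulated rule"
    }
  ))
  invisible(x)
}

#' Remove physiologically implausible weight values
#'
#' Sets implausible values to missing (the daily grid is unchanged, values
#' are never altered). A value is removed when it lies outside the absolute
#' bounds, or when it violates the per-gap rate bound against *both* its
#' previous and next retained observations (against its single neighbour at
#' the series edges) -- a lone spike, not the surrounding trend, is treated
#' as the implausible datum. Removal is iterative, dropping the worst
#' offender and rechecking until a fixed point, so cleaning is idempotent.
#'
#' @param series A single-participant weight-series tibble.
#' @param limits A [plausibility_limits()] object.
#' @return The cleaned series tibble, with a `"cleaning_report"` attribute
#'   (see [cleaning_report()]) recording removed day indices and reasons
#'   (`"absolute-bound"` or `"rate-bound"`).
#' @export
#' @examples
#' s <- to_daily_grid(data.frame(
#'   participant_id = "p1",
#'   date = as.Date("2023-01-01") + 0:3,
#'   weight_kg = c(80, 80, 90, 80)
#' ))
#' cleaned <- clean_series(s, plausibility_limits(rate_intercept_kg = 3,
#'                                                rate_slope_kg_per_day = 0))
#' cleaning_report(cleaned)
clean_series <- function(series, limits = plausibility_limits()) {
  check_single_series(series, min_obs = 1L)
  if (!inherits(limits, "plausibility_limits")) {
    abort("`limits` must be a plausibility_limits object.")
  }
  w <- series$weight
  removed_idx <- integer(0)
  removed_reason <- character(0)

  # absolute bounds first: unconditional
  abs_bad <- which(!is.na(w) & (w < limits$abs_min_kg | w > limits$abs_max_kg))
  if (length(abs_bad) > 0) {
    removed_idx <- c(removed_idx, abs_bad)
    removed_reason <- c(removed_reason, rep("absolute-bound", length(abs_bad)))
    w[abs_bad] <- NA_real_
  }

  repeat {
    obs <- which(!is.na(w))
    if (length(obs) < 2) break
    gaps <- diff(obs)
    dw <- abs(diff(w[obs]))
    viol <- dw > limits$max_change(gaps) # between obs[i] and obs[i+1]
    m <- length(obs)
    # excess over the bound on each side of every observation
    excess_prev <- c(NA, ifelse(viol, dw - limits$max_change(gaps), 0))
    excess_next <- c(ifelse(viol, dw - limits$max_change(gaps), 0), NA)
    bad_both <- rep(FALSE, m)
    score <- rep(0, m)
    for (i in seq_len(m)) {
      ep <- excess_prev[i]
      en <- excess_next[i]
      if (i == 1) {
        bad_both[i] <- !is.na(en) && en > 0
        score[i] <- if (bad_both[i]) en else 0
      } else if (i == m) {
        bad_both[i] <- !is.na(ep) && ep > 0
        score[i] <- if (bad_both[i]) ep else 0
      } else {
        bad_both[i] <- ep > 0 && en > 0
        score[i] <- if (bad_both[i]) ep + en else 0
      }
    }
    if (!any(bad_both)) break
    worst <- obs[which.max(score)]
    removed_idx <- c(removed_idx, worst)
    removed_reason <- c(removed_reason, "rate-bound")
    w[worst] <- NA_real_
  }

  if (sum(!is.na(w)) < 2) {
    abort("Cleaning left fewer than 2 observations.")
  }
  ord <- order(removed_idx)
  out <- series
  out$weight <- w
  attr(out, "cleaning_report") <- tibble(
    n_removed = length(removed_idx),
    removed = list(tibble(
      day = series$day[removed_idx[ord]],
      weight = series$weight[removed_idx[ord]],
      reason = removed_reason[ord]
    ))
  )
  out
}

#' Cleaning report of a cleaned series
#'
#' @param x A series returned by [clean_series()].
#' @return One-row tibble: `n_removed` and a list-column `removed` of
#'   per-removal day, value and reason.
#' @export
cleaning_report <- function(x) {
  rep <- attr(x, "cleaning_report")
  if (is.null(rep)) abort("`x` carries no cleaning report.")
  rep
}
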