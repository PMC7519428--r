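# Internal validation helpers shared across modules.

# Checks the weight-series contract: required columns, consecutive daily
# grid per participant, positive weights. Returns the tibble invisibly.
check_series <- function(series, min_obs = 0L, arg = "series") {
  if (!is.data.frame(series)) {
    abort(sprintf("`%s` must be a data frame (weight-series tibble).", arg))
  }
  needed <- c("participant_id", "date", "day", "weight")
  missing_cols <- setdiff(needed, names(series))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s.",
      arg, paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(series) == 0) abort(sprintf("`%s` has zero rows.", arg))
  split <- split(seq_len(nrow(series)), series$participant_id)
  for (idx in split) {
    d <- series$day[idx]
    if (any(diff(d) != 1L)) {
      abort(sprintf("`%s`: days must be consecutive and unique per participant.", arg))
    }
    dt <- series$date[idx]
    if (any(as.integer(diff(dt)) != 1L)) {
      abort(sprintf("`%s`: dates must be consecutive per participant.", arg))
    }
  }
  w <- series$weight
  if (any(!is.na(w) & w <= 0)) {
    abort(sprintf("`%s`: weights must be positive.", arg))
  }
  if (min_obs > 0 && sum(!is.na(w)) < min_obs) {
    abort(sprintf(
      "`%s` has %d observed value(s); at least %d are required.",
      arg, sum(!is.na(w)), min_obs
    ))
  }
  invisible(series)
}

# One participant only (most low-level operations).
check_single_series <- function(series, min_obs = 0L, arg = "series") {
  check_series(series, min_obs = min_obs, arg = arg)
  if (length(unique(series$participant_id)) != 1L) {
    abort(sprintf("`%s` must contain a single participant.", arg))
  }
  invisible(series)
}

n_obs <- function(series) sum(!is.na(series$weight))

check_scalar_number <- function(x, arg, lower = -Inf, upper = Inf,
                                strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower && x < upper else x >= lower && x <= upper)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single finite number in %s%s, %s%s.",
      arg, if (strict) "(" else "[", format(lower), format(upper),
      if (strict) ")" else "]"
    ))
  }
  invisible(x)
}

check_count <- function(x, arg, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) abort(sprintf("`%s` must be an integer >= %d.", arg, min))
  invisible(as.integer(x))
}

# ISO day of week, 1 = Monday ... 7 = Sunday.
iso_dow <- function(date) {
  dow <- as.integer(format(date, "%u"))
  dow
}

# Evaluate seeded code without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}
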