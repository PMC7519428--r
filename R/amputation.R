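#' Remove observed values completely at random (MCAR)
#'
#' Simulates missingness by deleting exactly `round(fraction * n_obs)`
#' currently observed values (round-half-to-even), chosen uniformly without
#' replacement. The fraction applies to observed measurements, not to the
#' grid length, mirroring removal of a share of the available data points.
#'
#' @param series A single-participant weight-series tibble with >= 2
#'   observed values.
#' @param fraction Fraction of observed values to remove, in (0, 1).
#' @param seed Integer seed; the same seed reproduces the same removal.
#' @return The amputed series tibble. The realized pattern is recoverable
#'   with [missingness_mask()].
#' @export
ampute_mcar <- function(series, fraction, seed) {
  check_single_series(series, min_obs = 2L)
  check_scalar_number(fraction, "fraction", lower = 0, upper = 1, strict = TRUE)
  obs <- which(!is.na(series$weight))
  n_remove <- round(fraction * length(obs))
  if (length(obs) - n_remove < 2) {
    abort("Amputation would leave fewer than 2 observations.")
  }
  out <- series
  if (n_remove > 0) {
    drop <- with_seed(seed, sample(obs, n_remove))
    out$weight[drop] <- NA_real_
  }
  out
}

#' Impose a donor pattern of missingness (RPM)
#'
#' Transfers an empirically observed (typically bursty) missingness pattern
#' onto a target series: wherever the donor mask is missing, the target day
#' becomes missing. Donor masks shorter or longer than the target are
#' recycled from their start, preserving the run-length structure of real
#' missingness. An optional seed rotates the donor by a random circular
#' offset so replicates draw different alignments of the same pattern.
#'
#' @param series A single-participant weight-series tibble.
#' @param donor A missingness-mask tibble (`day`, `observed`), e.g. from
#'   [missingness_mask()] or [generate_rpm_donor()].
#' @param seed Optional integer seed for the circular offset; `NULL` (the
#'   default) applies the donor unrotated.
#' @return The amputed series tibble.
#' @export
ampute_rpm <- function(series, donor, seed = NULL) {
  check_single_series(series, min_obs = 2L)
  if (!is.data.frame(donor) || !all(c("day", "observed") %in% names(donor)) ||
      nrow(donor) == 0) {
    abort("`donor` must be a mask tibble with columns day and observed.")
  }
  pattern <- as.logical(donor$observed)
  if (!any(pattern)) abort("Donor mask is entirely missing.")
  if (!is.null(seed)) {
    offset <- with_seed(seed, sample.int(length(pattern), 1L)) - 1L
    if (offset > 0) {
      pattern <- c(pattern[-seq_len(offset)], pattern[seq_len(offset)])
    }
  }
  keep <- pattern[((seq_len(nrow(series)) - 1L) %% length(pattern)) + 1L]
  out <- series
  out$weight[!keep] <- NA_real_
  if (sum(!is.na(out$weight)) < 2) {
    abort("Amputation would leave fewer than 2 observations.")
  }
  out
}

#' Observed/missing mask of a weight series
#'
#' @param series A single-participant weight-series tibble.
#' @return A tibble (`day`, `observed`) with attribute `"missing_fraction"`;
#'   see [missing_fraction()].
#' @export
missingness_mask <- function(series) {
  check_single_series(series)
  mask <- tibble(day = series$day, observed = !is.na(series$weight))
  attr(mask, "missing_fraction") <- 1 - mean(mask$observed)
  mask
}

#' Missing fraction of a mask or series
#'
#' @param x A mask tibble (`day`, `observed`) or a weight-series tibble.
#' @return The fraction of days without an observation, in \[0, 1\].
#' @export
missing_fraction <- function(x) {
  if (all(c("day", "observed") %in% names(x))) {
    1 - mean(as.logical(x$observed))
  } else {
    1 - mean(!is.na(x$weight))
  }
}
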