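#' Tidy a fitted trend
#'
#' @param x A `bwv_trend` object.
#' @param ... Unused.
#' @return A tibble with one row per observed day: `day`, `weight`, `trend`,
#'   `resid` and `rel_resid`.
#' @export
tidy.bwv_trend <- function(x, ...) {
  mutate(
    x$data,
    resid = .data$weight - .data$trend,
    rel_resid = (.data$weight - .data$trend) / .data$weight
  )
}

#' One-row summary of a fitted trend
#'
#' @param x A `bwv_trend` object.
#' @param ... Unused.
#' @return A one-row tibble: `kind`, `span`, `degree`, `n_obs`,
#'   `resid_rmse_kg`.
#' @export
glance.bwv_trend <- function(x, ...) {
  tibble(
    kind = x$kind,
    span = x$span,
    degree = x$degree,
    n_obs = nrow(x$data),
    resid_rmse_kg = sqrt(mean((x$data$weight - x$data$trend)^2))
  )
}

#' Tidy experiment results
#'
#' @param x A `bwv_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return The per-dataset result rows: imputation scores and BWV errors
#'   (where imputation methods were configured) stacked with the
#'   missing-only BWV error rows, distinguished by the `kind` column.
#' @export
tidy.bwv_experiment <- function(x, ...) {
  bind_rows(
    if (nrow(x$results) > 0) mutate(x$results, kind = "imputed"),
    mutate(x$missing_only, kind = "missing-only")
  )
}

#' One-row summary of an experiment
#'
#' @param x A `bwv_experiment`.
#' @param ... Unused.
#' @return A one-row tibble of design counts.
#' @export
glance.bwv_experiment <- function(x, ...) {
  tibble(
    n_levels = length(x$config$levels),
    n_mechanisms = length(x$config$mechanisms),
    n_methods = length(x$config$methods),
    replicates = x$config$replicates,
    n_imputed_datasets = nrow(x$results),
    n_missing_only_datasets = nrow(x$missing_only)
  )
}
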