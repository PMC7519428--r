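#' Score an imputation against known truth
#'
#' Evaluated only at positions that were amputed -- days where the truth is
#' known and the value was imputed -- so scores are comparable across
#' missingness levels instead of being diluted by the observed fraction.
#' Relative errors drive the headline percent-scale RMSE and MAPE; MAE is
#' additionally reported in kg.
#'
#' @param truth The complete (pre-amputation) single-participant series.
#' @param imputed An imputed series from [impute_series()] (must carry the
#'   `imputed` flag column) on the same grid.
#' @return One-row tibble: `method`, `rmse_pct`, `mae_kg`, `mape_pct`,
#'   `n_eval`.
#' @export
imputation_error <- function(truth, imputed) {
  check_single_series(truth)
  if (!("imputed" %in% names(imputed))) {
    abort("`imputed` must carry the `imputed` flag column.")
  }
  check_single_series(imputed)
  if (nrow(truth) != nrow(imputed) || !identical(truth$day, imputed$day)) {
    abort("`truth` and `imputed` must share the same daily grid.")
  }
  eval_at <- which(imputed$imputed & !is.na(truth$weight))
  if (length(eval_at) == 0) {
    abort("No imputed position has a known true value to score against.")
  }
  e_abs <- imputed$weight[eval_at] - truth$weight[eval_at]
  e_rel <- e_abs / truth$weight[eval_at]
  tibble(
    method = attr(imputed, "method") %||% NA_character_,
    rmse_pct = 100 * sqrt(mean(e_rel^2)),
    mae_kg = mean(abs(e_abs)),
    mape_pct = 100 * mean(abs(e_rel)),
    n_eval = length(eval_at)
  )
}

#' Signed disagreement between two BWV estimates
#'
#' @param truth A one-row BWV estimate tibble computed on the full data
#'   (`value_pct` > 0).
#' @param estimate A one-row BWV estimate tibble of the same method computed
#'   on amputed or imputed data.
#' @return One-row tibble with `method` and `signed_error_pct` =
#'   `100 * (estimate - truth) / truth`; negative means underestimation.
#' @export
bwv_disagreement <- function(truth, estimate) {
  for (x in list(truth, estimate)) {
    if (!is.data.frame(x) || nrow(x) != 1 ||
        !all(c("method", "value_pct") %in% names(x))) {
      abort("BWV estimates must be one-row tibbles with method and value_pct.")
    }
  }
  if (truth$method != estimate$method) {
    abort("BWV estimates must come from the same method.")
  }
  if (truth$value_pct <= 0) {
    abort("True BWV is zero; relative disagreement is undefined.")
  }
  tibble(
    method = truth$method,
    signed_error_pct = 100 * (estimate$value_pct - truth$value_pct) / truth$value_pct
  )
}
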