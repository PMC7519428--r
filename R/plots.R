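#' Plot a weight series with its fitted trend
#'
#' @param object A `bwv_trend` object.
#' @param ... Unused.
#' @return A ggplot: observed weights and the fitted trend line.
#' @export
autoplot.bwv_trend <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$weight),
                        alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend),
                       colour = "#d55e00", linewidth = 0.9) +
    ggplot2::labs(
      x = "Day", y = "Weight (kg)",
      title = sprintf(
        "%s trend%s", tools::toTitleCase(object$kind),
        if (object$kind == "loess") sprintf(" (span %.2f)", object$span) else ""
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an imputed series against the observed values
#'
#' @param imputed A series from [impute_series()].
#' @param truth Optional complete series to overlay as ground truth.
#' @return A ggplot distinguishing observed and imputed days.
#' @export
plot_imputation <- function(imputed, truth = NULL) {
  if (!("imputed" %in% names(imputed))) {
    abort("`imputed` must carry the `imputed` flag column.")
  }
  d <- mutate(imputed,
              status = ifelse(.data$imputed, "imputed", "observed"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$weight)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 0.9) +
    ggplot2::scale_colour_manual(
      values = c(observed = "grey30", imputed = "#0072b2"), name = NULL
    ) +
    ggplot2::labs(
      x = "Day", y = "Weight (kg)",
      title = sprintf("Imputation: %s", attr(imputed, "method") %||% "?")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_line(
      data = truth, ggplot2::aes(x = .data$day, y = .data$weight),
      colour = "grey70", linewidth = 0.3, na.rm = TRUE
    )
  }
  p
}

#' Plot experiment error distributions
#'
#' Boxplots of per-dataset errors by method and missingness level, in the
#' style of simulation-validation summaries: imputation RMSE (`what =
#' "imputation"`) or BWV estimation error for either estimator.
#'
#' @param object A `bwv_experiment`.
#' @param what `"imputation"`, `"bwv_rmse"`, or `"bwv_nlmd"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bwv_experiment <- function(object,
                                    what = c("imputation", "bwv_rmse", "bwv_nlmd"),
                                    ...) {
  what <- match.arg(what)
  if (nrow(object$results) == 0) {
    abort("Experiment was run without imputation methods; nothing to plot.")
  }
  d <- object$results
  yvar <- switch(what,
                 imputation = "rmse_pct",
                 bwv_rmse = "bwv_error_rmse_pct",
                 bwv_nlmd = "bwv_error_nlmd_pct")
  ylab <- switch(what,
                 imputation = "Imputation RMSE (% of body weight)",
                 bwv_rmse = "Linear BWV signed error (%)",
                 bwv_nlmd = "NLMD signed error (%)")
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = factor(.data$level), y = .data[[yvar]],
                 fill = .data$mechanism)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "Missing fraction", y = ylab, fill = "Mechanism") +
    ggplot2::theme_minimal()
}
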