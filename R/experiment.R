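#' Configuration of the amputation-imputation validation experiment
#'
#' @param levels Missingness fractions (default 0.2, 0.4, 0.6, 0.8).
#' @param mechanisms Amputation mechanisms: `"mcar"` and/or `"rpm"`.
#' @param replicates Amputation replicates per participant and level
#'   (default 20, the full design; the scaled preset uses 5).
#' @param methods Imputation methods to evaluate (subset of
#'   [imputation_methods()]; empty to skip imputation and study missing-data
#'   BWV only).
#' @param seed Master seed.
#' @param scaled If `TRUE`, shrink to the scaled preset: `replicates = 5`
#'   and the first 10 participants of the cohort.
#' @param rule Span rule used for every NLMD estimate.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(levels = c(0.2, 0.4, 0.6, 0.8),
                              mechanisms = c("mcar", "rpm"),
                              replicates = 20,
                              methods = imputation_methods(),
                              seed = 1,
                              scaled = FALSE,
                              rule = default_span_rule()) {
  if (!is.numeric(levels) || length(levels) == 0 ||
      any(levels <= 0 | levels >= 1)) {
    abort("`levels` must be fractions in (0, 1).")
  }
  mechanisms <- match.arg(mechanisms, c("mcar", "rpm"), several.ok = TRUE)
  replicates <- check_count(replicates, "replicates", min = 1L)
  if (length(methods) > 0) {
    methods <- match.arg(methods, imputation_methods(), several.ok = TRUE)
  }
  seed <- check_count(seed, "seed", min = 0L)
  if (isTRUE(scaled)) replicates <- min(replicates, 5L)
  structure(
    list(
      levels = sort(levels), mechanisms = mechanisms,
      replicates = replicates, methods = methods, seed = seed,
      scaled = isTRUE(scaled), rule = rule
    ),
    class = "experiment_config"
  )
}

#' Run the amputation-imputation validation experiment
#'
#' For every participant x mechanism x level x replicate the cohort series
#' is amputed; each configured imputation method is scored against the
#' known values at the amputed positions; and both BWV statistics are
#' computed on the amputed (missing-data) series and on every imputed
#' series, then compared with the full-data estimates. Fully seeded.
#'
#' @param cohort A cleaned weight-series tibble (several participants).
#' @param config An [experiment_config()].
#' @param progress Emit per-stage progress messages (default `FALSE`).
#' @return A `bwv_experiment` object with components `results` (one row per
#'   evaluated dataset x method), `missing_only` (per-dataset BWV errors
#'   without imputation), and summary tables `imputation_summary`,
#'   `missing_only_summary`, `missing_only_pooled` (mechanisms combined).
#'   Access tidy rows with [tidy.bwv_experiment()].
#' @export
run_experiment <- function(cohort, config = experiment_config(),
                           progress = FALSE) {
  if (!inherits(config, "experiment_config")) {
    abort("`config` must come from experiment_config().")
  }
  pieces <- split_cohort(cohort)
  if (config$scaled) pieces <- pieces[seq_len(min(10, length(pieces)))]
  say <- function(...) if (progress) message(sprintf(...))

  # full-data reference estimates per participant
  full_est <- purrr::map(pieces, function(s) {
    list(rmse = bwv_rmse(s), nlmd = bwv_nlmd(s, rule = config$rule))
  })

  grid <- tidyr::expand_grid(
    participant = names(pieces),
    mechanism = config$mechanisms,
    level = config$levels,
    replicate = seq_len(config$replicates)
  )
  say("Evaluating %d amputed datasets", nrow(grid))

  eval_one <- function(participant, mechanism, level, replicate) {
    s <- pieces[[participant]]
    ds_seed <- config$seed +
      17L * match(participant, names(pieces)) +
      1009L * match(mechanism, c("mcar", "rpm")) +
      4057L * match(level, config$levels) +
      31L * replicate
    amp <- tryCatch(
      if (mechanism == "mcar") {
        ampute_mcar(s, fraction = level, seed = ds_seed)
      } else {
        donor <- generate_rpm_donor(
          n_days = nrow(s),
          fraction = level,
          seed = ds_seed + 1L
        )
        amp_try <- ampute_rpm(s, donor, seed = ds_seed + 2L)
        # bin realized fraction to the nominal level (+/- 5 points)
        realized <- 1 - n_obs(amp_try) / n_obs(s)
        tries <- 0
        while (abs(realized - level) > 0.05 && tries < 20) {
          tries <- tries + 1
          donor <- generate_rpm_donor(nrow(s), level, seed = ds_seed + 2L + tries)
          amp_try <- ampute_rpm(s, donor, seed = ds_seed + 100L + tries)
          realized <- 1 - n_obs(amp_try) / n_obs(s)
        }
        amp_try
      },
      error = function(e) NULL
    )
    if (is.null(amp)) {
      warn(sprintf("Skipping %s %s level %.2f rep %d: amputation failed.",
                   participant, mechanism, level, replicate))
      return(NULL)
    }

    base_row <- tibble(
      participant_id = participant, mechanism = mechanism,
      level = level, replicate = replicate
    )
    missing_only <- purrr::map_dfr(c("rmse", "nlmd"), function(est) {
      val <- tryCatch(
        if (est == "rmse") bwv_rmse(amp) else bwv_nlmd(amp, rule = config$rule),
        error = function(e) NULL
      )
      if (is.null(val)) return(NULL)
      mutate(base_row, estimator = est,
             signed_error_pct = bwv_disagreement(full_est[[participant]][[est]],
                                                 val)$signed_error_pct)
    })

    per_method <- purrr::map_dfr(config$methods, function(m) {
      imp <- tryCatch(
        impute_series(amp, method = m, seed = ds_seed + 3L),
        error = function(e) NULL
      )
      if (is.null(imp)) {
        warn(sprintf("Method %s failed on %s %s level %.2f rep %d.",
                     m, participant, mechanism, level, replicate))
        return(NULL)
      }
      score <- imputation_error(s, imp)
      bwv_err <- purrr::map_dbl(c("rmse", "nlmd"), function(est) {
        val <- tryCatch(
          if (est == "rmse") bwv_rmse(imp[names(imp) != "imputed"]) else
            bwv_nlmd(imp[names(imp) != "imputed"], rule = config$rule),
          error = function(e) NULL
        )
        if (is.null(val)) return(NA_real_)
        bwv_disagreement(full_est[[participant]][[est]], val)$signed_error_pct
      })
      mutate(base_row,
             method = m,
             rmse_pct = score$rmse_pct, mae_kg = score$mae_kg,
             mape_pct = score$mape_pct, n_eval = score$n_eval,
             bwv_error_rmse_pct = bwv_err[1],
             bwv_error_nlmd_pct = bwv_err[2])
    })
    list(missing_only = missing_only, results = per_method)
  }

  pieces_out <- purrr::pmap(grid, eval_one)
  pieces_out <- purrr::compact(pieces_out)
  if (length(pieces_out) == 0) abort("Every dataset failed preconditions.")
  missing_only <- purrr::map_dfr(pieces_out, "missing_only")
  results <- purrr::map_dfr(pieces_out, "results")
  say("Aggregating")

  msd <- function(x) list(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE))
  imputation_summary <- if (nrow(results) > 0) {
    results %>%
      group_by(.data$method, .data$mechanism, .data$level) %>%
      summarise(
        n_datasets = n(),
        mean_rmse_pct = mean(.data$rmse_pct), sd_rmse_pct = sd(.data$rmse_pct),
        mean_mae_kg = mean(.data$mae_kg), sd_mae_kg = sd(.data$mae_kg),
        mean_mape_pct = mean(.data$mape_pct), sd_mape_pct = sd(.data$mape_pct),
        mean_bwv_error_rmse_pct = mean(.data$bwv_error_rmse_pct, na.rm = TRUE),
        sd_bwv_error_rmse_pct = sd(.data$bwv_error_rmse_pct, na.rm = TRUE),
        mean_bwv_error_nlmd_pct = mean(.data$bwv_error_nlmd_pct, na.rm = TRUE),
        sd_bwv_error_nlmd_pct = sd(.data$bwv_error_nlmd_pct, na.rm = TRUE),
        .groups = "drop"
      )
  } else {
    tibble()
  }
  missing_only_summary <- missing_only %>%
    group_by(.data$mechanism, .data$level, .data$estimator) %>%
    summarise(
      n_datasets = n(),
      mean_signed_error_pct = mean(.data$signed_error_pct),
      sd_signed_error_pct = sd(.data$signed_error_pct),
      .groups = "drop"
    )
  missing_only_pooled <- missing_only %>%
    group_by(.data$level, .data$estimator) %>%
    summarise(
      n_datasets = n(),
      mean_signed_error_pct = mean(.data$signed_error_pct),
      sd_signed_error_pct = sd(.data$signed_error_pct),
      .groups = "drop"
    )

  structure(
    list(
      config = config,
      results = results,
      missing_only = missing_only,
      imputation_summary = imputation_summary,
      missing_only_summary = missing_only_summary,
      missing_only_pooled = missing_only_pooled
    ),
    class = "bwv_experiment"
  )
}

#' @export
print.bwv_experiment <- function(x, ...) {
  cat(sprintf(
    "<bwv_experiment> %d imputed-dataset rows, %d missing-only rows\n",
    nrow(x$results), nrow(x$missing_only)
  ))
  cat("Summary tables: imputation_summary, missing_only_summary, missing_only_pooled\n")
  invisible(x)
}
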