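#' Read smart-scale weight records from CSV
#'
#' Reads a long CSV of weigh-ins (`participant_id,date,weight_kg`; ISO-8601
#' dates) and regularizes each participant onto a consecutive daily grid.
#' Same-day repeat weigh-ins are averaged. Rows with unparseable dates or
#' non-positive/unparseable weights are dropped and listed in the parse
#' report attached as the `"parse_report"` attribute (see [parse_report()]).
#'
#' @param path Path to a CSV file with columns `participant_id`, `date`,
#'   `weight_kg`.
#' @return A weight-series tibble (`participant_id`, `date`, `day`,
#'   `weight`), one daily-grid block per participant, sorted by participant
#'   and date. Days with no measurement carry `NA` weight.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "participant_id,date,weight_kg",
#'   "p1,2023-01-01,80", "p1,2023-01-03,81"
#' ), f)
#' read_weights_csv(f)
read_weights_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  needed <- c("participant_id", "date", "weight_kg")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Input CSV is missing column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  n_total <- nrow(raw)
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  weight <- suppressWarnings(as.numeric(raw$weight_kg))
  bad_date <- is.na(date)
  bad_weight <- !bad_date & (is.na(weight) | weight <= 0)
  bad <- bad_date | bad_weight
  report <- tibble(
    row = which(bad),
    reason = c("unparseable-date", "invalid-weight")[
      ifelse(bad_date[bad], 1L, 2L)
    ]
  )
  records <- tibble(
    participant_id = as.character(raw$participant_id),
    date = date,
    weight_kg = weight
  )[!bad, ]
  if (nrow(records) == 0) abort("No valid weight records in input.")

  out <- records %>%
    group_by(.data$participant_id) %>%
    group_split() %>%
    purrr::map(to_daily_grid) %>%
    bind_rows()
  attr(out, "parse_report") <- tibble(
    n_rows = n_total,
    n_valid = nrow(records),
    n_dropped = sum(bad),
    dropped = list(report)
  )
  out
}

#' Parse report of a CSV read
#'
#' @param x A weight-series tibble returned by [read_weights_csv()].
#' @return A one-row tibble with counts of total, valid and dropped rows and
#'   a list-column of per-row drop reasons.
#' @export
parse_report <- function(x) {
  rep <- attr(x, "parse_report")
  if (is.null(rep)) abort("`x` carries no parse report.")
  rep
}

#' Regularize weigh-in records onto a daily grid
#'
#' Expands irregular records for one participant to a consecutive daily grid
#' spanning the first to the last observed date; unobserved days get `NA`.
#' Same-day duplicates are averaged (order-independent).
#'
#' @param records A data frame with columns `participant_id`, `date` (Date),
#'   `weight_kg` for a single participant.
#' @return A weight-series tibble.
#' @export
to_daily_grid <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a non-empty data frame.")
  }
  needed <- c("participant_id", "date", "weight_kg")
  if (length(setdiff(needed, names(records))) > 0) {
    abort("`records` must have columns participant_id, date, weight_kg.")
  }
  if (length(unique(records$participant_id)) != 1L) {
    abort("`records` must contain a single participant.")
  }
  if (any(is.na(records$date)) || any(is.na(records$weight_kg)) ||
      any(records$weight_kg <= 0)) {
    abort("`records` must have valid dates and positive weights.")
  }
  daily <- records %>%
    group_by(.data$date) %>%
    summarise(weight = mean(.data$weight_kg), .groups = "drop")
  grid_dates <- seq(min(daily$date), max(daily$date), by = "day")
  tibble(
    participant_id = records$participant_id[1],
    date = grid_dates,
    day = seq_along(grid_dates),
    weight = daily$weight[match(grid_dates, daily$date)]
  )
}

#' Write a weight series back to CSV
#'
#' Writes the observed rows (missing days omitted) in the same dialect read
#' by [read_weights_csv()], so write-then-read round-trips.
#'
#' @param series A weight-series tibble (one or more participants).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  check_series(series)
  obs <- series %>% filter(!is.na(.data$weight))
  if (nrow(obs) == 0) abort("Series has no observed values to write.")
  out <- tibble(
    participant_id = obs$participant_id,
    date = format(obs$date, "%Y-%m-%d"),
    weight_kg = obs$weight
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split a cohort tibble into single-participant series
#'
#' @param cohort A weight-series tibble with one or more participants.
#' @return A named list of single-participant weight-series tibbles.
#' @export
split_cohort <- function(cohort) {
  check_series(cohort)
  pieces <- cohort %>%
    group_by(.data$participant_id) %>%
    group_split()
  names(pieces) <- purrr::map_chr(pieces, ~ .x$participant_id[1])
  pieces
}
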