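# Fixture builders shared across the suite. All series start on a Monday
# (2023-01-02) unless stated, so ISO day-of-week is predictable.

make_series <- function(weights, id = "p1", start = as.Date("2023-01-02")) {
  n <- length(weights)
  tibble::tibble(
    participant_id = id,
    date = start + seq_len(n) - 1,
    day = seq_len(n),
    weight = as.numeric(weights)
  )
}

# Affine series with optional gaps (positions set to NA).
affine_series <- function(n, intercept = 80, slope = 0.05, gaps = integer(0)) {
  w <- intercept + slope * seq_len(n)
  w[gaps] <- NA_real_
  make_series(w)
}

# Noisy series around a constant, seeded.
noisy_series <- function(n, level = 80, sd = 0.4, seed = 1, gaps = integer(0)) {
  set.seed(seed)
  w <- level + rnorm(n, 0, sd)
  w[gaps] <- NA_real_
  make_series(w)
}

expect_imputation_contract <- function(imp, src) {
  expect_false(any(is.na(imp$weight)))
  expect_true("imputed" %in% names(imp))
  obs <- !is.na(src$weight)
  expect_identical(imp$weight[obs], src$weight[obs])
  expect_identical(imp$imputed, !obs)
}
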