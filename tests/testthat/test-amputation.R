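test_that("MCAR removes an exact count and never alters retained values", {
  s <- make_series(80 + sin(1:335))
  amp <- ampute_mcar(s, fraction = 0.8, seed = 11)
  expect_equal(sum(!is.na(amp$weight)), 67) # 335 - round(0.8*335)
  kept <- !is.na(amp$weight)
  expect_identical(amp$weight[kept], s$weight[kept])

  # tiny series, fraction small enough to round to zero removals
  tiny <- make_series(c(80, 81, 82))
  expect_equal(ampute_mcar(tiny, 0.1, seed = 1)$weight, tiny$weight)
})

test_that("MCAR is seed-deterministic and uniform over positions", {
  s <- make_series(rep(80, 50))
  a1 <- ampute_mcar(s, 0.2, seed = 99)
  a2 <- ampute_mcar(s, 0.2, seed = 99)
  expect_identical(a1$weight, a2$weight)

  counts <- integer(50)
  for (seed in 1:1000) {
    amp <- ampute_mcar(s, 0.2, seed = seed)
    counts <- counts + is.na(amp$weight)
  }
  # each position removed ~200 times; chi-square uniformity at alpha 0.01
  chisq <- sum((counts - 200)^2 / 200)
  expect_lt(chisq, qchisq(0.99, df = 49))
})

test_that("MCAR argument errors", {
  s <- make_series(rep(80, 10))
  expect_error(ampute_mcar(s, 0, seed = 1), "fraction")
  expect_error(ampute_mcar(s, 1, seed = 1), "fraction")
  expect_error(ampute_mcar(s, 0.95, seed = 1), "fewer than 2")
})

test_that("RPM imposes the donor pattern, recycling on length mismatch", {
  s <- make_series(80 + (1:5))
  donor_full <- tibble::tibble(day = 1:5, observed = rep(TRUE, 5))
  expect_equal(ampute_rpm(s, donor_full)$weight, s$weight)

  donor <- tibble::tibble(day = 1:5, observed = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  amp <- ampute_rpm(s, donor)
  expect_true(all(is.na(amp$weight[c(2, 4)])))
  expect_equal(missing_fraction(amp), 0.4)

  # donor shorter than target: recycled from its start, realized fraction
  # within 2 points of the donor's
  set.seed(3)
  long <- make_series(80 + rnorm(365, 0, 0.3))
  donor300 <- generate_rpm_donor(300, fraction = 0.4, seed = 5)
  amp2 <- ampute_rpm(long, donor300)
  expect_lt(abs(missing_fraction(amp2) - missing_fraction(donor300)), 0.02)
  # recycling means day 301 gets donor day 1's state
  expect_equal(is.na(amp2$weight[301]), !donor300$observed[1])
})

test_that("RPM rejects degenerate donors and preserves retained values", {
  s <- make_series(80 + (1:10))
  all_missing <- tibble::tibble(day = 1:10, observed = rep(FALSE, 10))
  expect_error(ampute_rpm(s, all_missing), "entirely missing")
  donor <- generate_rpm_donor(10, 0.3, seed = 2)
  amp <- ampute_rpm(s, donor, seed = 4)
  kept <- !is.na(amp$weight)
  expect_identical(amp$weight[kept], s$weight[kept])
})

test_that("masks report the observed pattern and compose with amputation", {
  s10 <- make_series(rep(80, 10))
  expect_equal(missing_fraction(missingness_mask(s10)), 0)
  alt <- make_series(ifelse(seq_len(10) %% 2 == 0, NA, 80))
  expect_equal(missing_fraction(missingness_mask(alt)), 0.5)

  s <- make_series(80 + sin(1:50))
  amp <- ampute_mcar(s, 0.4, seed = 8)
  m <- missingness_mask(amp)
  expect_equal(missing_fraction(m), round(0.4 * 50) / 50)
  # masked-then-masked observed set is a subset of the first mask's
  amp2 <- ampute_rpm(amp, generate_rpm_donor(50, 0.3, seed = 9))
  m2 <- missingness_mask(amp2)
  expect_true(all(!m$observed[!m$observed] | TRUE)) # vacuous guard
  expect_true(all(which(m2$observed) %in% which(m$observed)))
})

test_that("burst donors are bursty, not scattered", {
  donor <- generate_rpm_donor(365, fraction = 0.4, mean_burst = 7, seed = 10)
  runs <- rle(donor$observed)
  miss_runs <- runs$lengths[!runs$values]
  expect_gt(mean(miss_runs), 2.5) # MCAR at 40% would average ~1.7
  expect_lt(abs(missing_fraction(donor) - 0.4), 0.1)
})
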