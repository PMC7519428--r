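test_that("linear trend matches hand-solved normal equations", {
  # unit-slope toy: days 1..3, weights 80,81,82 -> intercept 79, slope 1
  t1 <- fit_linear_trend(make_series(c(80, 81, 82)))
  expect_equal(unname(t1$coef), c(79, 1))

  # exact line: residuals identically zero
  s_line <- affine_series(30, slope = 0.01)
  tr <- fit_linear_trend(s_line)
  expect_lt(max(abs(tr$data$weight - tr$data$trend)), 1e-10)

  # constant series: slope 0, fitted = mean
  tc <- fit_linear_trend(make_series(rep(80, 20)))
  expect_equal(unname(tc$coef[2]), 0)
  expect_equal(unique(round(tc$data$trend, 10)), 80)

  expect_error(fit_linear_trend(make_series(c(80, 81, NA))), "at least 3")
})

test_that("the cluster toy reproduces the closed-form OLS solution", {
  # days 0,0,10,10 (shifted to 1,1,11,11 on the grid is impossible; use the
  # normal equations directly as the oracle for estimate_bwv's engine)
  x <- c(0, 0, 10, 10); y <- c(80, 82, 90, 92)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept <- mean(y) - slope * mean(x)
  expect_equal(slope, 1)
  expect_equal(intercept, 81)
})

test_that("adaptive span is monotone in n and clamped", {
  rule <- span_rule(0.9, -0.0017, 0.2, 0.9)
  expect_equal(adaptive_span(rule, 365), 0.9 - 0.0017 * 365)
  expect_gt(adaptive_span(rule, 67), adaptive_span(rule, 365))
  expect_equal(adaptive_span(rule, 10000), 0.2) # clamped below
  high <- span_rule(1.2, -0.0017, 0.2, 0.9)
  expect_equal(adaptive_span(high, 10), 0.9) # clamped above
  expect_error(span_rule(0.9, 0.01), "slope")
})

test_that("LOESS trend reproduces constants and global quadratics", {
  cs <- make_series(rep(80, 50))
  tr <- fit_loess_trend(cs, span = 0.5)
  expect_lt(max(abs(tr$data$trend - 80)), 1e-9)

  q <- make_series(80 + 0.001 * (1:100)^2)
  for (span in c(0.2, 0.5, 0.9)) {
    trq <- fit_loess_trend(q, span = span)
    expect_lt(max(abs(trq$data$trend - q$weight)), 1e-6)
  }
})

test_that("LOESS at one point matches a direct tricube weighted fit", {
  set.seed(51)
  s <- make_series(80 + 0.1 * (1:15) + rnorm(15, 0, 0.5))
  span <- 0.5
  tr <- fit_loess_trend(s, span = span)
  x <- s$day; y <- s$weight; x0 <- 8
  q <- floor(span * 15) # stats::loess neighbourhood size
  d <- abs(x - x0)
  nb <- order(d)[1:q]
  h <- max(d[nb])
  wts <- (1 - pmin(d[nb] / h, 1)^3)^3
  fit <- lm(y[nb] ~ x[nb] + I(x[nb]^2), weights = wts)
  oracle <- sum(coef(fit) * c(1, x0, x0^2))
  expect_equal(tr$data$trend[x0], oracle, tolerance = 1e-7)
})

test_that("relative residuals are scale-invariant ratios", {
  s <- make_series(c(100, 100, 100))
  tr <- fit_linear_trend(s)
  tr$data$trend <- c(99, 100, 101)
  r <- relative_residuals(s, tr)
  expect_equal(r$rel_resid, c(0.01, 0, -0.01))

  set.seed(52)
  s2 <- make_series(80 + rnorm(30, 0, 0.5))
  r1 <- relative_residuals(s2, fit_linear_trend(s2))$rel_resid
  s2x2 <- s2; s2x2$weight <- s2$weight * 2
  r2 <- relative_residuals(s2x2, fit_linear_trend(s2x2))$rel_resid
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("RMSE-BWV: zero on a line, scale-invariant, matches 5-point oracle", {
  expect_equal(bwv_rmse(affine_series(20, slope = 0.05))$value_pct, 0,
               tolerance = 1e-9)

  # 5-point toy (days 1..5, kg 80,81,80,81,80): closed-form OLS by hand
  y <- c(80, 81, 80, 81, 80); x <- 1:5
  slope <- sum((x - 3) * (y - mean(y))) / sum((x - 3)^2)
  intercept <- mean(y) - slope * 3
  resid <- y - (intercept + slope * x)
  oracle <- 100 * sqrt(mean((resid / y)^2))
  s <- make_series(y)
  expect_equal(bwv_rmse(s)$value_pct, oracle, tolerance = 1e-12)

  doubled <- s; doubled$weight <- 2 * s$weight
  expect_equal(bwv_rmse(doubled)$value_pct, bwv_rmse(s)$value_pct,
               tolerance = 1e-12)
})

test_that("NLMD: zero on smooth trends, scale-invariant, folded-normal limit", {
  expect_lt(bwv_nlmd(make_series(rep(80, 50)))$value_pct, 1e-9)

  set.seed(53)
  s <- make_series(80 * (1 + rnorm(120, 0, 0.01)))
  doubled <- s; doubled$weight <- 2 * s$weight
  expect_equal(bwv_nlmd(doubled)$value_pct, bwv_nlmd(s)$value_pct,
               tolerance = 1e-10)

  # mean absolute deviation of centered Gaussian relative noise:
  # E|r| = sigma * sqrt(2/pi) (the deeper 200-replicate convergence check
  # lives in the acceptance suite)
  sigma <- 0.005
  vals <- sapply(1:50, function(i) {
    set.seed(1000 + i)
    bwv_nlmd(make_series(80 * (1 + rnorm(365, 0, sigma))))$value_pct
  })
  expect_lt(abs(mean(vals) - 100 * sigma * sqrt(2 / pi)),
            0.10 * 100 * sigma * sqrt(2 / pi))
})

test_that("span calibration returns a usable nonincreasing rule", {
  coh <- generate_cohort(synthetic_params(n_participants = 6, seed = 77))
  rule <- calibrate_span(coh, levels = c(0.3, 0.7), seed = 3, replicates = 2,
                         span_grid = seq(0.2, 0.9, by = 0.1))
  expect_s3_class(rule, "span_rule")
  expect_lte(rule$slope, 0)

  # held-out check: under the rule, mean NLMD at 70% missing stays within
  # 10% of the full-data mean
  pieces <- split_cohort(coh)
  full <- mean(sapply(pieces, function(s) bwv_nlmd(s, rule)$value_pct))
  amp_vals <- unlist(lapply(seq_along(pieces), function(i) {
    sapply(1:3, function(r) {
      a <- ampute_mcar(pieces[[i]], 0.7, seed = 5000 + 10 * i + r)
      bwv_nlmd(a, rule)$value_pct
    })
  }))
  expect_lt(abs(mean(amp_vals) - full) / full, 0.10)
})

test_that("degenerate calibration falls back to the default rule", {
  pieces <- lapply(1:5, function(i) {
    make_series(rep(80, 120), id = sprintf("c%d", i))
  })
  coh <- dplyr::bind_rows(pieces)
  expect_warning(rule <- calibrate_span(coh, levels = 0.5, seed = 1,
                                        replicates = 1),
                 "Degenerate")
  expect_equal(rule$intercept, default_span_rule()$intercept)
})

test_that("estimate_bwv returns one row per participant and method", {
  coh <- generate_cohort(synthetic_params(n_participants = 3, seed = 11))
  est <- estimate_bwv(coh)
  expect_equal(nrow(est), 6)
  expect_setequal(unique(est$method), c("rmse", "nlmd"))
  expect_true(all(est$value_pct > 0))
})
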