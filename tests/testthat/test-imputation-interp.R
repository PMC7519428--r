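test_that("all interpolants obey the universal contract and fill midpoints", {
  s <- make_series(c(80, NA, 82, 81, NA, 83, 84, 85))
  for (m in c("linear", "spline", "stine")) {
    imp <- impute_series(s, m)
    expect_imputation_contract(imp, s)
    expect_equal(attr(imp, "method"), m)
  }
  lin <- impute_series(make_series(c(80, NA, 82)), "linear")
  expect_equal(lin$weight[2], 81)
})

test_that("linear, spline and Stine recover an exactly affine series", {
  s <- affine_series(40, slope = 0.03, gaps = c(2, 5, 6, 20, 39))
  truth <- 80 + 0.03 * seq_len(40)
  for (m in c("linear", "spline", "stine")) {
    imp <- impute_series(s, m)
    expect_lt(max(abs(imp$weight - truth)), 1e-9)
  }
})

test_that("spline matches the natural-cubic-spline system solved directly", {
  # observations (day, kg): (1,80),(2,81),(4,85),(5,84); gap at day 3.
  # Natural spline: M1 = M4 = 0; tridiagonal system for M2, M3.
  x <- c(1, 2, 4, 5); y <- c(80, 81, 85, 84)
  h <- diff(x)
  rhs <- c(
    (y[3] - y[2]) / h[2] - (y[2] - y[1]) / h[1],
    (y[4] - y[3]) / h[3] - (y[3] - y[2]) / h[2]
  )
  A <- rbind(
    c((h[1] + h[2]) / 3, h[2] / 6),
    c(h[2] / 6, (h[2] + h[3]) / 3)
  )
  M <- c(0, solve(A, rhs), 0)
  # evaluate segment [x2, x4] at xq = 3
  xq <- 3; i <- 2
  t1 <- x[i + 1] - xq; t2 <- xq - x[i]
  oracle <- (M[i] * t1^3 + M[i + 1] * t2^3) / (6 * h[i]) +
    (y[i] / h[i] - M[i] * h[i] / 6) * t1 +
    (y[i + 1] / h[i] - M[i + 1] * h[i] / 6) * t2

  s <- make_series(c(80, 81, NA, 85, 84))
  imp <- impute_series(s, "spline")
  expect_equal(imp$weight[3], oracle, tolerance = 1e-9)
})

test_that("Stine is monotone on monotone data while spline overshoots", {
  # monotone rise with a convex bend
  w <- c(80, 80.1, 80.2, 80.4, 84, 88, 88.4, 88.6)
  s <- make_series(w)
  gaps <- c(2, 5, 7)
  s$weight[gaps] <- NA
  st <- impute_series(s, "stine")
  expect_true(all(diff(st$weight) >= -1e-12))
  expect_true(all(st$weight >= min(w) - 1e-12 & st$weight <= max(w) + 1e-12))
  sp <- impute_series(s, "spline")
  expect_true(any(diff(sp$weight) < -1e-12)) # the contrast the spline shows
})

test_that("interpolants enforce their observation minima and handle edges", {
  expect_error(impute_series(make_series(c(80, NA, NA)), "linear"), "at least 2")
  expect_error(impute_series(make_series(c(80, 81, 82, NA)), "spline"), "at least 4")
  # leading/trailing missing carried from nearest observation, still flagged
  s <- make_series(c(NA, NA, 80, NA, 82, NA))
  imp <- impute_series(s, "linear")
  expect_equal(imp$weight, c(80, 80, 80, 81, 82, 82))
  expect_equal(imp$imputed, c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("EWMA weights decay exponentially with day distance", {
  # symmetric neighbours: midpoint
  mid <- impute_ewma(make_series(c(80, NA, 82)), k = 1)
  expect_equal(mid$weight[2], 81)

  # hand-computed toy: missing day 5, observed days 3,4,6,7 with k = 2:
  # weights 2^-2, 2^-1, 2^-1, 2^-2 -> 81.5
  s <- make_series(c(NA, NA, 81, 80, NA, 83, 82))
  imp <- impute_ewma(s, k = 2)
  oracle <- (81 / 4 + 80 / 2 + 83 / 2 + 82 / 4) / (1 / 4 + 1 / 2 + 1 / 2 + 1 / 4)
  expect_equal(imp$weight[5], oracle)

  # constant series: constant fill regardless of k
  cs <- make_series(c(80, NA, 80, NA, NA, 80, 80))
  for (k in c(1, 4, 10)) {
    expect_equal(impute_ewma(cs, k = k)$weight, rep(80, 7))
  }
  expect_error(impute_ewma(cs, k = 0), "k")
})

test_that("the EWMA decay base is configurable", {
  # asymmetric neighbours at distances 1 and 2: base changes the blend
  s <- make_series(c(80, NA, NA, 83))
  w2 <- impute_ewma(s, k = 1, base = 2)$weight[2]
  w4 <- impute_ewma(s, k = 1, base = 4)$weight[2]
  expect_equal(w2, (80 / 2 + 83 / 4) / (1 / 2 + 1 / 4))
  expect_equal(w4, (80 / 4 + 83 / 16) / (1 / 4 + 1 / 16))
  expect_lt(w4, w2) # heavier decay leans harder on the near neighbour
})
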