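test_that("summary shape matches the design and reruns are identical", {
  coh <- generate_cohort(synthetic_params(n_participants = 2, seed = 3))
  cfg <- experiment_config(levels = 0.4, mechanisms = "mcar", replicates = 1,
                           methods = "linear", seed = 9)
  ex <- run_experiment(coh, cfg)
  expect_equal(nrow(ex$imputation_summary), 1) # 1 method x 1 mech x 1 level
  expect_equal(nrow(ex$missing_only_summary), 2) # 2 estimators
  expect_equal(unique(ex$missing_only_summary$n_datasets), 2) # 2 participants
  expect_true(all(ex$imputation_summary$sd_rmse_pct >= 0, na.rm = TRUE))

  ex2 <- run_experiment(coh, cfg)
  expect_identical(ex$imputation_summary, ex2$imputation_summary)
  expect_identical(ex$missing_only, ex2$missing_only)
})

test_that("tidy and glance expose per-dataset rows and design counts", {
  coh <- generate_cohort(synthetic_params(n_participants = 2, seed = 4))
  cfg <- experiment_config(levels = 0.3, mechanisms = "mcar", replicates = 2,
                           methods = c("linear", "ewma"), seed = 1)
  ex <- run_experiment(coh, cfg)
  td <- tidy(ex)
  expect_setequal(unique(td$kind), c("imputed", "missing-only"))
  expect_equal(sum(td$kind == "imputed"), 2 * 2 * 2) # part x rep x method
  gl <- glance(ex)
  expect_equal(gl$replicates, 2)
  expect_equal(gl$n_methods, 2)
})

test_that("an experiment without imputation methods studies missing-data BWV only", {
  coh <- generate_cohort(synthetic_params(n_participants = 3, seed = 6))
  cfg <- experiment_config(levels = c(0.2, 0.6), mechanisms = c("mcar", "rpm"),
                           replicates = 1, methods = character(0), seed = 2)
  ex <- run_experiment(coh, cfg)
  expect_equal(nrow(ex$results), 0)
  expect_equal(nrow(ex$missing_only_summary), 2 * 2 * 2)
  pooled <- ex$missing_only_pooled
  expect_equal(nrow(pooled), 2 * 2) # level x estimator, mechanisms combined
  expect_true(all(pooled$n_datasets == 6))
})

test_that("RPM datasets hit the nominal level within the binning tolerance", {
  coh <- generate_cohort(synthetic_params(n_participants = 2, seed = 8))
  pieces <- split_cohort(coh)
  cfg <- experiment_config(levels = 0.6, mechanisms = "rpm", replicates = 3,
                           methods = character(0), seed = 5)
  ex <- run_experiment(coh, cfg)
  expect_gt(nrow(ex$missing_only), 0)
  # every evaluated dataset recorded the nominal level
  expect_true(all(ex$missing_only$level == 0.6))
})

test_that("autoplot produces method-faceted error boxplots", {
  coh <- generate_cohort(synthetic_params(n_participants = 2, seed = 12))
  cfg <- experiment_config(levels = 0.4, mechanisms = "mcar", replicates = 2,
                           methods = "linear", seed = 3)
  ex <- run_experiment(coh, cfg)
  p <- autoplot(ex, what = "imputation")
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(ex, what = "bwv_nlmd")
  expect_s3_class(p2, "ggplot")
})

test_that("trend autoplot and tidiers work on a fitted trend", {
  s <- make_series(80 + 0.05 * (1:40))
  tr <- fit_linear_trend(s)
  expect_s3_class(autoplot(tr), "ggplot")
  td <- tidy(tr)
  expect_equal(nrow(td), 40)
  expect_lt(max(abs(td$resid)), 1e-9)
  gl <- glance(tr)
  expect_equal(gl$kind, "linear")
  expect_equal(gl$n_obs, 40)
})
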