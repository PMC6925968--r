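# evaluation statistics: bias / variance / MSE, ratios, coverage, CI length

test_that("bias, variance and MSE match hand arithmetic", {
  expect_equal(bias(c(0.5, 0.6, 0.7), 0.55), 0.05)
  expect_equal(bias(c(0.5, 0.6, 0.7), 0.6), 0)
  expect_true(is.na(bias(c(NA, NA), 0.5)))
  expect_equal(variance_of_estimates(c(0.5, 0.6, 0.7)), 0.02 / 3)
  expect_equal(variance_of_estimates(rep(0.4, 9)), 0)
  expect_equal(mse(0, 0.02 / 3), variance_of_estimates(c(0.5, 0.6, 0.7)))
})

test_that("mse identity: bias^2 + divisor-R variance = direct MSE", {
  set.seed(3)
  for (i in 1:10) {
    x <- runif(50)
    theta <- runif(1)
    direct <- mean((x - theta)^2)
    expect_equal(mse(bias(x, theta), variance_of_estimates(x)), direct,
                 tolerance = 1e-14)
  }
})

test_that("log_ratio is a natural log and antisymmetric", {
  expect_equal(log_ratio(0.496, 1), -0.701, tolerance = 5e-4)
  expect_equal(log_ratio(3, 3), 0)
  expect_equal(log_ratio(2, 5), -log_ratio(5, 2))
  expect_warning(out <- log_ratio(-1, 2), "nonpositive")
  expect_true(is.na(out))
})

test_that("coverage probability and band classification follow the scheme", {
  lows <- rep(0.4, 500)
  highs <- c(rep(0.6, 470), rep(0.45, 30))
  p <- coverage_probability(lows, highs, 0.5)
  expect_equal(as.numeric(p), 0.94)
  expect_equal(classify_coverage(0.94), "good")
  expect_equal(classify_coverage(0.94, detail = TRUE), "good_0.93_0.95")
  expect_equal(classify_coverage(1.0), "fair")        # > 0.97: conservative
  expect_equal(classify_coverage(1.0, detail = TRUE), "fair_high")
  expect_equal(classify_coverage(0.90), "poor")
  expect_equal(classify_coverage(0.92), "fair")
  # closed boundaries of the good band
  expect_equal(classify_coverage(0.93), "good")
  expect_equal(classify_coverage(0.97), "good")
  # truth on the interval boundary counts as covered
  expect_equal(as.numeric(coverage_probability(0.5, 0.7, 0.5)), 1)
})

test_that("coverage SE formula and monotonicity", {
  expect_equal(coverage_se(0.95, 500), sqrt(0.95 * 0.05 / 500))
  expect_equal(coverage_se(0.5, 1), 0.5)
  expect_lt(coverage_se(0.95, 1000), coverage_se(0.95, 500))
})

test_that("average CI length and information comparisons", {
  expect_equal(average_ci_length(c(0.1, 0.2, 0.3), c(0.3, 0.4, 0.5)), 0.2)
  expect_equal(average_ci_length(0.4, 0.4), 0)
  expect_equal(average_ci_length(c(0, 0.2, NA), c(0.1, 0.5, NA)), 0.2)
  expect_equal(information_ratio(1, 1), 0)
  expect_equal(information_ratio(1, 1.1), 21, tolerance = 1e-10)
  expect_true(is.na(information_ratio(0, 1)))
})

test_that("replicate bootstrap CI is degenerate for constants and flags 0", {
  const <- data.frame(x = rep(0.3, 40))
  ci <- replicate_bootstrap_ci(function(d) mean(d$x), const, B_m = 100,
                               seed = 1)
  expect_equal(ci, c(0.3, 0.3))

  set.seed(2)
  shifted <- data.frame(x = rnorm(200, mean = 1))
  ci2 <- replicate_bootstrap_ci(function(d) mean(d$x), shifted, B_m = 400,
                                seed = 3)
  expect_true(ci2[1] > 0)  # CI excludes zero for a clearly shifted mean
})

test_that("bootstrap CI width shrinks roughly like 1/sqrt(R)", {
  set.seed(11)
  x_big <- rnorm(500, sd = 0.1)
  widths <- vapply(c(125, 500), function(R) {
    ci <- replicate_bootstrap_ci(function(d) mean(d$x),
                                 data.frame(x = x_big[seq_len(R)]),
                                 B_m = 600, seed = R)
    ci[2] - ci[1]
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.35)
})

test_that("weighting and coverage metrics assemble per-cell summaries", {
  pop <- generate_facility_population(small_spa_config())
  smp <- draw_spa_sample(pop, seed = 50)
  cfg <- simulation_config(R = 40, mode = "cluster_resample", B = 30,
                           variance_methods = c("bootstrap", "svy1", "svy3"),
                           seed = 4)
  sim <- run_simulation(smp$clients, smp$spec, smp$indicators, cfg,
                        facilities = smp$facilities)

  wm <- weighting_metrics(sim, B_m = 200, seed = 7)
  expect_equal(nrow(wm), nrow(sim$truth))
  expect_equal(wm$var_ratio, exp(wm$log_var_ratio))
  expect_equal(wm$mse_unweighted,
               wm$bias_unweighted^2 + wm$var_unweighted,
               tolerance = 1e-14)
  expect_equal(wm$mse_weighted,
               wm$bias_weighted^2 + wm$var_weighted,
               tolerance = 1e-14)

  cm <- coverage_metrics(sim)
  expect_equal(nrow(cm), 3 * length(smp$indicators))  # national only
  expect_true(all(cm$coverage >= 0 & cm$coverage <= 1))
  expect_true(all(cm$band %in% c("good", "fair", "poor")))
  expect_identical(cm$band, classify_coverage(cm$coverage))
  expect_true(all(cm$avg_ci_length >= 0))
})
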