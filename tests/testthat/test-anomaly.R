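test_that("knn_score equals hand and brute-force oracles", {
  # hand case: train {0,1,2} on a line, query 0, k = 2 -> (0 + 1)/2
  expect_equal(knn_score(matrix(c(0, 1, 2)), matrix(0), k = 2), 0.5)
  # query coinciding with k training points scores 0
  expect_equal(knn_score(matrix(c(1, 1, 1, 5)), matrix(1), k = 3), 0)
  expect_error(knn_score(matrix(1:3), matrix(0), k = 4), "out of range")
  # oracle equivalence on 200 random points for every k
  set.seed(41)
  train <- matrix(rnorm(200 * 3), 200, 3)
  qry <- matrix(rnorm(40 * 3), 40, 3)
  for (k in c(1, 7, 50, 200))
    expect_equal(knn_score(train, qry, k), brute_knn_score(train, qry, k),
                 tolerance = 1e-12)
})

test_that("detection thresholds calibrate and respond monotonically", {
  set.seed(43)
  train <- matrix(rnorm(500 * 4), 500, 4)
  test <- matrix(rnorm(500 * 4), 500, 4)
  lab75 <- knn_detect(train, test, k = 10, pct = 75)
  expect_lt(abs(mean(lab75 == "normal") - 0.75), 0.05)
  # monotonicity: higher percentile, more normals
  lab40 <- knn_detect(train, test, k = 10, pct = 40)
  expect_gte(sum(lab75 == "normal"), sum(lab40 == "normal"))
  # far-away points are always abnormal
  far <- matrix(1e6, 3, 4)
  expect_true(all(knn_detect(train, far, k = 10, pct = 75) == "abnormal"))
})

test_that("the protocol enumerates the full grid and respects its preconditions", {
  x <- gen_population(population_spec(n_per_category = 110, n_features = 5,
                                      d_vector = 0.2, seed = 19))
  cfg1 <- run_config(transforms = "zscore")
  runs <- run_anomaly(x, cfg1, seed = 1)
  expect_s3_class(runs, "anomaly_runs")
  expect_equal(nrow(runs), 144L)  # 72 per training category
  expect_equal(as.integer(table(runs$training_category)), c(72L, 72L))
  expect_equal(nrow(unique(runs[, c("k", "threshold_percentile")])), 72L)
  expect_true(all(runs$pct_normal_same >= 0 & runs$pct_normal_same <= 100))
  # unbalanced input is rejected, as is a too-large k
  xu <- gen_population(population_spec(n_per_category = c(60, 50),
                                       n_features = 4, seed = 2))
  expect_error(run_anomaly(xu, cfg1), "balanced")
  small <- gen_population(population_spec(n_per_category = 30,
                                          n_features = 4, seed = 2))
  expect_error(run_anomaly(small, cfg1), "too small")
})

test_that("null data give matched normal rates; summaries flag separation", {
  # identical distributions: same- and other-category normal rates agree
  x <- gen_population(population_spec(n_per_category = 150, n_features = 5,
                                      d_vector = 0, seed = 23))
  runs <- run_anomaly(x, run_config(transforms = "zscore",
                                    k_values = c(10, 20, 30),
                                    threshold_percentiles = c(50, 60, 75)))
  s <- summarize_anomaly(runs)
  expect_true(all(abs(s$mean_ratio - 1) < 0.25))
  # ratio summary arithmetic on constructed runs
  eq <- data.frame(training_category = "f", pct_normal_same = 80,
                   pct_normal_other = 80)
  expect_equal(summarize_anomaly(eq)$mean_ratio, 1)
  zer <- data.frame(training_category = c("f", "f"),
                    pct_normal_same = c(60, 70),
                    pct_normal_other = c(0, 35))
  sz <- summarize_anomaly(zer)
  expect_equal(sz$n_runs_excluded_zero, 1L)
  expect_equal(sz$mean_ratio, 2)
  allz <- data.frame(training_category = "f", pct_normal_same = 60,
                     pct_normal_other = 0)
  expect_true(summarize_anomaly(allz)$complete_separation)
})

test_that("the three regimes order as expected: dimorphic >> gendered >> brain-like", {
  cfg <- run_config(transforms = "zscore", k_values = c(10, 20, 30),
                    threshold_percentiles = c(50, 60, 75))
  # dimorphic: complete separation (smaller k grid: 31 per category)
  xp <- balance_categories(gen_preset("primate_faces", seed = 1), seed = 1)
  cfg_small <- run_config(transforms = "zscore", k_values = c(5L, 10L),
                          threshold_percentiles = c(50, 60, 75))
  sp <- summarize_anomaly(run_anomaly(xp, cfg_small))
  expect_true(all(sp$complete_separation))
  # gendered vs corrected brain-like: ratio much larger, over several seeds
  ratio_of <- function(x) {
    s <- summarize_anomaly(run_anomaly(x, cfg))
    mean(s$mean_ratio, na.rm = TRUE)
  }
  gr <- vapply(1:5, function(sd0)
    ratio_of(gen_preset("gendered_behaviors", seed = sd0)), numeric(1))
  br <- vapply(1:5, function(sd0) {
    b <- gen_preset("brain_volumes", seed = sd0, n_per_category = 150L)
    ratio_of(apply_power_proportion(b, fit_power_proportion(b)))
  }, numeric(1))
  expect_true(all(gr > br))
  expect_lt(max(abs(br - 1)), 0.5)   # brain-like ratios stay near 1
  expect_gt(min(gr), 2)              # gendered ratios are far from 1
})
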