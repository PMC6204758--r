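test_that("both algorithms recover well-separated blobs and validate k", {
  set.seed(53)
  co <- rbind(matrix(rnorm(30 * 2), 30, 2), matrix(rnorm(30 * 2, 9), 30, 2))
  cat2 <- rep(c("a", "b"), each = 30)
  for (div in list(kmeans_divide(co, cat2, 2, seed = 1),
                   ward_divide(co, cat2, 2))) {
    ch <- same_cluster_chances(div)
    expect_equal(ch$fm, 0)
    expect_equal(ch$ff, 1)
    expect_equal(ch$mm, 1)
    expect_true(all(div$composition$P == 1))
  }
  expect_error(kmeans_divide(co, cat2, 100, seed = 1), "exceeds")
  expect_error(ward_divide(co, cat2, 61), "exceeds")
  # k = 1: everyone together, all chances 1
  d1 <- kmeans_divide(co, cat2, 1, seed = 1)
  expect_equal(same_cluster_chances(d1)$fm, 1)
  # k-means is deterministic per seed
  expect_identical(kmeans_divide(co, cat2, 3, seed = 5)$assignments,
                   kmeans_divide(co, cat2, 3, seed = 5)$assignments)
})

test_that("ward cuts are nested and k = n gives singletons", {
  set.seed(59)
  co <- matrix(rnorm(40 * 3), 40, 3)
  cat2 <- rep(c("a", "b"), 20)
  a2 <- ward_divide(co, cat2, 2)$assignments
  a3 <- ward_divide(co, cat2, 3)$assignments
  # every k = 3 cluster sits inside one k = 2 cluster
  expect_true(all(tapply(a2, a3, function(v) length(unique(v))) == 1))
  an <- ward_divide(co, cat2, 40)$assignments
  expect_equal(length(unique(an)), 40L)
})

test_that("same-cluster chances match closed forms and the pair-counting oracle", {
  # the 66%/56% two-cluster composition: 52/55/51 rounded
  assign2 <- rep(c(1, 2, 1, 2), c(66, 34, 56, 44))
  grp <- rep(c("f", "m"), c(100, 100))
  ch <- same_cluster_chances(assign2, groups = grp)
  expect_equal(round(100 * ch$fm), 52)
  expect_equal(round(100 * ch$ff), 55)
  expect_equal(round(100 * ch$mm), 51)
  # three-cluster hand case f = (.5,.3,.2), m = (.2,.3,.5)
  a3 <- c(rep(1:3, c(5, 3, 2)), rep(1:3, c(2, 3, 5)))
  g3 <- rep(c("f", "m"), each = 10)
  ch3 <- same_cluster_chances(a3, groups = g3)
  expect_equal(ch3$fm, 0.29)
  expect_equal(ch3$ff, 0.38)
  expect_equal(ch3$mm, 0.38)
  # oracle equivalence on random divisions, plus the Cauchy-Schwarz bound
  set.seed(61)
  for (rep0 in 1:20) {
    k <- sample(2:8, 1)
    n <- sample(20:60, 1)
    a <- sample(k, n, replace = TRUE)
    g <- sample(c("f", "m"), n, replace = TRUE)
    if (length(unique(g)) < 2) next
    got <- same_cluster_chances(a, groups = g)
    want <- pair_counting_chances(a, g)
    expect_equal(got$fm, want$fm)
    expect_equal(got$ff, want$ff)
    expect_equal(got$mm, want$mm)
    expect_lte(got$fm^2, got$ff * got$mm + 1e-12)
  }
})

test_that("cluster compositions respect disparity invariants", {
  set.seed(67)
  co <- matrix(rnorm(120 * 4), 120, 4)
  cat2 <- rep(c("f", "m"), 60)
  divs <- cluster_sweep(co, cat2, k_range = 2:6, seed = 3)
  for (d in divs) {
    comp <- d$composition
    expect_true(all(comp$P >= 0.5 & comp$P <= 1))
    # P-granularity: P is a multiple of 1/n given integer counts
    expect_true(all(abs(comp$P * comp$n - round(comp$P * comp$n)) < 1e-9))
    expect_equal(sum(comp$f), 1)
    expect_equal(sum(comp$m), 1)
  }
})

test_that("best_separating minimizes the cross-category chance", {
  co <- rbind(matrix(rnorm(30 * 2), 30, 2), matrix(rnorm(30 * 2, 9), 30, 2))
  cat2 <- rep(c("a", "b"), each = 30)
  perfect <- kmeans_divide(co, cat2, 2, seed = 1)     # fm = 0
  mixed <- kmeans_divide(matrix(rnorm(120), 60, 2), cat2, 2, seed = 1)
  expect_identical(best_separating(list(mixed, perfect)), perfect)
  expect_identical(best_separating(list(mixed)), mixed)
  expect_error(best_separating(list()), "empty")
})

test_that("disparity curve reflects the data regime", {
  # degenerate case: all clusters balanced -> p = 0.5, s = 0
  flat <- data.frame(n = seq(10, 200, by = 10), P = 0.5)
  cur <- disparity_curve(flat, bandwidth = 30)
  expect_true(all(abs(cur$p_of_n - 0.5) < 1e-12))
  expect_true(all(cur$s_of_n < 1e-6))
  expect_error(disparity_curve(flat, bandwidth = -1), "positive")
  expect_error(disparity_curve(flat[1:5, ]), "at least 10")
  # brain-like corrected: p(n) settles near 0.5 for large clusters;
  # gendered: p(n) stays high across sizes
  xb <- gen_preset("brain_volumes", seed = 1)
  xc <- zscore_columns(apply_power_proportion(xb, fit_power_proportion(xb)))
  cb <- disparity_curve(cluster_sweep(xc$features, xb$category, 2:10,
                                      seed = 1))
  expect_true(all(cb$p_of_n[cb$n > 300] > 0.5 &
                    cb$p_of_n[cb$n > 300] < 0.6))
  xg <- zscore_columns(gen_preset("gendered_behaviors", seed = 1))
  cg <- disparity_curve(cluster_sweep(xg$features, xg$category, 2:10,
                                      seed = 1))
  expect_true(all(cg$p_of_n > 0.8 & cg$p_of_n <= 1))
})

test_that("uncorrected volumes cluster by size; corrected volumes do not", {
  xb <- gen_preset("brain_volumes", seed = 3, n_per_category = 250L)
  split <- split_by_icv_median(xb)
  d_raw <- ward_divide(zscore_columns(xb)$features, xb$category, 2)
  fm_sex <- same_cluster_chances(d_raw)$fm
  fm_size <- icv_split_alignment(d_raw, split)$fm
  expect_lt(fm_size, fm_sex)
  # after correction both alignments sit near chance
  xc <- apply_power_proportion(xb, fit_power_proportion(xb))
  d_cor <- ward_divide(zscore_columns(xc)$features, xc$category, 2)
  ch <- same_cluster_chances(d_cor)
  ia <- icv_split_alignment(d_cor, split_by_icv_median(xc))
  base <- sum(table(d_cor$assignments)^2) / length(d_cor$assignments)^2
  expect_lt(abs(ch$fm - base), 0.1)
  expect_lt(abs(ia$fm - base), 0.1)
  # random split labels sit at the division's baseline chance
  set.seed(71)
  rnd <- factor(sample(c("small", "large"), 500, replace = TRUE))
  ar <- rep(1:2, c(300, 200))
  cr <- same_cluster_chances(ar, groups = rnd)
  base_r <- (300 / 500)^2 + (200 / 500)^2
  expect_lt(abs(cr$fm - base_r), 0.05)
  expect_lt(abs(cr$ff - base_r), 0.05)
})
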