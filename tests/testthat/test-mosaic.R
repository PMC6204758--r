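test_that("zone cuts land at the category quantiles", {
  set.seed(79)
  n <- 20000
  x <- feature_table(
    matrix(c(rnorm(n, -1), rnorm(n, 1)), ncol = 1,
           dimnames = list(NULL, "f1")),
    category = rep(c("female", "male"), each = n))
  z <- define_zones(x)
  expect_equal(z$direction, "male")
  expect_equal(z$male_end_cut, 1 + qnorm(0.67), tolerance = 0.05)
  expect_equal(z$female_end_cut, -1 - qnorm(0.67), tolerance = 0.05)
  # ~33% of the defining category falls in its own end zone
  prof <- profile_subjects(x, z)
  pct_m <- mean(prof$n_male_end[x$category == "male"] == 1)
  pct_f <- mean(prof$n_female_end[x$category == "female"] == 1)
  expect_lt(abs(pct_m - 0.33), 0.02)
  expect_lt(abs(pct_f - 0.33), 0.02)
  # identical distributions: ~33% of each category in each end zone
  y <- feature_table(matrix(rnorm(2 * n), ncol = 1,
                            dimnames = list(NULL, "f1")),
                     category = rep(c("female", "male"), n))
  zy <- define_zones(y)
  py <- profile_subjects(y, zy)
  expect_lt(abs(mean(py$n_male_end) - 0.33), 0.03)
  expect_lt(abs(mean(py$n_female_end) - 0.33), 0.03)
})

test_that("degenerate crossed cuts flag the feature and classify it intermediate", {
  # female mean is higher, but the female 67th percentile sits below the
  # male 33rd percentile: the cuts cross
  v <- c(-10, 0, 0, 0, 50, 1, 1, 1, 1, 1)
  x <- feature_table(matrix(v, ncol = 1, dimnames = list(NULL, "f1")),
                     category = rep(c("female", "male"), each = 5))
  expect_warning(z <- define_zones(x), "crossed")
  expect_true(z$degenerate)
  prof <- suppressWarnings(profile_subjects(x, z))
  expect_true(all(prof$n_intermediate == 1))
})

test_that("profiles count zones exhaustively and assign consistency types", {
  # seven features engineered so subject 1 has 4 male-end and 3 female-end
  cuts_m <- rep(10, 7); cuts_f <- rep(-10, 7)
  n <- 10
  set.seed(83)
  base <- matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, paste0("b", 1:7)))
  # widen category gap so zones are non-degenerate and deterministic
  base[1:5, ] <- base[1:5, ] - 30
  base[6:10, ] <- base[6:10, ] + 30
  x <- feature_table(base, category = rep(c("female", "male"), each = 5))
  z <- define_zones(x)
  subj <- base[1, ]
  subj[1:4] <- 40    # beyond every male-end cut
  subj[5:7] <- -40   # beyond every female-end cut
  x$features[1, ] <- subj
  prof <- profile_subjects(x, z)
  expect_equal(prof$n_male_end[1], 4L)
  expect_equal(prof$n_female_end[1], 3L)
  expect_equal(prof$consistency[1], factor("mosaic",
    levels = levels(prof$consistency)))
  # counts always sum to the number of features
  expect_true(all(prof$n_female_end + prof$n_male_end +
                    prof$n_intermediate == 7L))
  # a subject beyond every male-end cut is consistent_male
  x$features[2, ] <- 40 * sign(ifelse(z$direction == "male", 1, -1))
  prof2 <- profile_subjects(x, z)
  expect_equal(as.character(prof2$consistency[2]), "consistent_male")
})

test_that("majority typology follows the more-male-end rule with female ties", {
  p <- data.frame(n_female_end = c(3, 4, 0, 2),
                  n_male_end = c(4, 3, 0, 2))
  expect_equal(as.character(majority_type(p)),
               c("male_type", "female_type", "female_type", "female_type"))
})

test_that("mosaicism dominates the gendered regime and consistency the dimorphic one", {
  counts <- vapply(1:20, function(s) {
    pg <- profile_subjects(gen_preset("gendered_behaviors", seed = s))
    pp <- profile_subjects(gen_preset("primate_faces", seed = s))
    c(g_mosaic = sum(pg$consistency == "mosaic"),
      g_cons = sum(pg$consistency %in% c("consistent_female",
                                         "consistent_male")),
      p_mosaic = sum(pp$consistency == "mosaic"),
      p_cons = sum(pp$consistency %in% c("consistent_female",
                                         "consistent_male")))
  }, numeric(4))
  tot <- rowSums(counts)
  expect_gt(tot["g_mosaic"], tot["g_cons"])   # gendered: mosaic majority
  expect_gt(tot["p_cons"], tot["p_mosaic"])   # dimorphic: reverse
})

test_that("raising effect correlation raises internal consistency monotonically", {
  ec_grid <- c(0, 0.25, 0.5, 0.75, 1)
  cons_frac <- vapply(ec_grid, function(ec) {
    mean(vapply(1:20, function(s) {
      sp <- population_spec(n_per_category = 101, n_features = 10,
                            d_vector = 1.2, effect_correlation = ec,
                            noise_rho = 0.1, seed = s)
      prof <- profile_subjects(gen_population(sp))
      mean(prof$consistency %in% c("consistent_female", "consistent_male"))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(ec_grid, cons_frac, method = "spearman"), 0)
  expect_true(all(diff(cons_frac) > -0.02))  # near-monotone in the mean
})
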