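test_that("cross-validated separation tracks the data regime", {
  # separable dimorphic data: essentially perfect
  xp <- gen_preset("primate_faces", seed = 1)
  cvp <- cv_classify(zscore_columns(xp), algo = "svm_linear", folds = 5,
                     seed = 1)
  expect_true(all(cvp$rates > 95))
  # label-shuffled data: chance, averaged over seeds
  accs <- vapply(1:10, function(s) {
    x <- gen_population(population_spec(n_per_category = 100,
                                        n_features = 8, d_vector = 0.8,
                                        seed = s))
    restore <- brainmosaic:::local_rng(1000 + s)
    shuf <- sample(as.character(x$category))
    restore()
    cv_classify(zscore_columns(x$features), shuf, "svm_linear", folds = 5,
                seed = s)$overall
  }, numeric(1))
  ci <- mean(accs) + c(-2, 2) * sd(accs) / sqrt(length(accs))
  expect_gt(50, ci[1])
  expect_lt(50, ci[2])
  # brain-like corrected preset: well above chance, far below perfect
  xb <- gen_preset("brain_volumes", seed = 1)
  xc <- apply_power_proportion(xb, fit_power_proportion(xb))
  cvb <- cv_classify(zscore_columns(xc), algo = "svm_linear", seed = 1)
  expect_gt(cvb$overall, 60)
  expect_lt(cvb$overall, 90)
  expect_error(cv_classify(zscore_columns(xp), folds = 40), "per fold")
})

test_that("agreement closed forms and bounds match the printed table rows", {
  rows <- agreement_reference_rows()
  for (i in seq_len(nrow(rows))) {
    cf <- agreement_closed_forms(rows$self[i], rows$ref[i])
    # the correctness-rate columns are printed as rounded integers, so
    # recomputed U and P can sit up to one unit from the printed values
    expect_lte(abs(cf$U - rows$U[i]), 1)
    expect_lte(abs(cf$P_max - rows$P[i]), 1)
  }
  # identical label vectors: A = 100, only possible when a_self = a_ref
  truth <- factor(rep(c("f", "m"), 50))
  labs <- factor(rep(c("f", "m"), c(55, 45)), levels = c("f", "m"))
  a <- agreement_stats(labs, labs, truth)
  expect_equal(a$A, 100)
  expect_equal(a$a_self, a$a_ref)
  expect_equal(a$P_max, 100)
  expect_error(agreement_stats(labs[1:10], labs, truth), "align")
})

test_that("agreement bounds hold and are label/indicator equivalent", {
  set.seed(73)
  for (rep0 in 1:25) {
    n <- 80
    truth <- factor(sample(c("f", "m"), n, replace = TRUE,
                           prob = c(0.5, 0.5)))
    l1 <- factor(ifelse(runif(n) < 0.7, as.character(truth),
                        ifelse(truth == "f", "m", "f")), levels = c("f", "m"))
    l2 <- factor(ifelse(runif(n) < 0.6, as.character(truth),
                        ifelse(truth == "f", "m", "f")), levels = c("f", "m"))
    a <- agreement_stats(l1, l2, truth)
    expect_gte(a$A, abs(a$a_self + a$a_ref - 100) - 1e-9)
    expect_lte(a$A, a$P_max + 1e-9)
    # agreement computed on labels equals agreement on correctness
    # indicators (two binary classifiers agree iff both right or both wrong)
    ind <- mean((l1 == truth) == (l2 == truth))
    expect_equal(a$A, 100 * ind)
  }
})

test_that("transfer protocol reduces to the in-sample fit on self-transfer", {
  x <- gen_preset("gendered_behaviors", seed = 5)
  tr <- transfer_protocol(x, x, "zscore", seed = 2)
  z1 <- zscore_columns(x$features)
  comb <- zscore_columns(rbind(z1, z1))
  fit <- brainmosaic:::fit_classifier(comb[1:nrow(z1), ], x$category,
                                      "svm_linear")
  pred <- predict(fit, comb[-(1:nrow(z1)), ])
  want <- vapply(levels(x$category), function(lv)
    100 * mean(pred[x$category == lv] == lv), numeric(1))
  expect_equal(tr$rates_ref_model, want)
})

test_that("site distortions that z-scoring removes do not break transfer", {
  sp <- preset_population("multisite_brain", seed = 4)
  sites <- attr(sp, "sites")
  x <- gen_multisite(sp, 4, site_names = sites$names)  # zero shifts
  ref <- x[x$site == "boston"]
  tst <- x[x$site == "beijing"]
  tr <- transfer_protocol(ref, tst, "zscore", seed = 1)
  expect_lt(abs(tr$rates_ref_model[["female"]] +
                  tr$rates_ref_model[["male"]] -
                  sum(tr$self_cv$rates)) / 2, 15)
  expect_gt(tr$agreement$A, 50)
})

test_that("a site with a flipped category axis transfers below chance", {
  sp <- preset_population("multisite_brain", seed = 9)
  ref <- gen_population(sp, site = "ref")
  spf <- sp
  spf$d_vector <- -sp$d_vector      # same geometry, reversed category axis
  spf$seed <- 10L
  tst <- gen_population(spf, site = "flip")
  tr <- transfer_protocol(ref, tst, "zscore", seed = 1)
  expect_lt(mean(tr$rates_ref_model), 50)
  expect_gt(tr$self_cv$overall, 55)
  # the reference model still classifies consistently, so agreement falls
  # near 100 - A(self vs truth-aligned) rather than near P_max
  expect_lt(tr$agreement$A, tr$agreement$P_max)
})

test_that("age windows restrict evaluation to comparable subjects", {
  x <- gen_preset("multisite_brain", seed = 2)
  ref <- x[x$site == "boston"]
  tst <- x[x$site == "telaviv"]
  tr <- transfer_protocol(ref, tst, "zscore", age_window = c(18, 35),
                          seed = 1)
  expect_equal(tr$n_test, sum(tst$age >= 18 & tst$age <= 35))
  expect_error(transfer_protocol(ref, tst, age_window = c(200, 300)),
               "age window")
})
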