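# Shared fixtures and small oracles used across test files.

# Tiny deterministic table: 4 subjects, 2 features, 2 per category.
toy_table <- function() {
  feature_table(matrix(c(1, 2, 3, 4,
                         5, 6, 7, 8), 4, 2,
                       dimnames = list(NULL, c("a", "b"))),
                category = c("f", "f", "m", "m"),
                subject_id = c("s1", "s2", "s3", "s4"),
                icv = c(1, 2, 3, 4))
}

# Pooled-SD Cohen's d of a numeric vector between two categories.
cohens_d <- function(v, category) {
  m <- tapply(v, category, mean)
  s2 <- tapply(v, category, stats::var)
  n <- table(category)
  sp <- sqrt(((n[1] - 1) * s2[1] + (n[2] - 1) * s2[2]) / (sum(n) - 2))
  unname((m[2] - m[1]) / sp)
}

# Exhaustive pair-counting oracle for same-cluster chances (ordered pairs
# with replacement within the stated groups).
pair_counting_chances <- function(assignments, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  same <- outer(assignments, assignments, `==`)
  pick <- function(g1, g2) {
    i <- which(groups == g1); j <- which(groups == g2)
    mean(same[i, j, drop = FALSE])
  }
  list(fm = pick(lev[1], lev[2]), ff = pick(lev[1], lev[1]),
       mm = pick(lev[2], lev[2]))
}

# Brute-force kNN score oracle: full sort of all pairwise distances.
brute_knn_score <- function(train, x, k) {
  apply(x, 1, function(q) {
    d <- sqrt(colSums((t(train) - q)^2))
    mean(sort(d)[seq_len(k)])
  })
}

# Write a feature table to temp CSVs; returns c(features, metadata) paths.
write_temp_csvs <- function(x) {
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_feature_table(x, p1, p2)
  c(p1, p2)
}

# Published cross-sample agreement rows (printed integer self-model /
# reference-model / U / P values): SVM and random-forest rows spanning
# three test samples and several representations.
agreement_reference_rows <- function() {
  data.frame(
    self = c(53, 73, 66, 73, 74, 78, 64, 72),
    ref  = c(71, 75, 86, 70, 64, 63, 67, 81),
    U    = c(51, 61, 62, 60, 57, 58, 55, 63),
    P    = c(82, 98, 80, 97, 90, 85, 97, 91))
}
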