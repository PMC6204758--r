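#' Mean distance to the k nearest training points
#'
#' The kNN anomaly score: for each query point, the average Euclidean
#' distance to its `k` nearest neighbors in the training set.
#'
#' @param train Numeric matrix of training coordinates (rows = points).
#' @param x Numeric matrix (or vector, one point) of query coordinates.
#' @param k Number of neighbors, `1 <= k <= nrow(train)`.
#' @return Numeric vector of scores, one per query point.
#' @examples
#' knn_score(matrix(c(0, 1, 2)), matrix(0), k = 2)  # (0 + 1) / 2
#' @export
knn_score <- function(train, x, k) {
  train <- as.matrix(train)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  k <- as.integer(k)
  if (k < 1L || k > nrow(train))
    stop(sprintf("k = %d out of range for %d training points",
                 k, nrow(train)), call. = FALSE)
  d <- cross_dist(x, train)
  apply(d, 1L, function(row) mean(sort.int(row, partial = k)[seq_len(k)]))
}

# Euclidean distances between rows of a (queries) and rows of b (training).
cross_dist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Self-scores of the training set: each point's mean distance to its k
# nearest *other* training points. Including the point itself would make
# one neighbor distance identically zero for everyone, so self-exclusion is
# the only non-degenerate reading of the training step.
knn_self_scores <- function(train, k) {
  train <- as.matrix(train)
  if (k > nrow(train) - 1L)
    stop(sprintf("k = %d needs at least k + 1 training points", k),
         call. = FALSE)
  d <- cross_dist(train, train)
  diag(d) <- Inf
  apply(d, 1L, function(row) mean(sort.int(row, partial = k)[seq_len(k)]))
}

#' Classify test points as normal or abnormal
#'
#' The detection step: the threshold is the `pct`-th percentile (linear
#' interpolation between order statistics) of the training points' own kNN
#' scores (self excluded), and a test point is abnormal iff its score is
#' strictly larger than the threshold (ties are normal). Raising `pct`
#' therefore never decreases the number of points labeled normal.
#'
#' @param train Numeric matrix of training coordinates.
#' @param test Numeric matrix of test coordinates.
#' @param k Number of neighbors.
#' @param pct Threshold percentile in (0, 100).
#' @return Factor of labels (`normal`/`abnormal`), one per test point, with
#'   attributes `threshold` and `scores`.
#' @export
knn_detect <- function(train, test, k, pct) {
  stopifnot(pct > 0, pct < 100)
  thr <- stats::quantile(knn_self_scores(train, k), pct / 100, names = FALSE)
  sc <- knn_score(train, test, k)
  out <- factor(ifelse(sc > thr, "abnormal", "normal"),
                levels = c("normal", "abnormal"))
  attr(out, "threshold") <- thr
  attr(out, "scores") <- sc
  out
}

#' Run the cross-category anomaly-detection protocol
#'
#' For each training category and each data representation, half of the
#' training category (drawn once per category x representation, seeded) is
#' used as the training set; the other half of that category plus half of
#' the other category form the test set. Each (k, threshold) grid cell then
#' records the percentage of held-out same-category subjects and of
#' other-category subjects labeled normal. With the default grids this is
#' 72 runs per training category per representation and 864 runs in total
#' for two categories and six representations.
#'
#' Features are z-scored before embedding; the embedding is fitted once on
#' all subjects (the protocol is category-blind up to the choice of
#' training set).
#'
#' @param x A balanced [feature_table] (see [balance_categories()]).
#' @param config A [run_config]; its `transforms`, `k_values`,
#'   `threshold_percentiles`, and `mu` (first element) are used.
#' @param seed Integer seed for the half-splits.
#' @return A data.frame of class `anomaly_runs` with one row per run:
#'   `training_category`, `transform`, `k`, `threshold_percentile`,
#'   `pct_normal_same`, `pct_normal_other`.
#' @seealso [summarize_anomaly()]
#' @export
run_anomaly <- function(x, config = run_config(), seed = config$seed) {
  stopifnot(inherits(x, "feature_table"), inherits(config, "run_config"))
  cnt <- table(x$category)
  if (cnt[1L] != cnt[2L])
    stop("categories must be balanced; see balance_categories()",
         call. = FALSE)
  maxk <- max(config$k_values)
  if (min(cnt) < 2L * maxk)
    stop(sprintf(
      "category size %d too small for max k = %d (needs >= %d per category)",
      min(cnt), maxk, 2L * maxk), call. = FALSE)
  z <- zscore_columns(x)
  lev <- levels(x$category)
  rows <- vector("list", 0L)
  for (ti in seq_along(config$transforms)) {
    tr <- config$transforms[ti]
    emb <- embed_features(z, tr, mu = config$mu[1L])
    for (ci in 1:2) {
      train_cat <- lev[ci]
      other_cat <- lev[3L - ci]
      restore <- local_rng(seed + 101L * ti + 13L * ci)
      idx_tr <- which(x$category == train_cat)
      idx_ot <- which(x$category == other_cat)
      half_tr <- sample(idx_tr, length(idx_tr) %/% 2L)
      half_ot <- sample(idx_ot, length(idx_ot) %/% 2L)
      restore()
      train <- emb$coords[half_tr, , drop = FALSE]
      test_same <- emb$coords[setdiff(idx_tr, half_tr), , drop = FALSE]
      test_other <- emb$coords[half_ot, , drop = FALSE]
      for (k in config$k_values) {
        # when k equals the training-set size, the self-excluded training
        # step has only k - 1 neighbors available; use all of them
        self_sc <- knn_self_scores(train, min(k, nrow(train) - 1L))
        sc_same <- knn_score(train, test_same, k)
        sc_other <- knn_score(train, test_other, k)
        for (pct in config$threshold_percentiles) {
          thr <- stats::quantile(self_sc, pct / 100, names = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            training_category = train_cat, transform = tr, k = k,
            threshold_percentile = pct,
            pct_normal_same = 100 * mean(sc_same <= thr),
            pct_normal_other = 100 * mean(sc_other <= thr))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("anomaly_runs", "data.frame")
  out
}

#' Summarize anomaly runs into mean normal-rate ratios
#'
#' For each training category, computes the mean over runs of the ratio
#' (percent of same-category test subjects labeled normal) / (percent of
#' other-category subjects labeled normal), excluding runs whose
#' denominator is zero and reporting how many were excluded. A ratio near 1
#' means the model of one category accepts the other category just as
#' readily; a large ratio (or complete separation, where every
#' other-category rate is zero) means the categories form distinct types.
#'
#' @param runs An `anomaly_runs` data.frame from [run_anomaly()].
#' @return An object of class `anomaly_summary`: data.frame with columns
#'   `training_category`, `mean_ratio`, `n_runs`, `n_runs_excluded_zero`,
#'   `complete_separation`.
#' @export
summarize_anomaly <- function(runs) {
  stopifnot(is.data.frame(runs),
            all(c("training_category", "pct_normal_same",
                  "pct_normal_other") %in% names(runs)))
  out <- do.call(rbind, lapply(split(runs, runs$training_category),
    function(rr) {
      nz <- rr$pct_normal_other > 0
      data.frame(
        training_category = rr$training_category[1L],
        mean_ratio = if (any(nz))
          mean(rr$pct_normal_same[nz] / rr$pct_normal_other[nz]) else NA_real_,
        n_runs = nrow(rr),
        n_runs_excluded_zero = sum(!nz),
        complete_separation = !any(nz))
    }))
  rownames(out) <- NULL
  class(out) <- c("anomaly_summary", "data.frame")
  out
}

#' @export
print.anomaly_summary <- function(x, ...) {
  cat("Cross-category kNN anomaly detection\n")
  for (i in seq_len(nrow(x))) {
    if (x$complete_separation[i]) {
      cat(sprintf(
        "  '%s' model: complete separation (all %d runs had 0%% of the other category normal)\n",
        x$training_category[i], x$n_runs[i]))
    } else {
      cat(sprintf(
        "  '%s' model: mean normal-rate ratio %.2f over %d runs (%d zero-denominator runs excluded)\n",
        x$training_category[i], x$mean_ratio[i],
        x$n_runs[i] - x$n_runs_excluded_zero[i], x$n_runs_excluded_zero[i]))
    }
  }
  invisible(x)
}
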