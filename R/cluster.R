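#' Divide subjects into k clusters
#'
#' `kmeans_divide()` runs Lloyd's algorithm from a k-means++ style seeding
#' (each new initial center drawn with probability proportional to squared
#' distance from the centers already chosen); `ward_divide()` cuts a Ward
#' agglomerative dendrogram (on Euclidean distances) at `k` clusters and is
#' fully deterministic.
#'
#' Both return a `cluster_division` carrying, per cluster: its size `n`,
#' the within-cluster proportion `q` of first-category subjects, the
#' disparity `P = max(q, 1 - q)`, and the across-cluster shares `f_c`
#' (fraction of all first-category subjects in the cluster) and `m_c`
#' (same for the second category) used by [same_cluster_chances()]. Note
#' the two different "proportions": `q` is within-cluster composition,
#' `f_c`/`m_c` are where each category's members live.
#'
#' @param coords Numeric matrix of subject coordinates (or an `embedding`).
#' @param category Factor with two levels, one per subject.
#' @param k Number of clusters.
#' @param seed Integer seed for the k-means++ initialization.
#' @return An object of class `cluster_division`: list with `assignments`,
#'   `k`, `algorithm`, `category`, and `composition` (per-cluster
#'   data.frame).
#' @examples
#' co <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 5), 20))
#' cat2 <- rep(c("a", "b"), each = 20)
#' kmeans_divide(co, cat2, k = 2, seed = 1)
#' @export
kmeans_divide <- function(coords, category, k, seed = 1L) {
  coords <- embedding_coords(coords)
  k <- as.integer(k)
  if (k > nrow(coords))
    stop("k exceeds the number of subjects", call. = FALSE)
  restore <- local_rng(seed)
  centers <- kmeanspp_init(coords, k)
  km <- suppressWarnings(
    stats::kmeans(coords, centers = centers, iter.max = 100L,
                  algorithm = "Lloyd"))
  restore()
  new_division(km$cluster, category, k, "kmeans")
}

# k-means++ seeding: first center uniform, each next center sampled with
# probability proportional to the squared distance to the nearest chosen
# center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- colSums((t(x) - centers[1L, ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) idx <- sample.int(n, 1L)
      else idx <- sample.int(n, 1L, prob = d2)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, colSums((t(x) - centers[j, ])^2))
    }
  }
  # jitter-free duplicate guard: collapse exact duplicates would break
  # stats::kmeans; nudge any repeated center toward a distinct point
  dup <- duplicated(centers)
  if (any(dup)) {
    pool <- x[!duplicated(x), , drop = FALSE]
    extra <- utils::head(pool[sample.int(nrow(pool)), , drop = FALSE],
                         sum(dup))
    centers[dup, ] <- extra
  }
  centers
}

#' @rdname kmeans_divide
#' @export
ward_divide <- function(coords, category, k) {
  coords <- embedding_coords(coords)
  k <- as.integer(k)
  if (k > nrow(coords))
    stop("k exceeds the number of subjects", call. = FALSE)
  hc <- stats::hclust(stats::dist(coords), method = "ward.D2")
  new_division(stats::cutree(hc, k = k), category, k, "ward")
}

embedding_coords <- function(x) {
  if (inherits(x, "embedding")) x$coords
  else if (inherits(x, "feature_table")) x$features
  else as.matrix(x)
}

new_division <- function(assignments, category, k, algorithm) {
  category <- factor(category)
  stopifnot(nlevels(category) == 2L,
            length(assignments) == length(category))
  assignments <- as.integer(factor(assignments))
  lev <- levels(category)
  n1 <- sum(category == lev[1L])
  n2 <- sum(category == lev[2L])
  comp <- do.call(rbind, lapply(sort(unique(assignments)), function(cl) {
    inc <- assignments == cl
    c1 <- sum(inc & category == lev[1L])
    c2 <- sum(inc & category == lev[2L])
    q <- c1 / (c1 + c2)
    data.frame(cluster = cl, n = c1 + c2, n_cat1 = c1, n_cat2 = c2,
               q = q, P = max(q, 1 - q), f = c1 / n1, m = c2 / n2)
  }))
  structure(list(assignments = assignments, k = k, algorithm = algorithm,
                 category = category, composition = comp),
            class = "cluster_division")
}

#' @export
print.cluster_division <- function(x, ...) {
  ch <- same_cluster_chances(x)
  cat(sprintf("<cluster_division> %s, k = %d\n", x$algorithm, x$k))
  print(x$composition, row.names = FALSE, digits = 3)
  cat(sprintf("  same-cluster chances: cross %.2f, within %.2f / %.2f\n",
              ch$fm, ch$ff, ch$mm))
  invisible(x)
}

#' Same-cluster chances for a division
#'
#' The probability that two subjects drawn at random (with replacement,
#' from the stated categories) land in the same cluster: with `f_c` and
#' `m_c` the across-cluster shares of the two categories,
#' `fm = sum_c f_c m_c`, `ff = sum_c f_c^2`, `mm = sum_c m_c^2`.
#' When one cross-category chance is much smaller than both within-category
#' chances, the division separates the categories; equality of the three
#' means category is irrelevant to cluster membership.
#'
#' @param div A `cluster_division`, or an assignment vector (with `groups`).
#' @param groups Optional two-level factor overriding the division's
#'   category (used, e.g., for the small/large brain split, see
#'   [icv_split_alignment()]).
#' @return An object of class `same_cluster_chances`: list with `fm`, `ff`,
#'   `mm`, and `levels`.
#' @examples
#' d <- structure(list(assignments = rep(1:2, c(6, 4)),
#'                     category = factor(rep(c("f", "m", "f", "m"),
#'                                           c(4, 2, 1, 3)))),
#'                class = "cluster_division")
#' # computed from across-cluster shares f = (0.8, 0.2), m = (0.4, 0.6)
#' same_cluster_chances(d)
#' @export
same_cluster_chances <- function(div, groups = NULL) {
  if (inherits(div, "cluster_division")) {
    assignments <- div$assignments
    if (is.null(groups)) groups <- div$category
  } else {
    assignments <- div
    if (is.null(groups)) stop("'groups' required", call. = FALSE)
  }
  groups <- factor(groups)
  stopifnot(nlevels(groups) == 2L, length(assignments) == length(groups))
  lev <- levels(groups)
  if (any(table(groups) == 0L))
    stop("both groups must be non-empty", call. = FALSE)
  cl <- sort(unique(assignments))
  f <- vapply(cl, function(c0) mean(assignments[groups == lev[1L]] == c0),
              numeric(1L))
  m <- vapply(cl, function(c0) mean(assignments[groups == lev[2L]] == c0),
              numeric(1L))
  structure(list(fm = sum(f * m), ff = sum(f^2), mm = sum(m^2),
                 levels = lev),
            class = "same_cluster_chances")
}

#' @export
print.same_cluster_chances <- function(x, ...) {
  cat(sprintf("same-cluster chances: %s&%s %.2f | %s&%s %.2f | %s&%s %.2f\n",
              x$levels[1L], x$levels[2L], x$fm,
              x$levels[1L], x$levels[1L], x$ff,
              x$levels[2L], x$levels[2L], x$mm))
  invisible(x)
}

#' Alignment of a division with the small/large brain split
#'
#' Recomputes [same_cluster_chances()] with the ICV median split (see
#' [split_by_icv_median()]) in place of the category labels, to ask whether
#' an unsupervised division is really separating large from small brains
#' rather than one category from the other.
#'
#' @param div A `cluster_division`.
#' @param split Factor with levels `small`/`large`, one per subject.
#' @return A `same_cluster_chances` object whose `levels` are
#'   `small`/`large`.
#' @export
icv_split_alignment <- function(div, split) {
  stopifnot(inherits(div, "cluster_division"))
  same_cluster_chances(div, groups = split)
}

#' Pick the most separating division
#'
#' Among candidate divisions, returns the one with the smallest
#' cross-category same-cluster chance `fm`. Exact ties are broken by the
#' larger absolute difference between the category shares of the largest
#' cluster, then by algorithm name order.
#'
#' @param divisions A list of `cluster_division` objects.
#' @return The selected `cluster_division`.
#' @export
best_separating <- function(divisions) {
  if (!length(divisions)) stop("empty division list", call. = FALSE)
  stopifnot(all(vapply(divisions, inherits, logical(1L),
                       "cluster_division")))
  fm <- vapply(divisions, function(d) same_cluster_chances(d)$fm,
               numeric(1L))
  sepbig <- vapply(divisions, function(d) {
    comp <- d$composition
    big <- which.max(comp$n)
    abs(comp$f[big] - comp$m[big])
  }, numeric(1L))
  algo <- vapply(divisions, `[[`, character(1L), "algorithm")
  ord <- order(fm, -sepbig, algo)
  divisions[[ord[1L]]]
}

#' Sweep divisions over cluster counts and algorithms
#'
#' Convenience wrapper running [kmeans_divide()] and/or [ward_divide()] for
#' every cluster count in `k_range`.
#'
#' @param coords Subject coordinates (matrix or `embedding`).
#' @param category Two-level factor, one entry per subject.
#' @param k_range Integer vector of cluster counts (default 2-10).
#' @param algorithms Subset of `c("kmeans", "ward")`.
#' @param seed Integer seed for the k-means initializations.
#' @return A list of `cluster_division` objects.
#' @export
cluster_sweep <- function(coords, category, k_range = 2:10,
                          algorithms = c("kmeans", "ward"), seed = 1L) {
  algorithms <- match.arg(algorithms, c("kmeans", "ward"),
                          several.ok = TRUE)
  out <- list()
  for (alg in algorithms) {
    for (k in k_range) {
      out[[length(out) + 1L]] <-
        if (alg == "kmeans") kmeans_divide(coords, category, k,
                                           seed = seed + k)
        else ward_divide(coords, category, k)
    }
  }
  out
}

#' Collect per-cluster disparity records from divisions
#'
#' @param divisions A list of `cluster_division` objects.
#' @return A data.frame with one row per cluster: `n`, `P`, `k`,
#'   `algorithm`.
#' @export
cluster_records <- function(divisions) {
  do.call(rbind, lapply(divisions, function(d)
    data.frame(n = d$composition$n, P = d$composition$P, k = d$k,
               algorithm = d$algorithm)))
}

#' Smooth mean and SD of sex disparity as a function of cluster size
#'
#' Models the disparity of a cluster of size n as drawn from a distribution
#' with mean p(n) and standard deviation s(n), and estimates both as smooth
#' functions of n by a Nadaraya-Watson (Gaussian-kernel) running mean and
#' SD over all clusters pooled from the supplied divisions.
#'
#' @param divisions A list of `cluster_division`s, or a data.frame from
#'   [cluster_records()] (columns `n`, `P`). At least 10 clusters are
#'   required for the smoother to be meaningful.
#' @param bandwidth Gaussian kernel bandwidth in cluster-size units;
#'   default 0.3 times the size range.
#' @param grid Evaluation grid for n; default 100 points over the size
#'   range.
#' @return An object of class `disparity_curve`: data.frame with columns
#'   `n`, `p_of_n`, `s_of_n`, plus attribute `bandwidth`.
#' @export
disparity_curve <- function(divisions, bandwidth = NULL, grid = NULL) {
  rec <- if (is.data.frame(divisions)) divisions
         else cluster_records(divisions)
  stopifnot(all(c("n", "P") %in% names(rec)))
  if (nrow(rec) < 10L)
    stop("need at least 10 clusters to estimate the disparity curve",
         call. = FALSE)
  rng <- range(rec$n)
  if (is.null(bandwidth)) bandwidth <- 0.3 * max(diff(rng), 1)
  if (bandwidth <= 0) stop("'bandwidth' must be positive", call. = FALSE)
  if (is.null(grid)) grid <- seq(rng[1L], rng[2L], length.out = 100L)
  p <- s <- numeric(length(grid))
  for (i in seq_along(grid)) {
    w <- stats::dnorm(rec$n, mean = grid[i], sd = bandwidth)
    w <- w / sum(w)
    p[i] <- sum(w * rec$P)
    s[i] <- sqrt(max(0, sum(w * rec$P^2) - p[i]^2))
  }
  structure(data.frame(n = grid, p_of_n = p, s_of_n = s),
            class = c("disparity_curve", "data.frame"),
            bandwidth = bandwidth)
}

#' @export
plot.disparity_curve <- function(x, ...) {
  graphics::plot(x$n, x$p_of_n, type = "l", ylim = c(0.45, 1),
                 xlab = "cluster size n", ylab = "disparity P", ...)
  graphics::lines(x$n, pmin(1, x$p_of_n + x$s_of_n), lty = 2)
  graphics::lines(x$n, pmax(0.5, x$p_of_n - x$s_of_n), lty = 2)
  invisible(x)
}
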