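#' Analysis grid configuration
#'
#' Bundles the sweep parameters shared by the anomaly-detection and
#' clustering stages. The defaults reproduce the canonical grids: nine
#' neighbor counts k = 10, 15, ..., 50; eight threshold percentiles 40, 45,
#' ..., 75; divisions into 2-10 clusters; QR tolerances mu = 1e-8, 1e-6,
#' 1e-4, 1e-2; and all six data representations.
#'
#' @param transforms Character vector of representation names, a subset of
#'   `c("zscore", "pca", "dm", "midm", "icpqr", "icpqrd")`.
#' @param k_values Integer vector of neighbor counts for the kNN stage.
#' @param threshold_percentiles Numeric vector of percentile thresholds in
#'   (0, 100).
#' @param n_clusters_range Integer vector of cluster counts for the
#'   unsupervised sweep.
#' @param mu Numeric vector of pivoted-QR truncation tolerances in (0, 1).
#' @param seed Integer seed used by stochastic stages.
#' @return An object of class `run_config` (a validated list).
#' @examples
#' cfg <- run_config()
#' length(cfg$k_values) * length(cfg$threshold_percentiles)  # 72
#' @export
run_config <- function(transforms = c("zscore", "pca", "dm", "midm",
                                      "icpqr", "icpqrd"),
                       k_values = seq(10L, 50L, by = 5L),
                       threshold_percentiles = seq(40, 75, by = 5),
                       n_clusters_range = 2:10,
                       mu = c(1e-8, 1e-6, 1e-4, 1e-2),
                       seed = 1L) {
  transforms <- match.arg(transforms,
                          c("zscore", "pca", "dm", "midm", "icpqr", "icpqrd"),
                          several.ok = TRUE)
  k_values <- as.integer(k_values)
  stopifnot(all(k_values >= 1L),
            all(threshold_percentiles > 0),
            all(threshold_percentiles < 100),
            all(n_clusters_range >= 1L),
            all(mu > 0), all(mu < 1))
  structure(list(transforms = transforms,
                 k_values = k_values,
                 threshold_percentiles = threshold_percentiles,
                 n_clusters_range = as.integer(n_clusters_range),
                 mu = mu,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  transforms:", paste(x$transforms, collapse = ", "), "\n")
  cat("  k:", paste(x$k_values, collapse = ", "), "\n")
  cat("  thresholds (%):", paste(x$threshold_percentiles, collapse = ", "),
      "\n")
  cat("  clusters:", paste(range(x$n_clusters_range), collapse = "-"),
      " mu:", paste(format(x$mu), collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
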