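#' Run the full two-category structure analysis
#'
#' End-to-end orchestration: generate (or accept) a feature table, balance
#' the categories, optionally apply the power-proportion size correction,
#' then run the requested stages - cross-category anomaly detection,
#' unsupervised cluster composition, supervised transfer (when the table
#' has at least two sites), and mosaicism profiling - and collect their
#' summaries into a single report. When `out_dir` is given, each stage's
#' tabular output is written as CSV and the report as JSON; a fixed seed
#' makes the whole report deterministic.
#'
#' @param data A [feature_table], or a preset name for [gen_preset()].
#' @param config A [run_config].
#' @param stages Character subset of
#'   `c("anomaly", "cluster", "supervised", "mosaic")`.
#' @param correct `"none"` or `"power-proportion"` (requires `icv`).
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param seed Integer seed; overrides `config$seed`.
#' @return An object of class `pipeline_report`: list with one entry per
#'   executed stage plus `provenance`.
#' @examples
#' \donttest{
#' rep <- run_pipeline("gendered_behaviors",
#'                     config = run_config(transforms = "zscore",
#'                                         k_values = c(10, 20),
#'                                         threshold_percentiles = c(50, 75)),
#'                     stages = c("anomaly", "cluster", "mosaic"))
#' rep
#' }
#' @export
run_pipeline <- function(data, config = run_config(),
                         stages = c("anomaly", "cluster", "supervised",
                                    "mosaic"),
                         correct = c("none", "power-proportion"),
                         out_dir = NULL, seed = config$seed) {
  stages <- match.arg(stages, c("anomaly", "cluster", "supervised",
                                "mosaic"), several.ok = TRUE)
  correct <- match.arg(correct)
  stopifnot(inherits(config, "run_config"))
  preset <- NULL
  if (is.character(data)) {
    preset <- data
    data <- gen_preset(preset, seed = seed)
  }
  stopifnot(inherits(data, "feature_table"))
  x <- balance_categories(data, seed = seed)
  if (correct == "power-proportion")
    x <- apply_power_proportion(x, fit_power_proportion(x))
  report <- list()

  if ("anomaly" %in% stages) {
    runs <- run_anomaly(x, config, seed = seed)
    report$anomaly <- list(summary = summarize_anomaly(runs), runs = runs)
  }
  if ("cluster" %in% stages) {
    z <- zscore_columns(x)
    divisions <- list()
    for (tr in config$transforms) {
      emb <- embed_features(z, tr, mu = config$mu[1L])
      divisions <- c(divisions,
                     cluster_sweep(emb, x$category,
                                   k_range = config$n_clusters_range,
                                   seed = seed))
    }
    two <- Filter(function(d) d$k == 2L, divisions)
    best <- best_separating(two)
    report$cluster <- list(
      divisions = divisions,
      best_two_cluster = best,
      best_chances = same_cluster_chances(best),
      curve = tryCatch(disparity_curve(divisions), error = function(e) NULL))
    if (!is.null(x$icv))
      report$cluster$icv_alignment <-
        icv_split_alignment(best, split_by_icv_median(x))
  }
  if ("supervised" %in% stages) {
    sites <- unique(x$site)
    if (length(sites) >= 2L) {
      # largest site is the reference; ties go to the first site encountered
      ref_site <- names(which.max(table(factor(x$site,
                                               levels = unique(x$site)))))
      agr <- list()
      for (s in setdiff(sites, ref_site)) {
        agr[[s]] <- transfer_protocol(
          x[x$site == ref_site], x[x$site == s],
          transform = config$transforms[1L], mu = config$mu[1L],
          seed = seed)
      }
      report$supervised <- list(reference_site = ref_site, transfers = agr)
    } else {
      report$supervised <- list(
        cv = cv_classify(zscore_columns(x), seed = seed))
    }
  }
  if ("mosaic" %in% stages) {
    prof <- profile_subjects(x)
    report$mosaic <- list(
      profiles = prof,
      consistency_counts = table(prof$consistency),
      majority = table(type = majority_type(prof), category = prof$category))
  }
  report$provenance <- list(
    preset = preset, seed = seed, correct = correct,
    stages = stages, n_subjects = nrow(x$features),
    n_features = ncol(x$features),
    package_version = as.character(utils::packageVersion("brainmosaic")))
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("<pipeline_report> %s%d subjects x %d features (seed %d)\n",
              if (is.null(pv$preset)) "" else paste0(pv$preset, ": "),
              pv$n_subjects, pv$n_features, pv$seed))
  if (!is.null(x$anomaly)) print(x$anomaly$summary)
  if (!is.null(x$cluster)) {
    cat(sprintf("Best-separating 2-cluster division (%s):\n",
                x$cluster$best_two_cluster$algorithm))
    print(x$cluster$best_chances)
  }
  if (!is.null(x$supervised) && !is.null(x$supervised$transfers)) {
    cat(sprintf("Supervised transfer from '%s':\n",
                x$supervised$reference_site))
    for (s in names(x$supervised$transfers))
      print(x$supervised$transfers[[s]]$agreement)
  }
  if (!is.null(x$mosaic)) {
    cat("Mosaic consistency counts:\n")
    print(x$mosaic$consistency_counts)
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$anomaly)) {
    utils::write.csv(report$anomaly$runs,
                     file.path(out_dir, "anomaly_runs.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$cluster)) {
    utils::write.csv(cluster_records(report$cluster$divisions),
                     file.path(out_dir, "cluster_records.csv"),
                     row.names = FALSE)
    if (!is.null(report$cluster$curve))
      utils::write.csv(as.data.frame(report$cluster$curve),
                       file.path(out_dir, "disparity_curve.csv"),
                       row.names = FALSE)
  }
  if (!is.null(report$mosaic))
    utils::write.csv(report$mosaic$profiles,
                     file.path(out_dir, "mosaic_profiles.csv"),
                     row.names = FALSE)
  json <- report_to_json(report)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

report_to_json <- function(report) {
  out <- list(provenance = report$provenance)
  if (!is.null(report$anomaly))
    out$anomaly <- as.data.frame(report$anomaly$summary)
  if (!is.null(report$cluster)) {
    ch <- report$cluster$best_chances
    out$cluster <- list(best_two_cluster = list(
      algorithm = report$cluster$best_two_cluster$algorithm,
      fm = ch$fm, ff = ch$ff, mm = ch$mm))
    if (!is.null(report$cluster$icv_alignment)) {
      ia <- report$cluster$icv_alignment
      out$cluster$icv_alignment <- list(sl = ia$fm, ss = ia$ff, ll = ia$mm)
    }
  }
  if (!is.null(report$supervised) && !is.null(report$supervised$transfers)) {
    out$supervised <- lapply(report$supervised$transfers, function(tr) {
      a <- tr$agreement
      list(a_self = a$a_self, a_ref = a$a_ref, A = a$A, U = a$U,
           P_max = a$P_max, flag_U = a$flag_U, flag_Pmax = a$flag_Pmax)
    })
  }
  if (!is.null(report$mosaic))
    out$mosaic <- as.list(report$mosaic$consistency_counts)
  out
}
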