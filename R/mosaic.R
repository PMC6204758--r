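#' Define per-feature female-end / male-end zones
#'
#' For each feature, the "end" zones are the score regions occupied by the
#' 33 percent most extreme members of each category, in that category's
#' direction. Concretely, with "male" the category whose mean is higher on
#' a feature: the male-end cut is the male distribution's 67th percentile
#' (scores at or beyond it are male-end), the female-end cut is the female
#' distribution's 33rd percentile (scores at or below it are female-end),
#' and the open interval between the cuts is "intermediate". Directions
#' flip per feature according to which category scores higher on average.
#' Quantiles use linear interpolation; zones are closed on the extreme
#' side.
#'
#' Here "female" denotes the first factor level of the category and "male"
#' the second; the terminology follows the human application but the
#' machinery is generic. If the cuts cross (possible when the category
#' distributions barely differ), the feature is flagged degenerate and all
#' its scores are classified intermediate, with a warning.
#'
#' @param x A [feature_table] with at least 3 subjects per category.
#' @return An object of class `zone_boundaries`: data.frame with one row
#'   per feature: `feature`, `direction` (level scoring higher),
#'   `female_end_cut`, `male_end_cut`, `degenerate`.
#' @seealso [profile_subjects()]
#' @export
define_zones <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  lev <- levels(x$category)
  if (any(table(x$category) < 3L))
    stop("need at least 3 subjects per category", call. = FALSE)
  f_rows <- x$category == lev[1L]
  m_rows <- x$category == lev[2L]
  res <- do.call(rbind, lapply(colnames(x$features), function(feat) {
    v <- x$features[, feat]
    male_higher <- mean(v[m_rows]) >= mean(v[f_rows])
    if (male_higher) {
      mc <- stats::quantile(v[m_rows], 0.67, names = FALSE)
      fc <- stats::quantile(v[f_rows], 0.33, names = FALSE)
      degen <- fc >= mc
    } else {
      mc <- stats::quantile(v[m_rows], 0.33, names = FALSE)
      fc <- stats::quantile(v[f_rows], 0.67, names = FALSE)
      degen <- fc <= mc
    }
    data.frame(feature = feat,
               direction = lev[if (male_higher) 2L else 1L],
               female_end_cut = fc, male_end_cut = mc,
               degenerate = degen)
  }))
  if (any(res$degenerate))
    warning(sprintf(
      "%d feature(s) with crossed zone cuts; their scores are all classified intermediate: %s",
      sum(res$degenerate),
      paste(utils::head(res$feature[res$degenerate], 5L), collapse = ", ")),
      call. = FALSE)
  rownames(res) <- NULL
  structure(res, class = c("zone_boundaries", "data.frame"),
            levels = lev)
}

#' Per-subject mosaic profiles
#'
#' Classifies every feature of every subject into exactly one zone
#' (female-end, male-end, or intermediate; see [define_zones()]) and counts
#' the zones per subject. A subject with at least one feature at each end
#' is a *mosaic*; a subject with end features on one side only is
#' *internally consistent* (`consistent_female` / `consistent_male`); a
#' subject with no end features at all is `all_intermediate`.
#'
#' @param x A [feature_table].
#' @param zones A `zone_boundaries` defined on the same features (defaults
#'   to zones computed from `x` itself).
#' @return An object of class `mosaic_profiles`: data.frame with one row
#'   per subject: `subject_id`, `category`, `n_female_end`, `n_male_end`,
#'   `n_intermediate`, `consistency`.
#' @examples
#' x <- gen_preset("gendered_behaviors", seed = 1)
#' table(profile_subjects(x)$consistency)
#' @export
profile_subjects <- function(x, zones = define_zones(x)) {
  stopifnot(inherits(x, "feature_table"),
            inherits(zones, "zone_boundaries"))
  if (!identical(colnames(x$features), zones$feature))
    stop("zone boundaries do not match the table's features", call. = FALSE)
  lev <- levels(x$category)
  n <- nrow(x$features)
  nf <- nm <- integer(n)
  for (j in seq_len(nrow(zones))) {
    v <- x$features[, j]
    if (zones$degenerate[j]) next
    if (zones$direction[j] == lev[2L]) {     # male-higher feature
      nm <- nm + (v >= zones$male_end_cut[j])
      nf <- nf + (v <= zones$female_end_cut[j])
    } else {
      nm <- nm + (v <= zones$male_end_cut[j])
      nf <- nf + (v >= zones$female_end_cut[j])
    }
  }
  p <- ncol(x$features)
  consistency <- ifelse(nf >= 1L & nm >= 1L, "mosaic",
                 ifelse(nf >= 1L, "consistent_female",
                 ifelse(nm >= 1L, "consistent_male", "all_intermediate")))
  out <- data.frame(subject_id = x$subject_id,
                    category = x$category,
                    n_female_end = as.integer(nf),
                    n_male_end = as.integer(nm),
                    n_intermediate = p - as.integer(nf) - as.integer(nm),
                    consistency = factor(consistency,
                                         levels = c("consistent_female",
                                                    "consistent_male",
                                                    "mosaic",
                                                    "all_intermediate")))
  class(out) <- c("mosaic_profiles", "data.frame")
  out
}

#' Majority-end typology of mosaic profiles
#'
#' Assigns each profile to one of two coarse types: `male_type` when it has
#' strictly more male-end than female-end features, `female_type` when it
#' has more (or the same number of) female-end features. The tie rule
#' (including the all-intermediate case) goes to `female_type`.
#'
#' @param profiles A `mosaic_profiles` data.frame (or any data.frame with
#'   `n_female_end` and `n_male_end` columns).
#' @return Factor with levels `female_type`, `male_type`.
#' @examples
#' majority_type(data.frame(n_female_end = c(3, 4, 0),
#'                          n_male_end = c(4, 3, 0)))
#' @export
majority_type <- function(profiles) {
  stopifnot(all(c("n_female_end", "n_male_end") %in% names(profiles)))
  factor(ifelse(profiles$n_male_end > profiles$n_female_end,
                "male_type", "female_type"),
         levels = c("female_type", "male_type"))
}

#' @export
print.mosaic_profiles <- function(x, ...) {
  cat(sprintf("<mosaic_profiles> %d subjects, %d features\n", nrow(x),
              x$n_female_end[1L] + x$n_male_end[1L] + x$n_intermediate[1L]))
  print(table(consistency = x$consistency, category = x$category))
  invisible(x)
}

#' Summary grid of mosaic profiles
#'
#' Counts subjects per (number of female-end, number of male-end) cell,
#' the bivariate scattergram view of mosaicism.
#'
#' @param object A `mosaic_profiles`.
#' @param ... Ignored.
#' @return A data.frame with `n_female_end`, `n_male_end`, and per-category
#'   counts.
#' @export
summary.mosaic_profiles <- function(object, ...) {
  agg <- stats::aggregate(
    list(count = rep(1L, nrow(object))),
    by = list(n_female_end = object$n_female_end,
              n_male_end = object$n_male_end,
              category = object$category),
    FUN = sum)
  agg[order(agg$n_female_end, agg$n_male_end), ]
}
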