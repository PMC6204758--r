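#' Column-wise z-score transformation
#'
#' Standardizes every feature to mean 0 and standard deviation 1
#' (denominator n - 1). This is the "raw" data representation of the
#' pipeline, and the harmonization step of the cross-sample transfer
#' protocol.
#'
#' @param x A [feature_table] or numeric matrix.
#' @return An object of the same class with standardized feature columns.
#' @examples
#' zscore_columns(matrix(c(1, 2, 3), 3, 1))
#' @export
zscore_columns <- function(x) {
  m <- if (inherits(x, "feature_table")) x$features else as.matrix(x)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  if (inherits(x, "feature_table")) { x$features <- z; x } else z
}

#' Fit the power-proportion (allometric) size correction
#'
#' For each volume feature v, fits the allometric exponent b as the ordinary
#' least-squares slope of log(v) on log(ICV), pooling both categories (the
#' correction is category-blind by design: fitting within category would
#' leak labels into a supposedly unsupervised preprocessing step). The
#' corrected volume is then v / ICV^b, which removes the log-log association
#' with overall size while preserving proportional (architectural)
#' differences between subjects.
#'
#' @param x A [feature_table] with positive `icv` and strictly positive
#'   feature values.
#' @return An object of class `power_proportion_fit` with per-feature
#'   exponents `b` and intercepts.
#' @seealso [apply_power_proportion()]
#' @export
fit_power_proportion <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (is.null(x$icv)) stop("'icv' metadata is required", call. = FALSE)
  v <- x$features
  if (any(v <= 0))
    stop("power-proportion correction requires strictly positive volumes",
         call. = FALSE)
  licv <- log(x$icv)
  lv <- log(v)
  xc <- licv - mean(licv)
  b <- colSums(xc * lv) / sum(xc^2)
  intercept <- colMeans(lv) - b * mean(licv)
  structure(list(b = stats::setNames(b, colnames(v)),
                 intercept = stats::setNames(intercept, colnames(v)),
                 features = colnames(v)),
            class = "power_proportion_fit")
}

#' @export
print.power_proportion_fit <- function(x, ...) {
  cat(sprintf("<power_proportion_fit> %d features, b in [%.3f, %.3f]\n",
              length(x$b), min(x$b), max(x$b)))
  invisible(x)
}

#' Apply a power-proportion correction
#'
#' Divides each volume by ICV raised to its fitted allometric exponent:
#' `corrected = v / ICV^b`.
#'
#' @param x A [feature_table] with `icv`.
#' @param fit A `power_proportion_fit` from [fit_power_proportion()], fitted
#'   on the same feature set.
#' @return A [feature_table] of corrected volumes.
#' @examples
#' sp <- preset_population("brain_volumes", n_per_category = 50)
#' x <- gen_population(sp)
#' xc <- apply_power_proportion(x, fit_power_proportion(x))
#' @export
apply_power_proportion <- function(x, fit) {
  stopifnot(inherits(x, "feature_table"),
            inherits(fit, "power_proportion_fit"))
  if (is.null(x$icv)) stop("'icv' metadata is required", call. = FALSE)
  if (!identical(colnames(x$features), fit$features))
    stop("feature names of table and fit do not match", call. = FALSE)
  x$features <- x$features / outer(x$icv, fit$b, `^`)
  x
}

#' Split subjects at the median intracranial volume
#'
#' Labels each subject `"large"` (ICV above the median) or `"small"` (ICV at
#' or below the median; ties go to small, a deterministic convention that is
#' immaterial for continuous volumes). Used to ask whether an unsupervised
#' division tracks overall size rather than category.
#'
#' @param x A [feature_table] with `icv`.
#' @return A factor with levels `small`, `large`, one per subject.
#' @examples
#' x <- feature_table(matrix(rnorm(8), 4), c("f", "f", "m", "m"),
#'                    icv = c(1, 2, 3, 4))
#' split_by_icv_median(x)
#' @export
split_by_icv_median <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  if (is.null(x$icv)) stop("'icv' metadata is required", call. = FALSE)
  med <- stats::median(x$icv)
  lab <- ifelse(x$icv > med, "large", "small")
  if (length(unique(lab)) < 2L)
    stop("degenerate ICV split: all subjects on one side of the median",
         call. = FALSE)
  factor(lab, levels = c("small", "large"))
}
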