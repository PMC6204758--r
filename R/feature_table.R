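#' Construct a feature table
#'
#' A `feature_table` bundles a numeric subjects-by-features matrix with the
#' per-subject metadata used throughout the pipeline: a binary category label
#' (e.g., female/male or one species vs. another), an optional acquisition
#' site, an optional total intracranial volume (ICV), and an optional age.
#'
#' @param features Numeric matrix, one row per subject, one named column per
#'   feature (regional volumes, cortical thicknesses, behavior scores, ...).
#'   No missing values are allowed; a cell that cannot be interpreted as a
#'   number is a hard error, never silently imputed.
#' @param category Vector coercible to a factor with exactly two levels, one
#'   entry per subject.
#' @param subject_id Character vector of unique subject identifiers. Defaults
#'   to the rownames of `features`, or `"S1", "S2", ...` when absent.
#' @param site Optional character vector of site labels (one per subject).
#' @param icv Optional positive numeric vector of total intracranial volumes.
#' @param age Optional numeric vector of ages in years.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `features`, `subject_id`, `category` (factor, two levels), `site`,
#'   `icv`, `age`.
#' @examples
#' x <- feature_table(matrix(rnorm(20), 10, 2,
#'                           dimnames = list(NULL, c("a", "b"))),
#'                    category = rep(c("female", "male"), each = 5))
#' x
#' @export
feature_table <- function(features, category, subject_id = NULL,
                          site = NULL, icv = NULL, age = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features))
    stop("'features' must be a numeric matrix", call. = FALSE)
  n <- nrow(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  if (anyDuplicated(colnames(features)))
    stop("feature names must be unique", call. = FALSE)
  if (anyNA(features)) {
    bad <- which(is.na(features), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in features at row %d, column '%s'",
                 bad[1L], colnames(features)[bad[2L]]), call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- rownames(features)
    if (is.null(subject_id)) subject_id <- paste0("S", seq_len(n))
  }
  subject_id <- as.character(subject_id)
  if (length(subject_id) != n || anyDuplicated(subject_id))
    stop("'subject_id' must be unique, one per row of 'features'",
         call. = FALSE)
  category <- factor(category)
  if (length(category) != n)
    stop("'category' must have one entry per subject", call. = FALSE)
  if (nlevels(category) != 2L)
    stop(sprintf("'category' must have exactly two levels, found %d",
                 nlevels(category)), call. = FALSE)
  if (!is.null(site)) {
    site <- as.character(site)
    if (length(site) != n) stop("'site' length mismatch", call. = FALSE)
  }
  if (!is.null(icv)) {
    icv <- as.numeric(icv)
    if (length(icv) != n) stop("'icv' length mismatch", call. = FALSE)
    if (anyNA(icv) || any(icv <= 0))
      stop("'icv' must be positive with no missing values", call. = FALSE)
  }
  if (!is.null(age)) {
    age <- as.numeric(age)
    if (length(age) != n) stop("'age' length mismatch", call. = FALSE)
  }
  rownames(features) <- subject_id
  structure(list(features = features, subject_id = subject_id,
                 category = category, site = site, icv = icv, age = age),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cnt <- table(x$category)
  cat(sprintf("<feature_table> %d subjects x %d features\n",
              nrow(x$features), ncol(x$features)))
  cat(sprintf("  category: %s\n",
              paste(sprintf("%s (n=%d)", names(cnt), cnt), collapse = ", ")))
  if (!is.null(x$site))
    cat(sprintf("  sites: %s\n",
                paste(sort(unique(x$site)), collapse = ", ")))
  cat(sprintf("  metadata: icv %s, age %s\n",
              if (is.null(x$icv)) "absent" else "present",
              if (is.null(x$age)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' @export
as.matrix.feature_table <- function(x, ...) x$features

#' Subset a feature table by subjects
#'
#' @param x A [feature_table].
#' @param i Row (subject) index: logical, integer, or subject-id character.
#' @param ... Ignored.
#' @return A [feature_table] restricted to the selected subjects.
#' @export
`[.feature_table` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$subject_id)
  feature_table(x$features[i, , drop = FALSE],
                category = x$category[i],
                subject_id = x$subject_id[i],
                site = if (!is.null(x$site)) x$site[i],
                icv = if (!is.null(x$icv)) x$icv[i],
                age = if (!is.null(x$age)) x$age[i])
}

#' Read a feature table from CSV/TSV files
#'
#' Reads a subjects-by-features table and a metadata table, aligns them on
#' `subject_id`, and validates the result. The feature file must have a
#' header row and a `subject_id` column (or row names in the first column);
#' the metadata file must have columns `subject_id` and `category`, and may
#' have `site`, `icv`, `age`.
#'
#' Any subject present in one file but not the other is an error listing the
#' offending identifiers; any non-numeric or missing feature cell is an error
#' naming its row and column. Subject order follows the feature file.
#'
#' @param path Path to the feature CSV/TSV (delimiter sniffed from the
#'   header line).
#' @param meta_path Path to the metadata CSV/TSV.
#' @param quiet Suppress the one-line load report.
#' @return A [feature_table].
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(path, meta_path, quiet = FALSE) {
  sniff <- function(p) {
    hdr <- readLines(p, n = 1L)
    if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  }
  feat <- utils::read.table(path, header = TRUE, sep = sniff(path),
                            colClasses = "character",
                            check.names = FALSE, stringsAsFactors = FALSE)
  meta <- utils::read.table(meta_path, header = TRUE, sep = sniff(meta_path),
                            check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- match("subject_id", names(feat))
  if (is.na(idcol)) idcol <- 1L
  ids <- as.character(feat[[idcol]])
  fmat <- as.matrix(feat[, -idcol, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(fmat), nrow(fmat), ncol(fmat),
                                 dimnames = dimnames(fmat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-numeric or missing feature value for subject '%s', column '%s'",
      ids[bad[1L]], colnames(num)[bad[2L]]), call. = FALSE)
  }
  if (!all(c("subject_id", "category") %in% names(meta)))
    stop("metadata must have columns 'subject_id' and 'category'",
         call. = FALSE)
  missing_meta <- setdiff(ids, meta$subject_id)
  missing_feat <- setdiff(meta$subject_id, ids)
  if (length(missing_meta))
    stop("subjects missing from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  if (length(missing_feat))
    stop("subjects missing from feature table: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  meta <- meta[match(ids, meta$subject_id), , drop = FALSE]
  out <- feature_table(num, category = meta$category, subject_id = ids,
                       site = if ("site" %in% names(meta)) meta$site,
                       icv = if ("icv" %in% names(meta)) meta$icv,
                       age = if ("age" %in% names(meta)) meta$age)
  if (!quiet) {
    cnt <- table(out$category)
    message(sprintf("loaded %d subjects (%s) x %d features", nrow(num),
                    paste(sprintf("%d %s", cnt, names(cnt)), collapse = ", "),
                    ncol(num)))
  }
  out
}

#' Write a feature table to CSV files
#'
#' Inverse of [read_feature_table()]: writes the feature matrix (with a
#' `subject_id` column) and the metadata to two CSV files at full precision,
#' so that a read/write round trip preserves all values exactly.
#'
#' @param x A [feature_table].
#' @param path,meta_path Output CSV paths.
#' @return Invisibly, `x`.
#' @export
write_feature_table <- function(x, path, meta_path) {
  feat <- data.frame(subject_id = x$subject_id,
                     format(x$features, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     check.names = FALSE)
  utils::write.csv(feat, path, row.names = FALSE, quote = FALSE)
  meta <- data.frame(subject_id = x$subject_id,
                     category = as.character(x$category))
  if (!is.null(x$site)) meta$site <- x$site
  if (!is.null(x$icv))
    meta$icv <- format(x$icv, digits = 17, trim = TRUE, scientific = TRUE)
  if (!is.null(x$age))
    meta$age <- format(x$age, digits = 17, trim = TRUE, scientific = TRUE)
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(x)
}

#' Balance the two categories by random subsampling
#'
#' Downsamples the larger category uniformly at random so both categories
#' have equal counts, mirroring standard practice of equating group sizes
#' before category-blind analyses so that base rates cannot masquerade as
#' structure. The smaller category is kept intact; subject order of the
#' retained rows is preserved. Deterministic for a fixed seed; an already
#' balanced table is returned unchanged.
#'
#' @param x A [feature_table].
#' @param seed Integer seed for the subsampling draw.
#' @return A [feature_table] with equal category counts.
#' @examples
#' x <- feature_table(matrix(rnorm(12), 6), rep(c("f", "m"), c(4, 2)))
#' table(balance_categories(x, seed = 1)$category)
#' @export
balance_categories <- function(x, seed = 1L) {
  stopifnot(inherits(x, "feature_table"))
  cnt <- table(x$category)
  if (any(cnt == 0L))
    stop("both categories must be non-empty", call. = FALSE)
  if (cnt[1L] == cnt[2L]) return(x)
  big <- names(cnt)[which.max(cnt)]
  keep_n <- min(cnt)
  idx_big <- which(x$category == big)
  rng <- local_rng(seed)
  drop <- sample(idx_big, length(idx_big) - keep_n)
  rng()
  x[sort(setdiff(seq_len(nrow(x$features)), drop))]
}

# Scoped RNG: set the seed, return a restorer for the caller's RNG state.
# All stochastic operations in the package funnel through this so a single
# integer seed fixes every draw without clobbering the user's session RNG.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
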