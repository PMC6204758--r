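#' Cross-validated supervised separation
#'
#' Stratified k-fold cross-validation of a two-category classifier: a
#' linear-kernel support vector machine or a random forest (500 trees).
#' Reports the percent of each category correctly classified, the overall
#' rate, and the per-subject cross-validated predictions (used downstream
#' by the model-agreement analysis).
#'
#' @param x A [feature_table], `embedding`, or numeric matrix of
#'   coordinates.
#' @param category Two-level factor; taken from `x` when it is a
#'   [feature_table].
#' @param algo `"svm_linear"` or `"random_forest"`.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for fold assignment and the forest.
#' @return An object of class `cv_result`: list with `rates` (named percent
#'   correct per category), `overall`, `predictions` (factor), `truth`,
#'   `algo`, `folds`.
#' @examples
#' x <- gen_preset("gendered_behaviors", seed = 2)
#' cv_classify(x, folds = 5)
#' @export
cv_classify <- function(x, category = NULL,
                        algo = c("svm_linear", "random_forest"),
                        folds = 10L, seed = 1L) {
  algo <- match.arg(algo)
  if (inherits(x, "feature_table")) {
    if (is.null(category)) category <- x$category
    coords <- x$features
  } else coords <- embedding_coords(x)
  category <- factor(category)
  stopifnot(nlevels(category) == 2L, folds >= 2L,
            length(category) == nrow(coords))
  if (min(table(category)) < folds)
    stop("each category must have at least one subject per fold",
         call. = FALSE)
  restore <- local_rng(seed)
  on.exit(restore())
  fold_of <- integer(length(category))
  for (lv in levels(category)) {
    idx <- which(category == lv)
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  pred <- factor(rep(NA_character_, length(category)),
                 levels = levels(category))
  for (f in seq_len(folds)) {
    hold <- fold_of == f
    fit <- fit_classifier(coords[!hold, , drop = FALSE], category[!hold],
                          algo)
    pred[hold] <- predict_classifier(fit, coords[hold, , drop = FALSE])
  }
  rates <- vapply(levels(category), function(lv)
    100 * mean(pred[category == lv] == lv), numeric(1L))
  structure(list(rates = rates, overall = 100 * mean(pred == category),
                 predictions = pred, truth = category, algo = algo,
                 folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-fold CV\n", x$algo, x$folds))
  cat(sprintf("  %% correct: %s; overall %.1f%%\n",
              paste(sprintf("%s %.1f", names(x$rates), x$rates),
                    collapse = ", "), x$overall))
  invisible(x)
}

fit_classifier <- function(coords, category, algo) {
  if (algo == "svm_linear")
    e1071::svm(coords, factor(category), kernel = "linear", scale = FALSE)
  else
    randomForest::randomForest(coords, factor(category), ntree = 500L)
}

predict_classifier <- function(fit, coords) {
  stats::predict(fit, coords)
}

#' Cross-sample transfer of a category classifier
#'
#' Implements the harmonize-then-transfer protocol: each sample is
#' z-scored separately, the two are concatenated and z-scored again, the
#' chosen representation is fitted on the combined data, a classifier is
#' trained on the reference sample, and its correctness is evaluated on the
#' test sample (optionally restricted to an age window first). A model is
#' also cross-validated on the test sample itself, and the two models'
#' classifications of the same test subjects are compared via
#' [agreement_stats()].
#'
#' @param ref,test [feature_table]s with identical feature sets.
#' @param transform Representation name, see [embed_features()].
#' @param mu QR tolerance for the pivoted-QR representations.
#' @param age_window Optional length-2 numeric; test subjects outside
#'   `[age_window[1], age_window[2]]` are dropped before evaluation.
#' @param algo Classifier, as in [cv_classify()].
#' @param folds CV folds for the test sample's own model.
#' @param seed Integer seed.
#' @return An object of class `transfer_result`: list with `rates_ref_model`
#'   (per-category percent of test subjects correctly classified by the
#'   reference-sample model), `self_cv` (the test sample's own
#'   `cv_result`), and `agreement` (an `agreement_stats`).
#' @export
transfer_protocol <- function(ref, test, transform = "zscore", mu = 1e-4,
                              age_window = NULL,
                              algo = c("svm_linear", "random_forest"),
                              folds = 10L, seed = 1L) {
  algo <- match.arg(algo)
  stopifnot(inherits(ref, "feature_table"), inherits(test, "feature_table"))
  if (!identical(colnames(ref$features), colnames(test$features)))
    stop("reference and test samples must share the same feature set",
         call. = FALSE)
  zr <- zscore_columns(ref$features)
  zt <- zscore_columns(test$features)
  combined <- zscore_columns(rbind(zr, zt))
  emb <- embed_features(combined, transform, mu = mu)
  n_ref <- nrow(zr)
  co_ref <- emb$coords[seq_len(n_ref), , drop = FALSE]
  co_test <- emb$coords[-seq_len(n_ref), , drop = FALSE]
  keep <- rep(TRUE, nrow(co_test))
  if (!is.null(age_window)) {
    if (is.null(test$age)) stop("'test' has no age metadata", call. = FALSE)
    keep <- test$age >= age_window[1L] & test$age <= age_window[2L]
    if (!any(keep)) stop("age window excludes every test subject",
                         call. = FALSE)
  }
  co_test <- co_test[keep, , drop = FALSE]
  truth <- factor(test$category[keep], levels = levels(ref$category))

  fit_ref <- local({
    restore <- local_rng(seed)
    on.exit(restore())
    fit_classifier(co_ref, ref$category, algo)
  })
  pred_ref <- predict_classifier(fit_ref, co_test)
  rates_ref <- vapply(levels(truth), function(lv)
    100 * mean(pred_ref[truth == lv] == lv), numeric(1L))
  self_cv <- cv_classify(co_test, truth, algo = algo, folds = folds,
                         seed = seed + 1L)
  agr <- agreement_stats(pred_ref, self_cv$predictions, truth)
  structure(list(transform = transform, algo = algo,
                 rates_ref_model = rates_ref, self_cv = self_cv,
                 agreement = agr, n_test = sum(keep)),
            class = "transfer_result")
}

#' @export
print.transfer_result <- function(x, ...) {
  cat(sprintf("<transfer_result> %s on '%s' representation, %d test subjects\n",
              x$algo, x$transform, x$n_test))
  cat(sprintf("  reference-model %% correct on test: %s\n",
              paste(sprintf("%s %.1f", names(x$rates_ref_model),
                            x$rates_ref_model), collapse = ", ")))
  print(x$agreement)
  invisible(x)
}

#' Agreement between two classifiers of the same subjects
#'
#' Given the labels assigned to the same subjects by a reference-sample
#' model and by the test sample's own cross-validated model, computes the
#' observed percent agreement A together with two closed-form benchmarks
#' derived from the models' correctness rates `a_self` and `a_ref` (in
#' percent):
#' \deqn{U = (a_{self} a_{ref} + (100 - a_{self})(100 - a_{ref})) / 100,}
#' the agreement expected if the two models' correct/incorrect indicators
#' were statistically independent, and
#' \deqn{P_{max} = 100 - |a_{self} - a_{ref}|,}
#' the maximum agreement possible given the two correctness rates (reached
#' when the "female"/"male" regions of the two models overlap as completely
#' as the rates allow). A near U and far below P_max means the two models
#' carve the test sample differently even when both beat chance.
#' Two-sided exact binomial tests compare the observed agreement count
#' against U/100 and against P_max/100.
#'
#' @param labels_ref_model,labels_self_model Factors over the same
#'   subjects.
#' @param truth The true category labels of those subjects.
#' @return An object of class `agreement_stats`: list with `a_self`,
#'   `a_ref`, `A`, `U`, `P_max` (all percent), `n`, `p_vs_U`, `p_vs_Pmax`,
#'   and printable significance flags.
#' @examples
#' # correctness rates 53% and 71% give U = 51, P_max = 82
#' agreement_closed_forms(53, 71)
#' @export
agreement_stats <- function(labels_ref_model, labels_self_model, truth) {
  if (length(labels_ref_model) != length(truth) ||
      length(labels_self_model) != length(truth))
    stop("label vectors must align over the same subjects", call. = FALSE)
  n <- length(truth)
  a_self <- 100 * mean(labels_self_model == truth)
  a_ref <- 100 * mean(labels_ref_model == truth)
  agree <- sum(labels_ref_model == labels_self_model)
  cf <- agreement_closed_forms(a_self, a_ref)
  p_u <- stats::binom.test(agree, n, min(cf$U, 100) / 100)$p.value
  p_p <- stats::binom.test(agree, n, min(cf$P_max, 100) / 100)$p.value
  structure(list(a_self = a_self, a_ref = a_ref, A = 100 * agree / n,
                 U = cf$U, P_max = cf$P_max, n = n,
                 p_vs_U = p_u, p_vs_Pmax = p_p,
                 flag_U = sig_flag(p_u), flag_Pmax = sig_flag(p_p)),
            class = "agreement_stats")
}

#' Closed-form agreement benchmarks
#'
#' @param a_self,a_ref Correctness rates in percent.
#' @return List with `U` (independence expectation) and `P_max` (maximum
#'   possible agreement), both in percent.
#' @rdname agreement_stats
#' @export
agreement_closed_forms <- function(a_self, a_ref) {
  list(U = (a_self * a_ref + (100 - a_self) * (100 - a_ref)) / 100,
       P_max = 100 - abs(a_self - a_ref))
}

sig_flag <- function(p) if (p < 0.01) "2" else if (p < 0.05) "1" else "ns"

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "  agreement: Self %.0f | Ref %.0f | U %.0f | Pmax %.0f | A %.0f (vs U: %s, vs Pmax: %s)\n",
    x$a_self, x$a_ref, x$U, x$P_max, x$A, x$flag_U, x$flag_Pmax))
  invisible(x)
}
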