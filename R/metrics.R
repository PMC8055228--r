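#' Balanced accuracy
#'
#' Unweighted mean of per-class recall: each class contributes equally
#' regardless of its prevalence, so a constant predictor on a two-class
#' problem scores 0.5 however imbalanced the classes are. The classes are
#' those present in `y_true`.
#'
#' @param y_true,y_pred Equal-length label vectors (any atomic type).
#' @return A score in \[0, 1\].
#' @examples
#' balanced_accuracy(c(0, 0, 1, 1, 1), c(0, 1, 1, 1, 0)) # (1/2 + 2/3) / 2
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0) abort("empty label vectors.")
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length.")
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  recalls <- vapply(classes, function(cl) {
    sel <- y_true == cl
    mean(y_pred[sel] == cl)
  }, numeric(1))
  mean(recalls)
}

#' Relative balanced-accuracy regret
#'
#' The relative distance of a score from the best known score for its
#' dataset: `(ba_best - ba) / ba_best`. Zero at the optimum; undefined (an
#' error) when the best score is zero.
#'
#' @param ba_best Best known score for the dataset (must be > 0).
#' @param ba Score achieved by a recommendation.
#' @return The relative gap (vectorized over `ba`).
#' @examples
#' delta_ba(0.8, 0.6) # 0.25
#' @export
delta_ba <- function(ba_best, ba) {
  if (any(ba_best <= 0)) {
    abort("`ba_best` must be positive; the relative gap is undefined at 0.")
  }
  (ba_best - ba) / ba_best
}

#' Fraction of datasets solved to within a relative threshold
#'
#' A dataset counts as a success when the best configuration recommended for
#' it so far scores within `threshold` (relative regret, e.g. 0.01 or 0.05)
#' of the best known configuration for that dataset. Datasets with no
#' recommendations yet count as failures, so the rate starts at 0 and can
#' only grow as recommendations accumulate.
#'
#' @param achieved Data frame with columns `dataset` and `best_achieved`
#'   (best held-out score among configurations recommended so far); at most
#'   one row per dataset, datasets without recommendations omitted.
#' @param kb_best Data frame with columns `dataset` and `best_score`
#'   (the reference optima, e.g. from [kb_best_scores()]); defines the
#'   denominator.
#' @param threshold Relative optimality threshold in (0, 1).
#' @return Fraction of `kb_best` datasets at success, in \[0, 1\].
#' @export
success_rate <- function(achieved, kb_best, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie strictly between 0 and 1.")
  }
  if (nrow(kb_best) == 0) abort("`kb_best` is empty.")
  unknown <- setdiff(achieved$dataset, kb_best$dataset)
  if (length(unknown) > 0) {
    abort(paste0("dataset(s) absent from `kb_best`: ",
                 paste(unknown, collapse = ", ")))
  }
  if (nrow(achieved) == 0) return(0)
  hit <- dplyr::inner_join(achieved, kb_best, by = "dataset")
  gaps <- delta_ba(hit$best_score, hit$best_achieved)
  sum(gaps <= threshold) / nrow(kb_best)
}
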