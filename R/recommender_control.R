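# Control strategies: uniform-random recommendation (the floor any learning
# strategy must beat) and a cheating oracle that ranks by true held-out
# scores (the ceiling; a test instrument, never a deployable strategy).

#' @export
recommend.rec_random <- function(rec, dataset, n = 1L, candidates = NULL,
                                 exclude = character(), seed = NULL, ...) {
  stopifnot(n >= 1)
  cand <- rec_candidates(rec, dataset, candidates, exclude)
  if (length(cand) == 0) {
    warn(sprintf("no candidate configurations left for dataset '%s'.", dataset))
    return(rec_empty_recs(dataset))
  }
  if (length(cand) < n) {
    warn(sprintf("only %d candidate(s) left for dataset '%s' (requested %d).",
                 length(cand), dataset, n))
  }
  seed <- seed %||% derive_seed(rec$seed, rec$n_updates, "random")
  picks <- with_seed(seed, sample(cand, min(n, length(cand))))
  tibble::tibble(rank = seq_along(picks), dataset = dataset,
                 config_id = picks, r_hat = NA_real_,
                 note = "random")
}

#' @export
predict_ratings.rec_random <- function(rec, dataset, config_ids, ...) {
  abort("the random control has no rating model; use recommend().")
}

#' @export
recommend.rec_oracle <- function(rec, dataset, n = 1L, candidates = NULL,
                                 exclude = character(), seed = NULL, ...) {
  stopifnot(n >= 1)
  truth <- rec$opts$truth
  if (is.null(truth)) abort("oracle strategy needs a `truth` ratings table.")
  if (inherits(truth, "ml_kb") && "split" %in% names(truth)) {
    truth <- truth[truth$split == "holdout", ]
  }
  cand <- rec_candidates(rec, dataset, candidates, exclude)
  if (length(cand) == 0) {
    warn(sprintf("no candidate configurations left for dataset '%s'.", dataset))
    return(rec_empty_recs(dataset))
  }
  rows <- truth[truth$dataset == dataset & truth$config_id %in% cand, ]
  preds <- pred_frame(dataset, rows$config_id, rows$score, "oracle")
  rank_predictions(preds, n)
}

#' @export
predict_ratings.rec_oracle <- function(rec, dataset, config_ids, ...) {
  truth <- rec$opts$truth
  if (inherits(truth, "ml_kb") && "split" %in% names(truth)) {
    truth <- truth[truth$split == "holdout", ]
  }
  key <- paste(truth$dataset, truth$config_id, sep = "\r")
  hit <- match(paste(dataset, config_ids, sep = "\r"), key)
  pred_frame(dataset, config_ids, truth$score[hit], "oracle")
}
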