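#' Create a recommender
#'
#' A recommender learns online from experiment results (ratings of algorithm
#' configurations on datasets) and, on request, ranks configurations it
#' expects to score well on a given dataset. All strategies share one
#' interface — [rec_update()] to absorb new results and [recommend()] to rank
#' unseen configurations — so they are interchangeable in the evaluation
#' loop.
#'
#' Strategies:
#' \describe{
#'   \item{`svd`}{Biased matrix factorization trained by stochastic gradient
#'     descent; predicts `mu + b_a + b_d + q_a . p_d`. The main model; see
#'     the package vignette. Options: `k` (latent dimension, default 40),
#'     `gamma` (learning rate, 0.01), `lambda` (regularization, 0.02),
#'     `epochs_per_result` (online epoch proportionality, 1), `min_epochs`
#'     (10), `init_sd` (factor initialization sd, 0.1).}
#'   \item{`knn-data`}{Dataset-neighborhood model: mean-centered ratings of
#'     the most similar datasets (shrunk Pearson similarity over co-rated
#'     configurations). Options: `k_neighbors` (10), `shrinkage` (10),
#'     `min_support` (1).}
#'   \item{`knn-ml`}{Item-based analogue of `knn-data`: neighbors are
#'     configurations, similarity over co-rating datasets.}
#'   \item{`knn-meta`}{Metalearning cold-start strategy: recommends the
#'     best-scoring configurations of the `k_neighbors` datasets nearest in
#'     metafeature space. Requires a `metafeatures` cache tibble. Option
#'     `k_neighbors` (5).}
#'   \item{`slopeone`}{Slope-one: average deviations between co-rated
#'     configuration pairs.}
#'   \item{`coclustering`}{Co-clustering of datasets and configurations with
#'     within-cluster mean prediction. Options: `n_dataset_clusters` (3),
#'     `n_config_clusters` (3), `n_iter` (20), `n_init` (5).}
#'   \item{`mean`}{Control: per-configuration mean rating across datasets.}
#'   \item{`random`}{Control: uniform sampling without replacement from the
#'     candidate set.}
#'   \item{`oracle`}{Test instrument that cheats by ranking candidates with a
#'     supplied table of true held-out ratings (`truth` option); used to
#'     upper-bound achievable performance in simulations and tests.}
#' }
#'
#' @param strategy One of `"svd"`, `"knn-data"`, `"knn-ml"`, `"knn-meta"`,
#'   `"slopeone"`, `"coclustering"`, `"mean"`, `"random"`, `"oracle"`.
#' @param ... Strategy options (see Details).
#' @param seed Session seed from which all of the recommender's internal
#'   randomness (factor initialization, epoch shuffles, random sampling) is
#'   derived.
#' @return An object of class `c("rec_<strategy>", "recommender")`.
#' @examples
#' kb <- simulate_kb(n_datasets = 6, n_configs = 12, seed = 1)$kb
#' rec <- recommender("mean") |>
#'   rec_update(dplyr::filter(kb, split == "cv"))
#' recommend(rec, dataset = "d01", n = 3)
#' @export
recommender <- function(strategy = c("svd", "knn-data", "knn-ml", "knn-meta",
                                     "slopeone", "coclustering", "mean",
                                     "random", "oracle"),
                        ..., seed = 1L) {
  strategy <- match.arg(strategy)
  cls <- paste0("rec_", gsub("-", "_", strategy))
  defaults <- switch(strategy,
    "svd" = list(k = 40L, gamma = 0.01, lambda = 0.02,
                 epochs_per_result = 1, min_epochs = 10L, init_sd = 0.1),
    "knn-data" = ,
    "knn-ml" = list(k_neighbors = 10L, shrinkage = 10, min_support = 1L),
    "knn-meta" = list(k_neighbors = 5L, metafeatures = NULL),
    "coclustering" = list(n_dataset_clusters = 3L, n_config_clusters = 3L,
                          n_iter = 20L, n_init = 5L),
    list()
  )
  opts <- modifyList(defaults, list(...))
  unknown <- setdiff(names(opts), c(names(defaults), "truth"))
  if (strategy != "oracle" && length(unknown) > 0) {
    abort(paste0("unknown option(s) for strategy '", strategy, "': ",
                 paste(unknown, collapse = ", ")))
  }
  rec <- structure(
    list(
      strategy = strategy,
      seed = as.integer(seed),
      n_updates = 0L,
      ratings = tibble::tibble(dataset = character(), config_id = character(),
                               score = double()),
      opts = opts,
      state = list()
    ),
    class = c(cls, "recommender")
  )
  rec
}

#' @export
print.recommender <- function(x, ...) {
  cat(sprintf("<recommender: %s> %d rating(s) over %d dataset(s) x %d configuration(s), %d update(s)\n",
              x$strategy, nrow(x$ratings), length(unique(x$ratings$dataset)),
              length(unique(x$ratings$config_id)), x$n_updates))
  invisible(x)
}

#' Feed new experiment results to a recommender
#'
#' Online update: the recommender absorbs a batch of newly scored
#' (dataset, configuration) pairs and returns its updated self. Model
#' parameters persist between updates, so a recommender can be trained
#' incrementally as results stream in. Ratings for an already-known key
#' replace the stored value (latest wins).
#'
#' @param rec A [recommender()].
#' @param results Data frame of new results with columns `dataset`, `score`
#'   in \[0, 1\] and either `config_id` or `algorithm` (+ optional
#'   `parameters` JSON). An `ml_kb` may be passed directly; only its `"cv"`
#'   rows are used, and a message is emitted if other splits were present.
#' @param ... Passed to methods.
#' @return The updated recommender.
#' @export
rec_update <- function(rec, results, ...) {
  UseMethod("rec_update")
}

# Normalize a results batch to (dataset, config_id, score) and range-check.
rec_results_frame <- function(results) {
  if (!is.data.frame(results) || nrow(results) == 0) {
    abort("`results` must be a non-empty data frame.")
  }
  if (inherits(results, "ml_kb") && "split" %in% names(results) &&
      any(results$split != "cv")) {
    results <- results[results$split == "cv", ]
    inform("rec_update: using only 'cv' rows; holdout scores are never shown to a recommender.")
    if (nrow(results) == 0) abort("`results` contains no 'cv' rows.")
  }
  if (!"config_id" %in% names(results)) {
    if (!"algorithm" %in% names(results)) {
      abort("`results` needs a `config_id` or `algorithm` column.")
    }
    params <- if ("parameters" %in% names(results)) results$parameters else "{}"
    params <- rep_len(params, nrow(results))
    results$config_id <- vapply(seq_len(nrow(results)), function(i) {
      config_id(results$algorithm[i], parse_params(params[i]))
    }, character(1))
  }
  if (!all(c("dataset", "score") %in% names(results))) {
    abort("`results` needs `dataset` and `score` columns.")
  }
  if (!is.numeric(results$score) ||
      any(!is.finite(results$score) | results$score < 0 | results$score > 1)) {
    abort("all scores must be finite and in [0, 1]; nothing was updated.")
  }
  tibble::tibble(dataset = as.character(results$dataset),
                 config_id = as.character(results$config_id),
                 score = as.double(results$score))
}

merge_ratings <- function(old, new) {
  key_old <- paste(old$dataset, old$config_id, sep = "\r")
  key_new <- paste(new$dataset, new$config_id, sep = "\r")
  new <- new[!duplicated(key_new, fromLast = TRUE), ]
  key_new <- key_new[!duplicated(key_new, fromLast = TRUE)]
  hit <- match(key_new, key_old)
  replace <- !is.na(hit)
  if (any(replace)) old$score[hit[replace]] <- new$score[replace]
  dplyr::bind_rows(old, new[!replace, ])
}

#' @export
rec_update.recommender <- function(rec, results, ...) {
  new <- rec_results_frame(results)
  rec$ratings <- merge_ratings(rec$ratings, new)
  rec$n_updates <- rec$n_updates + 1L
  rec
}

#' Predict ratings for (dataset, configuration) pairs
#'
#' Raw model predictions, unclamped: residual computations must see the
#' model's actual output, so clamping to \[0, 1\] happens only when
#' predictions are surfaced by [recommend()].
#'
#' @param rec A trained [recommender()].
#' @param dataset A single dataset id.
#' @param config_ids Character vector of configuration ids.
#' @param ... Passed to methods.
#' @return A tibble with columns `dataset`, `config_id`, `r_hat` and `note`
#'   (`NA` or the fallback used, e.g. `"mean_fallback"`, `"global_mean"`).
#' @export
predict_ratings <- function(rec, dataset, config_ids, ...) {
  UseMethod("predict_ratings")
}

pred_frame <- function(dataset, config_ids, r_hat, note = NA_character_) {
  tibble::tibble(dataset = dataset, config_id = config_ids,
                 r_hat = r_hat, note = rep_len(note, length(config_ids)))
}

#' Rank configurations for a dataset
#'
#' Ranks the candidate configurations by predicted rating, best first, and
#' returns the top `n`. The candidate set excludes configurations already
#' rated for the dataset (the recommender has nothing to learn from
#' re-running them) and anything in `exclude` — the caller's record of pairs
#' already recommended this session, which enforces the rule that no
#' (dataset, configuration) pair is ever recommended twice. Ties in
#' predicted rating break lexicographically on `config_id` so rankings are
#' reproducible across platforms. Surfaced predictions are clamped to
#' \[0, 1\].
#'
#' @param rec A trained [recommender()].
#' @param dataset Dataset id to recommend for (may be unseen: cold start).
#' @param n Number of recommendations requested.
#' @param candidates Character vector of candidate configuration ids;
#'   `NULL` uses every configuration the recommender has seen a rating for.
#' @param exclude Configuration ids to exclude (already recommended).
#' @param seed Optional seed override for stochastic strategies (`random`);
#'   defaults to a stream derived from the recommender's session seed.
#' @param ... Passed to methods.
#' @return A tibble with columns `rank` (1..n), `dataset`, `config_id`,
#'   `r_hat`, `note`; fewer than `n` rows (with a warning) iff the candidate
#'   set is smaller than `n`, and zero rows (with a warning, not an error)
#'   if it is exhausted.
#' @export
recommend <- function(rec, dataset, n = 1L, candidates = NULL,
                      exclude = character(), seed = NULL, ...) {
  UseMethod("recommend")
}

rec_candidates <- function(rec, dataset, candidates, exclude) {
  if (is.null(candidates)) candidates <- unique(rec$ratings$config_id)
  rated <- rec$ratings$config_id[rec$ratings$dataset == dataset]
  sort(setdiff(candidates, union(exclude, rated)))
}

rec_empty_recs <- function(dataset) {
  tibble::tibble(rank = integer(), dataset = character(),
                 config_id = character(), r_hat = double(),
                 note = character())
}

rank_predictions <- function(preds, n) {
  preds <- preds[order(-preds$r_hat, preds$config_id, method = "radix"), ]
  preds <- head(preds, n)
  tibble::tibble(rank = seq_len(nrow(preds)), dataset = preds$dataset,
                 config_id = preds$config_id,
                 r_hat = clamp01(preds$r_hat), note = preds$note)
}

#' @export
recommend.recommender <- function(rec, dataset, n = 1L, candidates = NULL,
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
  preds <- predict_ratings(rec, dataset, cand)
  rank_predictions(preds, n)
}
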