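# Metalearning (knn-meta) strategy: pure cold-start recommender. It ignores
# the target dataset's own ratings entirely and instead recommends the
# best-scoring configurations of the datasets nearest in metafeature space —
# strong before any feedback exists, but unable to exploit feedback, which
# is exactly the trade-off it is included to expose.

#' @export
recommend.rec_knn_meta <- function(rec, dataset, n = 1L, candidates = NULL,
                                   exclude = character(), seed = NULL, ...) {
  stopifnot(n >= 1)
  cache <- rec$opts$metafeatures
  if (is.null(cache) || !is.data.frame(cache)) {
    abort("knn-meta needs a `metafeatures` cache; run compute_metafeatures() over your datasets and pass the cache to recommender().")
  }
  if (!dataset %in% cache$dataset) {
    abort(sprintf("no metafeatures cached for dataset '%s'; run compute_metafeatures() on it first.", dataset))
  }
  rated_sets <- setdiff(intersect(unique(rec$ratings$dataset), cache$dataset),
                        dataset)
  if (length(rated_sets) == 0) {
    abort("knn-meta needs metafeatures for at least one rated dataset.")
  }
  scaling <- metafeature_scaling(cache)
  target <- cache[cache$dataset == dataset, ][1, ]
  dists <- vapply(rated_sets, function(d) {
    metafeature_distance(target, cache[cache$dataset == d, ][1, ], scaling)
  }, numeric(1))
  nb <- rated_sets[order(dists, rated_sets)][seq_len(min(rec$opts$k_neighbors,
                                                         length(rated_sets)))]
  pool <- rec$ratings[rec$ratings$dataset %in% nb, ]
  cand <- rec_candidates(rec, dataset, candidates, exclude)
  pool <- pool[pool$config_id %in% cand, ]
  if (nrow(pool) == 0) {
    warn(sprintf("no candidate configurations left for dataset '%s'.", dataset))
    return(rec_empty_recs(dataset))
  }
  # each neighbor configuration enters once, at its best neighbor score
  ranked <- pool |>
    dplyr::group_by(.data$config_id) |>
    dplyr::summarise(r_hat = max(.data$score), .groups = "drop")
  if (nrow(ranked) < n) {
    warn(sprintf("only %d candidate(s) available for dataset '%s' (requested %d).",
                 nrow(ranked), dataset, n))
  }
  preds <- pred_frame(dataset, ranked$config_id, ranked$r_hat, "knn_meta")
  rank_predictions(preds, n)
}

#' @export
predict_ratings.rec_knn_meta <- function(rec, dataset, config_ids, ...) {
  abort("knn-meta ranks configurations via recommend(); it does not define pointwise rating predictions.")
}
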