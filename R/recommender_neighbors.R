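# Memory-based collaborative-filtering strategies. These keep no model state
# beyond the accumulated rating set; predictions are recomputed from it on
# demand, which is exact and cheap at knowledge-base scales where
# neighborhood methods are competitive.

rec_matrix <- function(rec) {
  r <- rec$ratings
  datasets <- sort(unique(r$dataset))
  configs <- sort(unique(r$config_id))
  m <- matrix(NA_real_, length(datasets), length(configs),
              dimnames = list(datasets, configs))
  m[cbind(match(r$dataset, datasets), match(r$config_id, configs))] <- r$score
  m
}

# --- mean control --------------------------------------------------------

#' @export
predict_ratings.rec_mean <- function(rec, dataset, config_ids, ...) {
  if (nrow(rec$ratings) == 0) abort("mean recommender has no ratings.")
  global <- mean(rec$ratings$score)
  means <- tapply(rec$ratings$score, rec$ratings$config_id, mean)
  hit <- match(config_ids, names(means))
  r_hat <- ifelse(is.na(hit), global, as.numeric(means)[hit])
  pred_frame(dataset, config_ids, r_hat,
             ifelse(is.na(hit), "global_mean", NA_character_))
}

# --- shrunk Pearson similarity -------------------------------------------

# Similarity between row `i` of `m` and every other row, over co-rated
# columns, shrunk by n_co / (n_co + shrinkage) to damp estimates from few
# co-ratings. Rows with fewer than `min_support` co-ratings (or undefined
# correlation) get similarity 0.
row_similarities <- function(m, i, shrinkage, min_support) {
  target <- m[i, ]
  obs_t <- !is.na(target)
  vapply(seq_len(nrow(m)), function(j) {
    if (j == i) return(NA_real_)
    co <- obs_t & !is.na(m[j, ])
    n_co <- sum(co)
    if (n_co < max(min_support, 2L)) {
      # a single co-rating supports no correlation estimate; treat as 0
      return(0)
    }
    s <- suppressWarnings(cor(target[co], m[j, co]))
    if (!is.finite(s)) return(0)
    (n_co / (n_co + shrinkage)) * s
  }, numeric(1))
}

# Mean-centered neighborhood prediction for one target row and a set of
# target columns. Neighbors are the k most similar rows that rated the
# column; the prediction is the target row's mean plus the similarity-
# weighted mean of neighbors' centered ratings.
knn_row_predict <- function(m, row_id, col_ids, k_neighbors, shrinkage,
                            min_support, global) {
  i <- match(row_id, rownames(m))
  if (is.na(i) || all(is.na(m[i, ]))) {
    return(list(r_hat = rep(NA_real_, length(col_ids)),
                note = rep("mean_fallback", length(col_ids))))
  }
  sims <- row_similarities(m, i, shrinkage, min_support)
  row_means <- rowMeans(m, na.rm = TRUE)
  centered <- m - row_means
  r_hat <- numeric(length(col_ids))
  note <- rep(NA_character_, length(col_ids))
  for (ci in seq_along(col_ids)) {
    c_idx <- match(col_ids[ci], colnames(m))
    raters <- if (is.na(c_idx)) integer(0) else which(!is.na(m[, c_idx]))
    raters <- raters[raters != i & sims[raters] != 0]
    if (length(raters) == 0) {
      r_hat[ci] <- NA_real_
      note[ci] <- "mean_fallback"
      next
    }
    nb <- raters[order(-sims[raters])][seq_len(min(k_neighbors, length(raters)))]
    w <- sims[nb]
    r_hat[ci] <- row_means[i] +
      sum(w * centered[nb, c_idx]) / sum(abs(w))
  }
  list(r_hat = r_hat, note = note)
}

knn_predict_frame <- function(rec, m, row_id, col_ids, dataset, config_ids) {
  o <- rec$opts
  out <- knn_row_predict(m, row_id, col_ids, o$k_neighbors, o$shrinkage,
                         o$min_support, mean(rec$ratings$score))
  fb <- is.na(out$r_hat)
  if (any(fb)) {
    out$r_hat[fb] <- predict_ratings.rec_mean(rec, dataset, config_ids[fb])$r_hat
  }
  pred_frame(dataset, config_ids, out$r_hat, out$note)
}

#' @export
predict_ratings.rec_knn_data <- function(rec, dataset, config_ids, ...) {
  if (nrow(rec$ratings) == 0) abort("knn-data recommender has no ratings.")
  m <- rec_matrix(rec)
  knn_predict_frame(rec, m, dataset, config_ids, dataset, config_ids)
}

#' @export
predict_ratings.rec_knn_ml <- function(rec, dataset, config_ids, ...) {
  if (nrow(rec$ratings) == 0) abort("knn-ml recommender has no ratings.")
  # item-based: transpose so configurations are rows, neighbors are
  # configurations and similarity runs over co-rating datasets
  m <- t(rec_matrix(rec))
  o <- rec$opts
  r_hat <- numeric(length(config_ids))
  note <- rep(NA_character_, length(config_ids))
  for (ci in seq_along(config_ids)) {
    out <- knn_row_predict(m, config_ids[ci], dataset, o$k_neighbors,
                           o$shrinkage, o$min_support,
                           mean(rec$ratings$score))
    r_hat[ci] <- out$r_hat
    note[ci] <- out$note
  }
  fb <- is.na(r_hat)
  if (any(fb)) {
    r_hat[fb] <- predict_ratings.rec_mean(rec, dataset, config_ids[fb])$r_hat
  }
  pred_frame(dataset, config_ids, r_hat, note)
}

# --- slope-one -----------------------------------------------------------

#' @export
predict_ratings.rec_slopeone <- function(rec, dataset, config_ids, ...) {
  if (nrow(rec$ratings) == 0) abort("slopeone recommender has no ratings.")
  m <- rec_matrix(rec)
  di <- match(dataset, rownames(m))
  rated <- if (is.na(di)) integer(0) else which(!is.na(m[di, ]))
  r_hat <- numeric(length(config_ids))
  note <- rep(NA_character_, length(config_ids))
  for (ci in seq_along(config_ids)) {
    ti <- match(config_ids[ci], colnames(m))
    preds <- numeric(0)
    if (!is.na(ti) && length(rated) > 0) {
      for (j in setdiff(rated, ti)) {
        both <- !is.na(m[, ti]) & !is.na(m[, j])
        if (!any(both)) next
        dev <- mean(m[both, ti] - m[both, j])
        preds <- c(preds, m[di, j] + dev)
      }
    }
    if (length(preds) == 0) {
      r_hat[ci] <- NA_real_
      note[ci] <- "mean_fallback"
    } else {
      r_hat[ci] <- mean(preds)
    }
  }
  fb <- is.na(r_hat)
  if (any(fb)) {
    r_hat[fb] <- predict_ratings.rec_mean(rec, dataset, config_ids[fb])$r_hat
  }
  pred_frame(dataset, config_ids, r_hat, note)
}
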