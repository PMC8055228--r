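# Co-clustering collaborative filtering: datasets and configurations are
# simultaneously clustered, and a rating is predicted as its co-cluster mean
# corrected by how far the dataset and configuration sit from their own
# cluster means:
#   r_hat = A_gh + (mean_d - A_g) + (mean_a - A_h)
# Assignments are fitted by seeded alternating reassignment (k-means-style)
# minimizing training squared error; several random restarts are taken and
# the best kept, since the objective is non-convex.

#' Fit a co-clustering of a ratings matrix
#'
#' @param m Ratings matrix (datasets x configurations, `NA` unobserved).
#' @param n_row_clusters,n_col_clusters Cluster counts (capped at the matrix
#'   dimensions).
#' @param n_iter Maximum alternating-reassignment sweeps per restart.
#' @param n_init Random restarts; the fit with lowest training error wins.
#' @param seed Seed for the random initial assignments.
#' @return A list with `row_assign`, `col_assign`, the cluster mean tables
#'   and `train_rmse`, usable with [cocluster_predict()].
#' @export
cocluster_fit <- function(m, n_row_clusters = 3L, n_col_clusters = 3L,
                          n_iter = 20L, n_init = 5L, seed = 1L) {
  stopifnot(is.matrix(m), nrow(m) >= 1, ncol(m) >= 1)
  g_max <- min(n_row_clusters, nrow(m))
  h_max <- min(n_col_clusters, ncol(m))
  best <- NULL
  for (init in seq_len(n_init)) {
    fit <- with_seed(derive_seed(seed, init, "cocluster"), {
      cocluster_once(m, g_max, h_max, n_iter)
    })
    if (is.null(best) || fit$train_rmse < best$train_rmse) best <- fit
  }
  best$row_assign <- setNames(best$row_assign, rownames(m))
  best$col_assign <- setNames(best$col_assign, colnames(m))
  best
}

cocluster_once <- function(m, G, H, n_iter) {
  n <- nrow(m)
  p <- ncol(m)
  # every cluster gets at least one member at initialization
  ra <- sample(c(seq_len(G), sample.int(G, max(0, n - G), replace = TRUE)))[seq_len(n)]
  ca <- sample(c(seq_len(H), sample.int(H, max(0, p - H), replace = TRUE)))[seq_len(p)]
  obs <- !is.na(m)
  mu <- mean(m, na.rm = TRUE)
  row_means <- rowMeans(m, na.rm = TRUE)
  col_means <- colMeans(m, na.rm = TRUE)
  row_means[is.nan(row_means)] <- mu
  col_means[is.nan(col_means)] <- mu

  means <- function(ra, ca) {
    A_gh <- matrix(mu, G, H)
    for (g in seq_len(G)) {
      for (h in seq_len(H)) {
        cells <- m[ra == g, ca == h, drop = FALSE]
        if (any(!is.na(cells))) A_gh[g, h] <- mean(cells, na.rm = TRUE)
      }
    }
    A_g <- vapply(seq_len(G), function(g) {
      cells <- m[ra == g, , drop = FALSE]
      if (any(!is.na(cells))) mean(cells, na.rm = TRUE) else mu
    }, numeric(1))
    A_h <- vapply(seq_len(H), function(h) {
      cells <- m[, ca == h, drop = FALSE]
      if (any(!is.na(cells))) mean(cells, na.rm = TRUE) else mu
    }, numeric(1))
    list(A_gh = A_gh, A_g = A_g, A_h = A_h)
  }

  for (it in seq_len(n_iter)) {
    mm <- means(ra, ca)
    ra_new <- vapply(seq_len(n), function(i) {
      errs <- vapply(seq_len(G), function(g) {
        pred <- mm$A_gh[g, ca] + (row_means[i] - mm$A_g[g]) +
          (col_means - mm$A_h[ca])
        sum((m[i, ] - pred)^2, na.rm = TRUE)
      }, numeric(1))
      which.min(errs)
    }, integer(1))
    mm <- means(ra_new, ca)
    ca_new <- vapply(seq_len(p), function(j) {
      errs <- vapply(seq_len(H), function(h) {
        pred <- mm$A_gh[ra_new, h] + (row_means - mm$A_g[ra_new]) +
          (col_means[j] - mm$A_h[h])
        sum((m[, j] - pred)^2, na.rm = TRUE)
      }, numeric(1))
      which.min(errs)
    }, integer(1))
    converged <- identical(ra_new, ra) && identical(ca_new, ca)
    ra <- ra_new
    ca <- ca_new
    if (converged) break
  }
  mm <- means(ra, ca)
  pred <- mm$A_gh[cbind(rep(ra, p), rep(ca, each = n))] +
    (row_means[rep(seq_len(n), p)] - mm$A_g[rep(ra, p)]) +
    (col_means[rep(seq_len(p), each = n)] - mm$A_h[rep(ca, each = n)])
  err2 <- (as.numeric(m) - pred)^2
  list(row_assign = ra, col_assign = ca, A_gh = mm$A_gh, A_g = mm$A_g,
       A_h = mm$A_h, row_means = row_means, col_means = col_means, mu = mu,
       train_rmse = sqrt(mean(err2, na.rm = TRUE)))
}

#' Predict ratings from a fitted co-clustering
#'
#' @param fit Result of [cocluster_fit()].
#' @param datasets,config_ids Vectors of equal length naming the cells to
#'   predict. Unseen datasets fall back to the configuration mean, unseen
#'   configurations to the dataset mean, and fully cold pairs to the global
#'   mean.
#' @return Numeric vector of predictions.
#' @export
cocluster_predict <- function(fit, datasets, config_ids) {
  stopifnot(length(datasets) == length(config_ids))
  g <- fit$row_assign[datasets]
  h <- fit$col_assign[config_ids]
  out <- numeric(length(datasets))
  for (i in seq_along(out)) {
    if (is.na(g[i]) && is.na(h[i])) {
      out[i] <- fit$mu
    } else if (is.na(g[i])) {
      out[i] <- fit$col_means[[config_ids[i]]]
    } else if (is.na(h[i])) {
      out[i] <- fit$row_means[[datasets[i]]]
    } else {
      out[i] <- fit$A_gh[g[i], h[i]] +
        (fit$row_means[[datasets[i]]] - fit$A_g[g[i]]) +
        (fit$col_means[[config_ids[i]]] - fit$A_h[h[i]])
    }
  }
  unname(out)
}

#' @export
predict_ratings.rec_coclustering <- function(rec, dataset, config_ids, ...) {
  if (nrow(rec$ratings) == 0) abort("coclustering recommender has no ratings.")
  o <- rec$opts
  # refit lazily against the current rating set; the fit is cached on the
  # rating-set fingerprint so repeated predictions reuse it
  fp <- nrow(rec$ratings)
  fit <- rec$state$fit
  if (is.null(fit) || !identical(rec$state$fingerprint, fp)) {
    fit <- cocluster_fit(rec_matrix(rec), o$n_dataset_clusters,
                         o$n_config_clusters, o$n_iter, o$n_init,
                         seed = derive_seed(rec$seed, rec$n_updates, "ccfit"))
  }
  r_hat <- cocluster_predict(fit, rep(dataset, length(config_ids)), config_ids)
  note <- ifelse(is.na(fit$row_assign[dataset]) |
                   is.na(fit$col_assign[config_ids]),
                 "cold_start", NA_character_)
  pred_frame(dataset, config_ids, r_hat, unname(note))
}
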