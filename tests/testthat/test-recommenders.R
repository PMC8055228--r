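# Baseline collaborative-filtering strategies, each checked against a
# brute-force or independently recomputed oracle on small dense matrices.

test_that("mean strategy averages per configuration with a global fallback", {
  rec <- rec_update(recommender("mean"),
                    results_tbl(c("d1", "d2", "d1"), c("a", "a", "b"),
                                c(0.4, 0.6, 0.9)))
  expect_equal(predict_ratings(rec, "d3", "a")$r_hat, 0.5)
  unseen <- predict_ratings(rec, "d3", "zzz")
  expect_equal(unseen$r_hat, mean(c(0.4, 0.6, 0.9)))
  expect_equal(unseen$note, "global_mean")

  # 50 random ratings: equals the brute-force scan mean
  set.seed(7)
  res <- results_tbl(sample(sprintf("d%d", 1:6), 50, replace = TRUE),
                     sprintf("c%d", 1:50), runif(50))
  res$config_id <- sample(sprintf("c%d", 1:8), 50, replace = TRUE)
  res <- mlrecommend:::merge_ratings(results_tbl(character(), character(),
                                                 numeric()), res)
  rec <- rec_update(recommender("mean"), res)
  for (cfg in unique(res$config_id)) {
    expect_equal(predict_ratings(rec, "dx", cfg)$r_hat,
                 mean(res$score[res$config_id == cfg]))
  }
})

test_that("ranking by the mean strategy matches brute-force column means", {
  set.seed(13)
  m <- matrix(runif(40, 0.3, 0.9), 5, 8,
              dimnames = list(sprintf("d%d", 1:5), sprintf("c%d", 1:8)))
  kb <- kb_from_matrix(m)
  rec <- rec_update(recommender("mean"), kb[kb$split == "cv", ])
  recs <- recommend(rec, "new_dataset", n = 8, candidates = colnames(m))
  expect_equal(recs$config_id, names(sort(colMeans(m), decreasing = TRUE)))
  expect_true(all(diff(recs$r_hat) <= 0))
})

test_that("recommendation contract: exclusion, exhaustion, ties", {
  kb <- dominant_kb()
  rec <- rec_update(recommender("mean"), kb[kb$split == "cv", ])
  expect_warning(out <- recommend(rec, "d1", n = 2,
                                  exclude = unique(kb$config_id)),
                 "no candidate")
  expect_equal(nrow(out), 0)
  # the dominant configuration is always rank 1 for a new dataset
  recs <- recommend(rec, "new_dataset", n = 3)
  expect_equal(recs$config_id[1], "cfg1")
  # ties break lexicographically on config_id
  tie <- rec_update(recommender("mean"),
                    results_tbl(c("d1", "d1"), c("zz", "aa"), c(0.5, 0.5)))
  tied <- recommend(tie, "d2", n = 2)
  expect_equal(tied$config_id, c("aa", "zz"))
  # already-rated configurations are not candidates
  expect_warning(again <- recommend(rec, "d1", n = 10), "no candidate")
  expect_equal(nrow(again), 0)
})

test_that("knn-data matches a transparent neighborhood oracle", {
  # a perfect twin (identical co-ratings, equal means): the twin's rating
  # for the unseen configuration is returned exactly
  m <- matrix(c(0.4, 0.8, 0.6, 0.6,
                0.4, 0.8, 0.6, NA,
                0.9, 0.2, 0.5, 0.7), 3, 4, byrow = TRUE,
              dimnames = list(c("twin1", "twin2", "other"),
                              c("c1", "c2", "c3", "c4")))
  kb <- kb_from_matrix(m)
  rec <- rec_update(recommender("knn-data", k_neighbors = 1),
                    kb[kb$split == "cv", ])
  expect_equal(predict_ratings(rec, "twin2", "c4")$r_hat, 0.6)

  # dense 5x5: independently recompute the shrunk-Pearson weighted mean
  set.seed(17)
  m5 <- matrix(runif(25, 0.3, 0.9), 5, 5,
               dimnames = list(sprintf("d%d", 1:5), sprintf("c%d", 1:5)))
  m5["d1", "c5"] <- NA
  kb5 <- kb_from_matrix(m5)
  k_nb <- 3
  rec5 <- rec_update(recommender("knn-data", k_neighbors = k_nb,
                                 shrinkage = 10), kb5[kb5$split == "cv", ])
  got <- predict_ratings(rec5, "d1", "c5")$r_hat
  # oracle: shrunk Pearson over co-rated cells, top-k weighted centered mean
  sims <- sapply(2:5, function(j) {
    co <- !is.na(m5[1, ]) & !is.na(m5[j, ])
    (sum(co) / (sum(co) + 10)) * cor(m5[1, co], m5[j, co])
  })
  names(sims) <- rownames(m5)[2:5]
  raters <- names(sims)[!is.na(m5[2:5, "c5"])]
  nb <- raters[order(-sims[raters])][seq_len(k_nb)]
  mu_rows <- rowMeans(m5, na.rm = TRUE)
  want <- mu_rows["d1"] +
    sum(sims[nb] * (m5[nb, "c5"] - mu_rows[nb])) / sum(abs(sims[nb]))
  expect_equal(got, unname(want))

  # no neighbor rated the config -> mean fallback, flagged
  m_fb <- matrix(c(0.5, NA, 0.6, NA), 2, 2,
                 dimnames = list(c("a", "b"), c("c1", "c2")))
  kbf <- kb_from_matrix(m_fb)
  recf <- rec_update(recommender("knn-data"), kbf[kbf$split == "cv", ])
  out <- predict_ratings(recf, "a", "c2")
  expect_equal(out$note, "mean_fallback")
})

test_that("knn-ml is the item-based transpose of knn-data", {
  # a perfect twin configuration (identical co-ratings, equal means):
  # its rating on the unseen dataset is returned exactly
  m <- matrix(c(0.3, 0.3, 0.9,
                0.5, 0.5, 0.1,
                0.4, 0.4, 0.6,
                0.4, NA,  0.7), 4, 3, byrow = TRUE,
              dimnames = list(c("d1", "d2", "d3", "d4"),
                              c("twinA", "twinB", "c3")))
  kb <- kb_from_matrix(m)
  rec <- rec_update(recommender("knn-ml", k_neighbors = 1),
                    kb[kb$split == "cv", ])
  expect_equal(predict_ratings(rec, "d4", "twinB")$r_hat, 0.4)

  # transposing the matrix and swapping roles gives identical predictions
  set.seed(19)
  m6 <- matrix(runif(30, 0.2, 0.9), 5, 6,
               dimnames = list(sprintf("d%d", 1:5), sprintf("c%d", 1:6)))
  m6["d2", "c4"] <- NA
  kb_d <- kb_from_matrix(m6)
  kb_t <- kb_from_matrix(t(m6))
  rec_ml <- rec_update(recommender("knn-ml", k_neighbors = 2),
                       kb_d[kb_d$split == "cv", ])
  rec_dt <- rec_update(recommender("knn-data", k_neighbors = 2),
                       kb_t[kb_t$split == "cv", ])
  expect_equal(predict_ratings(rec_ml, "d2", "c4")$r_hat,
               predict_ratings(rec_dt, "c4", "d2")$r_hat)
})

test_that("slope-one reproduces constant offsets and a direct oracle", {
  # configurations offset by a constant 0.1: prediction is exact
  m <- matrix(c(0.5, 0.6,
                0.7, 0.8,
                0.3, NA), 3, 2, byrow = TRUE,
              dimnames = list(c("d1", "d2", "d3"), c("c1", "c2")))
  kb <- kb_from_matrix(m)
  rec <- rec_update(recommender("slopeone"), kb[kb$split == "cv", ])
  expect_equal(predict_ratings(rec, "d3", "c2")$r_hat, 0.3 + 0.1)

  # 4x4 with gaps: independently recompute the deviation table
  set.seed(23)
  m4 <- matrix(runif(16, 0.2, 0.9), 4, 4,
               dimnames = list(sprintf("d%d", 1:4), sprintf("c%d", 1:4)))
  m4["d1", "c1"] <- NA
  m4["d3", "c2"] <- NA
  kb4 <- kb_from_matrix(m4)
  rec4 <- rec_update(recommender("slopeone"), kb4[kb4$split == "cv", ])
  got <- predict_ratings(rec4, "d1", "c1")$r_hat
  preds <- c()
  for (j in c("c2", "c3", "c4")) {
    both <- !is.na(m4[, "c1"]) & !is.na(m4[, j])
    if (!any(both)) next
    preds <- c(preds, m4["d1", j] + mean(m4[both, "c1"] - m4[both, j]))
  }
  expect_equal(got, mean(preds))

  # no co-rated configuration -> flagged mean fallback
  m_iso <- matrix(c(0.5, NA, NA, 0.7), 2, 2,
                  dimnames = list(c("d1", "d2"), c("c1", "c2")))
  kbi <- kb_from_matrix(m_iso)
  reci <- rec_update(recommender("slopeone"), kbi[kbi$split == "cv", ])
  expect_equal(predict_ratings(reci, "d1", "c2")$note, "mean_fallback")
})

test_that("co-clustering reduces correctly and fits block structure", {
  # 1x1 clustering: prediction = dataset mean + config mean - global mean
  set.seed(29)
  m <- matrix(runif(20, 0.3, 0.8), 4, 5,
              dimnames = list(sprintf("d%d", 1:4), sprintf("c%d", 1:5)))
  fit <- cocluster_fit(m, 1, 1, seed = 3)
  expect_equal(cocluster_predict(fit, "d2", "c3"),
               mean(m["d2", ]) + mean(m[, "c3"]) - mean(m))

  # block-constant matrix with matching cluster counts: zero training error
  blocks <- matrix(0, 6, 6)
  blocks[1:3, 1:3] <- 0.9; blocks[1:3, 4:6] <- 0.4
  blocks[4:6, 1:3] <- 0.3; blocks[4:6, 4:6] <- 0.7
  dimnames(blocks) <- list(sprintf("d%d", 1:6), sprintf("c%d", 1:6))
  fit_b <- cocluster_fit(blocks, 2, 2, n_init = 5, seed = 7)
  expect_lt(fit_b$train_rmse, 1e-10)

  # random 8x8: strategy predictions equal the closed-form recomputation
  # from the fitted assignments
  set.seed(31)
  m8 <- matrix(runif(64, 0.2, 0.9), 8, 8,
               dimnames = list(sprintf("d%d", 1:8), sprintf("c%d", 1:8)))
  kb8 <- kb_from_matrix(m8)
  rec8 <- rec_update(recommender("coclustering", seed = 11),
                     kb8[kb8$split == "cv", ])
  fit8 <- cocluster_fit(m8, 3, 3, n_iter = 20, n_init = 5,
                        seed = mlrecommend:::derive_seed(11, 1, "ccfit"))
  got <- predict_ratings(rec8, "d5", c("c2", "c7"))$r_hat
  g <- fit8$row_assign[["d5"]]
  want <- vapply(c("c2", "c7"), function(cc) {
    h <- fit8$col_assign[[cc]]
    fit8$A_gh[g, h] + (mean(m8["d5", ]) - fit8$A_g[g]) +
      (mean(m8[, cc]) - fit8$A_h[h])
  }, numeric(1))
  expect_equal(got, unname(want))
})

test_that("random strategy is seeded, exhaustive and uniform", {
  kb <- dominant_kb(3, 4)
  rec <- rec_update(recommender("random", seed = 5), kb[kb$split == "cv", ])
  cand <- sprintf("new%d", 1:4)
  r1 <- recommend(rec, "dx", n = 2, candidates = cand, seed = 77)
  r2 <- recommend(rec, "dx", n = 2, candidates = cand, seed = 77)
  expect_identical(r1, r2)
  # n >= candidates: a permutation of the full candidate set
  expect_warning(all4 <- recommend(rec, "dx", n = 10, candidates = cand),
                 "only 4")
  expect_setequal(all4$config_id, cand)
  # 10^4 draws of 1 from 4: each frequency within 3 sigma of 1/4
  draws <- vapply(seq_len(1e4), function(i) {
    recommend(rec, "dx", n = 1, candidates = cand, seed = i)$config_id
  }, character(1))
  freq <- table(draws) / 1e4
  sigma <- sqrt(0.25 * 0.75 / 1e4)
  expect_true(all(abs(freq - 0.25) < 3 * sigma))
})

test_that("knn-meta recommends neighbors' best configurations, best-first", {
  tabs <- simulate_tables(n_datasets = 3, rows = 80, cols = 4, seed = 13)
  cache <- purrr::imap_dfr(tabs, function(tab, nm) {
    compute_metafeatures(tab, dataset = nm)
  })
  # a twin of tab01 under a new id: identical metafeatures, distance zero
  cache <- dplyr::bind_rows(cache,
                            dplyr::mutate(cache[1, ], dataset = "newcomer"))
  ratings <- results_tbl(
    c("tab01", "tab01", "tab02", "tab02", "tab03"),
    c("A", "B", "C", "D", "E"),
    c(0.9, 0.7, 0.95, 0.5, 0.6)
  )
  rec <- rec_update(recommender("knn-meta", k_neighbors = 1,
                                metafeatures = cache), ratings)
  recs <- recommend(rec, "newcomer", n = 2)
  # zero-distance neighbor is tab01; its configs come back best-first
  expect_equal(recs$config_id, c("A", "B"))
  expect_equal(recs$r_hat, c(0.9, 0.7))

  # recommendations are a subset of the neighbors' rated configurations
  rec3 <- rec_update(recommender("knn-meta", k_neighbors = 2,
                                 metafeatures = cache), ratings)
  recs3 <- suppressWarnings(recommend(rec3, "newcomer", n = 10))
  expect_true(all(recs3$config_id %in% ratings$config_id))

  expect_error(recommend(rec, "uncached_dataset", n = 1),
               "compute_metafeatures")
  bare <- rec_update(recommender("knn-meta"), ratings)
  expect_error(recommend(bare, "newcomer", n = 1), "metafeatures")
})
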