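# The factorization model predicts mu + b_a + b_d + q_a . p_d. These tests
# pin the prediction arithmetic, the SGD update rules, online behaviour and
# planted-structure recovery.

# Build an svd recommender with hand-set parameters for arithmetic checks.
svd_with_state <- function(mu, b_d, b_a, p, q, lambda = 0.02, k = ncol(p)) {
  rec <- recommender("svd", k = k, lambda = lambda)
  rec$ratings <- results_tbl("dummy", "dummy_cfg", mu)  # makes mu defined
  rec$state <- list(mu = mu, b_d = b_d, b_a = b_a, p = p, q = q,
                    loss_trace = numeric(0))
  rec
}

test_that("prediction equals mu + b_a + b_d + q_a.p_d with absent terms zero", {
  p <- matrix(c(0.1, 0.2), 1, 2, dimnames = list("d1", NULL))
  q <- matrix(c(0.2, 0.0), 1, 2, dimnames = list("cfgA", NULL))
  # all biases and factors zero -> prediction is the global mean
  rec0 <- svd_with_state(0.7, c(d1 = 0), c(cfgA = 0), 0 * p, 0 * q)
  expect_equal(predict_ratings(rec0, "d1", "cfgA")$r_hat, 0.7)

  # mu = 0.5, b_a = 0.1, b_d = -0.05, q_a.p_d = 0.02 -> 0.57
  rec <- svd_with_state(0.5, c(d1 = -0.05), c(cfgA = 0.1), p, q)
  expect_equal(predict_ratings(rec, "d1", "cfgA")$r_hat,
               0.5 + 0.1 - 0.05 + 0.1 * 0.2)

  # unseen dataset: rank by mu + b_a (cold start); unseen config: mu + b_d
  cold <- predict_ratings(rec, "new_dataset", "cfgA")
  expect_equal(cold$r_hat, 0.5 + 0.1)
  expect_equal(cold$note, "cold_start")
  expect_equal(predict_ratings(rec, "d1", "new_cfg")$r_hat, 0.5 - 0.05)

  fresh <- recommender("svd")
  expect_error(predict_ratings(fresh, "d1", "cfgA"), "mu is undefined")
})

test_that("a zero-residual rating with lambda = 0 is an SGD no-op", {
  # craft a rating equal to the model's prediction; with zero
  # regularization the gradient vanishes and no parameter moves
  b_d <- c(d1 = -0.03)
  b_a <- c(cfgA = 0.08)
  p <- matrix(c(0.3, -0.1), 1, 2)
  q <- matrix(c(0.2, 0.5), 1, 2)
  mu <- 0.6
  r <- mu + b_a + b_d + sum(p * q)
  out <- mlrecommend:::sgd_train_cpp(b_d, b_a, p, q, 1L, 1L, r, mu,
                                     gamma = 0.05, lambda = 0,
                                     perm = matrix(1L, 1, 1))
  expect_equal(as.numeric(out$b_d), as.numeric(b_d))
  expect_equal(as.numeric(out$b_a), as.numeric(b_a))
  expect_equal(as.numeric(out$p), as.numeric(p))
  expect_equal(as.numeric(out$q), as.numeric(q))
})

test_that("factor updates use the pre-update vectors (simultaneous rule)", {
  b_d <- c(d1 = 0)
  b_a <- c(cfgA = 0)
  p <- matrix(0.5, 1, 1)
  q <- matrix(0.4, 1, 1)
  mu <- 0.5
  r <- 0.9
  gamma <- 0.1
  lambda <- 0.02
  e <- r - (mu + sum(p * q))
  out <- mlrecommend:::sgd_train_cpp(b_d, b_a, p, q, 1L, 1L, r, mu,
                                     gamma, lambda, matrix(1L, 1, 1))
  expect_equal(as.numeric(out$b_a), gamma * e)
  expect_equal(as.numeric(out$b_d), gamma * e)
  expect_equal(as.numeric(out$q), 0.4 + gamma * (e * 0.5 - lambda * 0.4))
  expect_equal(as.numeric(out$p), 0.5 + gamma * (e * 0.4 - lambda * 0.5))
})

test_that("training descends: loss non-increasing at small learning rate", {
  kb <- simulate_kb(n_datasets = 20, n_configs = 20, seed = 11)$kb
  rec <- recommender("svd", k = 5, gamma = 0.001, lambda = 0.02,
                     min_epochs = 100, epochs_per_result = 0, seed = 4)
  rec <- rec_update(rec, kb[kb$split == "cv", ])
  trace <- svd_loss_trace(rec)
  expect_length(trace, 100)
  expect_true(all(diff(trace) <= 1e-10))
  # the final stored loss matches an independent evaluation of the objective
  expect_equal(svd_loss(rec), trace[length(trace)], tolerance = 1e-10)

  # descent on a singleton: one rating, fresh state
  rec1 <- recommender("svd", k = 2, min_epochs = 5, seed = 1)
  rec1 <- rec_update(rec1, results_tbl("d", "c", 1.0))
  tr1 <- svd_loss_trace(rec1)
  expect_lte(tr1[length(tr1)], tr1[1])
})

test_that("mu is the exact mean of all ratings seen, across online updates", {
  rec <- recommender("svd", k = 2, min_epochs = 2, seed = 8)
  rec <- rec_update(rec, results_tbl(c("d1", "d2"), c("a", "a"), c(0.4, 0.6)))
  expect_equal(rec$state$mu, 0.5)
  rec <- rec_update(rec, results_tbl("d3", "b", 0.8))
  expect_equal(rec$state$mu, mean(c(0.4, 0.6, 0.8)))
  # a replaced rating changes mu accordingly (latest wins)
  rec <- rec_update(rec, results_tbl("d1", "a", 0.1))
  expect_equal(rec$state$mu, mean(c(0.1, 0.6, 0.8)))
  # parameters persist: entities from the first update still have state
  expect_true(all(c("d1", "d2", "d3") %in% names(rec$state$b_d)))
})

test_that("the online epoch count scales with the batch size", {
  rec <- recommender("svd", k = 2, epochs_per_result = 2, min_epochs = 3,
                     seed = 1)
  rec <- rec_update(rec, results_tbl("d1", "a", 0.5))
  expect_length(svd_loss_trace(rec), 3)  # max(min_epochs, 2*1)
  rec <- rec_update(rec, results_tbl(rep("d1", 5), letters[2:6], runif(5)))
  expect_length(svd_loss_trace(rec), 10)  # 2 * 5 new results
})

test_that("updates reject out-of-range ratings before any mutation", {
  rec <- recommender("svd", k = 2, seed = 1)
  rec <- rec_update(rec, results_tbl("d1", "a", 0.5))
  before <- rec$state
  expect_error(rec_update(rec, results_tbl("d1", "b", 1.2)), "\\[0, 1\\]")
  expect_identical(rec$state, before)
})

test_that("recovery: planted low-rank ratings are fit below the noise ceiling", {
  # 200 ratings from a planted rank-2 model, 50 epochs: training RMS
  # residual below 1.5x the planted noise level
  sim <- simulate_kb(n_datasets = 20, n_configs = 10, k_true = 2,
                     noise_sd = 0.02, seed = 31)
  cv <- sim$kb[sim$kb$split == "cv", ]
  rec <- recommender("svd", k = 2, gamma = 0.01, lambda = 0.005,
                     min_epochs = 50, seed = 5)
  rec <- rec_update(rec, cv)
  pred <- vapply(seq_len(nrow(cv)), function(i) {
    predict_ratings(rec, cv$dataset[i], cv$config_id[i])$r_hat
  }, numeric(1))
  rmse <- sqrt(mean((pred - cv$score)^2))
  expect_lt(rmse, 1.5 * 0.02)
})

test_that("held-out RMSE approaches zero on noise-free planted ratings", {
  sim <- simulate_kb(n_datasets = 30, n_configs = 30, k_true = 2,
                     noise_sd = 0, seed = 9)
  hid <- hide_ratings(sim$kb, 0.6, seed = 10)
  rec <- recommender("svd", k = 2, gamma = 0.01, lambda = 0.005,
                     min_epochs = 500, seed = 7)
  rec <- rec_update(rec, hid$train[hid$train$split == "cv", ])
  m <- kb_ratings_matrix(sim$kb, "cv")
  tc <- hid$test_cells
  pred <- vapply(seq_len(nrow(tc)), function(i) {
    predict_ratings(rec, tc$dataset[i], tc$config_id[i])$r_hat
  }, numeric(1))
  expect_lte(sqrt(mean((pred - m[cbind(tc$dataset, tc$config_id)])^2)), 0.02)
})

test_that("updates and predictions are deterministic given the seed", {
  cv <- simulate_kb(n_datasets = 8, n_configs = 10, seed = 2)$kb
  cv <- cv[cv$split == "cv", ]
  r1 <- rec_update(recommender("svd", k = 4, seed = 42), cv)
  r2 <- rec_update(recommender("svd", k = 4, seed = 42), cv)
  expect_identical(r1$state, r2$state)
  r3 <- rec_update(recommender("svd", k = 4, seed = 43), cv)
  expect_false(identical(r1$state$p, r3$state$p))
})

test_that("model state survives a JSON save/load round trip", {
  cv <- simulate_kb(n_datasets = 6, n_configs = 8, seed = 2)$kb
  cv <- cv[cv$split == "cv", ]
  rec <- rec_update(recommender("svd", k = 3, seed = 1), cv)
  path <- withr::local_tempfile(fileext = ".json")
  rec_save(rec, path)
  rec2 <- rec_load(path)
  cand <- unique(cv$config_id)
  expect_equal(predict_ratings(rec2, "d01", cand)$r_hat,
               predict_ratings(rec, "d01", cand)$r_hat)
  expect_equal(rec2$opts, rec$opts)
})

test_that("tidy() and glance() expose the fitted parameters", {
  cv <- simulate_kb(n_datasets = 5, n_configs = 6, seed = 2)$kb
  cv <- cv[cv$split == "cv", ]
  rec <- rec_update(recommender("svd", k = 3, seed = 1), cv)
  td <- tidy(rec)
  expect_setequal(unique(td$entity), c("dataset", "config"))
  expect_equal(nrow(td), 5 + 6)
  expect_true(all(lengths(td$factors) == 3))
  gl <- glance(rec)
  expect_equal(gl$n_ratings, 30)
  expect_equal(gl$mu, mean(cv$score))
})
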