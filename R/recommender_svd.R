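# Biased matrix-factorization recommender trained online by SGD.
#
# Prediction: r_hat = mu + b_a + b_d + q_a . p_d, where mu is the observed
# mean of all ratings seen so far, b_a / b_d are configuration and dataset
# biases (zero until the entity is seen), and q_a / p_d are length-k latent
# factors initialized from N(0, init_sd). Each update recomputes mu exactly,
# then runs max(min_epochs, ceiling(epochs_per_result * n_new)) SGD epochs
# over the full accumulated rating set in seeded-shuffled order; parameters
# are maintained between updates, which is what makes the model usable as an
# online learner inside the recommendation feedback loop.

#' @export
rec_update.rec_svd <- function(rec, results, ...) {
  new <- rec_results_frame(results)
  n_new <- nrow(new)
  rec$ratings <- merge_ratings(rec$ratings, new)
  rec$n_updates <- rec$n_updates + 1L

  st <- rec$state
  o <- rec$opts
  datasets <- unique(rec$ratings$dataset)
  configs <- unique(rec$ratings$config_id)
  if (is.null(st$mu)) {
    st <- list(mu = 0, b_d = setNames(numeric(0), character(0)),
               b_a = setNames(numeric(0), character(0)),
               p = matrix(0, 0, o$k), q = matrix(0, 0, o$k),
               loss_trace = numeric(0))
  }
  # grow parameter containers for newly seen entities; biases start at zero,
  # factors from N(0, init_sd) under a derived substream seed
  new_d <- setdiff(datasets, names(st$b_d))
  new_a <- setdiff(configs, names(st$b_a))
  if (length(new_d) + length(new_a) > 0) {
    init <- with_seed(derive_seed(rec$seed, rec$n_updates, "init"), {
      list(p = matrix(rnorm(length(new_d) * o$k, 0, o$init_sd), ncol = o$k),
           q = matrix(rnorm(length(new_a) * o$k, 0, o$init_sd), ncol = o$k))
    })
    st$b_d <- c(st$b_d, setNames(numeric(length(new_d)), new_d))
    st$b_a <- c(st$b_a, setNames(numeric(length(new_a)), new_a))
    st$p <- rbind(st$p, init$p)
    rownames(st$p) <- names(st$b_d)
    st$q <- rbind(st$q, init$q)
    rownames(st$q) <- names(st$b_a)
  }
  # mu is the observed average of all ratings seen so far, recomputed
  # exactly rather than learned by gradient steps
  st$mu <- mean(rec$ratings$score)

  n <- nrow(rec$ratings)
  epochs <- max(o$min_epochs, ceiling(o$epochs_per_result * n_new))
  perm <- with_seed(derive_seed(rec$seed, rec$n_updates, "shuffle"), {
    matrix(unlist(lapply(seq_len(epochs), function(i) sample.int(n))),
           nrow = epochs, byrow = TRUE)
  })
  fit <- sgd_train_cpp(
    st$b_d, st$b_a, st$p, st$q,
    match(rec$ratings$dataset, names(st$b_d)),
    match(rec$ratings$config_id, names(st$b_a)),
    rec$ratings$score, st$mu, o$gamma, o$lambda, perm
  )
  st$b_d <- setNames(as.numeric(fit$b_d), names(st$b_d))
  st$b_a <- setNames(as.numeric(fit$b_a), names(st$b_a))
  st$p <- fit$p
  rownames(st$p) <- names(st$b_d)
  st$q <- fit$q
  rownames(st$q) <- names(st$b_a)
  st$loss_trace <- as.numeric(fit$loss)
  rec$state <- st
  rec
}

#' @export
predict_ratings.rec_svd <- function(rec, dataset, config_ids, ...) {
  st <- rec$state
  if (is.null(st$mu) || nrow(rec$ratings) == 0) {
    abort("SVD recommender has never seen a rating; mu is undefined.")
  }
  di <- match(dataset, names(st$b_d))
  ai <- match(config_ids, names(st$b_a))
  b_d <- if (is.na(di)) 0 else st$b_d[[di]]
  b_a <- ifelse(is.na(ai), 0, st$b_a[ai])
  inter <- numeric(length(config_ids))
  if (!is.na(di)) {
    seen <- !is.na(ai)
    if (any(seen)) {
      inter[seen] <- as.numeric(st$q[ai[seen], , drop = FALSE] %*% st$p[di, ])
    }
  }
  note <- ifelse(is.na(ai) | is.na(di), "cold_start", NA_character_)
  pred_frame(dataset, config_ids, st$mu + b_a + b_d + inter, note)
}

#' Regularized training loss of an SVD recommender
#'
#' The objective minimized by the SGD updates, evaluated on the accumulated
#' rating set: the sum over ratings of the squared residual plus
#' `lambda` times the squared norms of the involved biases and factors.
#'
#' @param rec A trained `svd` [recommender()].
#' @return A single number.
#' @export
svd_loss <- function(rec) {
  stopifnot(inherits(rec, "rec_svd"))
  st <- rec$state
  if (is.null(st$mu)) abort("recommender has never been updated.")
  di <- match(rec$ratings$dataset, names(st$b_d))
  ai <- match(rec$ratings$config_id, names(st$b_a))
  pred <- st$mu + st$b_a[ai] + st$b_d[di] +
    rowSums(st$q[ai, , drop = FALSE] * st$p[di, , drop = FALSE])
  err <- rec$ratings$score - pred
  reg <- st$b_a[ai]^2 + st$b_d[di]^2 +
    rowSums(st$q[ai, , drop = FALSE]^2) + rowSums(st$p[di, , drop = FALSE]^2)
  sum(err^2 + rec$opts$lambda * reg)
}

#' Per-epoch training loss of the most recent update
#'
#' @param rec A trained `svd` [recommender()].
#' @return Numeric vector, one regularized loss value per SGD epoch of the
#'   last [rec_update()] call.
#' @export
svd_loss_trace <- function(rec) {
  stopifnot(inherits(rec, "rec_svd"))
  rec$state$loss_trace %||% numeric(0)
}

#' @export
tidy.rec_svd <- function(x, ...) {
  st <- x$state
  if (is.null(st$mu)) {
    return(tibble::tibble(entity = character(), id = character(),
                          bias = double()))
  }
  dplyr::bind_rows(
    tibble::tibble(entity = "dataset", id = names(st$b_d),
                   bias = as.numeric(st$b_d),
                   factors = lapply(seq_along(st$b_d),
                                    function(i) as.numeric(st$p[i, ]))),
    tibble::tibble(entity = "config", id = names(st$b_a),
                   bias = as.numeric(st$b_a),
                   factors = lapply(seq_along(st$b_a),
                                    function(i) as.numeric(st$q[i, ])))
  )
}

#' @export
glance.rec_svd <- function(x, ...) {
  st <- x$state
  tibble::tibble(
    strategy = "svd",
    mu = st$mu %||% NA_real_,
    k = x$opts$k,
    gamma = x$opts$gamma,
    lambda = x$opts$lambda,
    n_ratings = nrow(x$ratings),
    n_datasets = length(unique(x$ratings$dataset)),
    n_configs = length(unique(x$ratings$config_id)),
    n_updates = x$n_updates,
    loss = if (is.null(st$mu)) NA_real_ else svd_loss(x)
  )
}

#' Save / load a recommender model state
#'
#' Serializes the recommender (strategy, options, accumulated ratings and
#' model state) as one version-tagged JSON document, so a trained model can
#' be reused across sessions, e.g. by the command-line tool.
#'
#' @param rec A [recommender()].
#' @param path JSON file path.
#' @return `rec_save()` returns `path` invisibly; `rec_load()` returns the
#'   recommender.
#' @export
rec_save <- function(rec, path) {
  stopifnot(inherits(rec, "recommender"))
  doc <- list(
    format = "mlrecommend-model", version = 1L,
    strategy = rec$strategy, seed = rec$seed, n_updates = rec$n_updates,
    ratings = rec$ratings,
    opts = rec$opts[!vapply(rec$opts, is.data.frame, logical(1))],
    state = if (rec$strategy == "svd" && !is.null(rec$state$mu)) {
      list(mu = rec$state$mu,
           b_d = as.list(rec$state$b_d), b_a = as.list(rec$state$b_a),
           p = rec$state$p, q = rec$state$q)
    } else {
      NULL
    }
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname rec_save
#' @export
rec_load <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(doc$format, "mlrecommend-model")) {
    abort("not an mlrecommend model file.")
  }
  rec <- do.call(recommender,
                 c(list(strategy = doc$strategy, seed = doc$seed), doc$opts))
  rec$n_updates <- doc$n_updates
  rec$ratings <- tibble::as_tibble(doc$ratings)
  if (!is.null(doc$state) && length(doc$state) > 0) {
    b_d <- unlist(doc$state$b_d) %||% setNames(numeric(0), character(0))
    b_a <- unlist(doc$state$b_a) %||% setNames(numeric(0), character(0))
    p <- doc$state$p
    q <- doc$state$q
    if (is.null(dim(p))) p <- matrix(p, nrow = length(b_d))
    if (is.null(dim(q))) q <- matrix(q, nrow = length(b_a))
    rownames(p) <- names(b_d)
    rownames(q) <- names(b_a)
    rec$state <- list(mu = doc$state$mu, b_d = b_d, b_a = b_a,
                      p = p, q = q, loss_trace = numeric(0))
  }
  rec
}
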