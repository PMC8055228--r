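# Synthetic study systems: a results cache with planted low-rank structure
# (so every recommender and metric has a known ground truth) and toy labeled
# tables with planted metafeatures. These define the study conditions the
# package's simulations run under; see the methods vignette.

#' Simulate a results cache with planted low-rank structure
#'
#' Emulates, at desk scale, a dense cache of cross-validated
#' balanced-accuracy scores over a grid of datasets and algorithm
#' configurations. Clean scores follow the same additive structure the
#' factorization recommender assumes — global mean, per-configuration and
#' per-dataset biases, and a rank-`k_true` latent interaction — and are
#' clipped into \[0, 1\]. Each cell receives two independently noised
#' ratings: a `"cv"` rating (shown to recommenders as feedback) and a
#' `"holdout"` rating (reserved for assessment), mirroring how real caches
#' separate model-selection from assessment scores.
#'
#' Default scales (`mu = 0.7`, bias sd 0.05, factor entry sd
#' `0.15/sqrt(k_true)`, `noise_sd = 0.02`) put most scores in 0.5–0.95,
#' the spread typical of balanced-accuracy benchmarks. `best_margin` nudges
#' each dataset's top clean configuration to exceed its runner-up by at
#' least that margin, so the planted best is identifiable under noise.
#'
#' @param n_datasets,n_configs Grid size.
#' @param k_true Planted latent rank (0 for a pure bias model).
#' @param noise_sd Rating noise standard deviation.
#' @param mu Planted global mean score.
#' @param bias_sd Standard deviation of planted dataset/configuration biases.
#' @param factor_sd Standard deviation of latent factor entries; default
#'   `0.15 / sqrt(k_true)` keeps the interaction's scale rank-independent.
#' @param best_margin Minimum clean-score gap between each dataset's top two
#'   configurations (0 disables the separation).
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A list with `kb` (an [as_kb()] tibble with `cv` and `holdout`
#'   rows for every cell) and `truth` (planted parameters: `mu`, `b_d`,
#'   `b_a`, factor matrices `p` and `q`, the `clean` score matrix, and the
#'   call's arguments).
#' @export
simulate_kb <- function(n_datasets = 25L, n_configs = 100L, k_true = 2L,
                        noise_sd = 0.02, mu = 0.7, bias_sd = 0.05,
                        factor_sd = NULL, best_margin = 0.03, seed = 1L) {
  stopifnot(n_datasets >= 1, n_configs >= 1, k_true >= 0, noise_sd >= 0)
  factor_sd <- factor_sd %||% if (k_true > 0) 0.15 / sqrt(k_true) else 0
  datasets <- sprintf("d%02d", seq_len(n_datasets))
  algs <- c("rf", "gb", "svc", "lr", "dt")
  configs <- sprintf("%s|setting=%d", algs[(seq_len(n_configs) - 1L) %% length(algs) + 1L],
                     seq_len(n_configs))
  out <- with_seed(seed, {
    b_d <- rnorm(n_datasets, 0, bias_sd)
    b_a <- rnorm(n_configs, 0, bias_sd)
    p <- matrix(rnorm(n_datasets * max(k_true, 1), 0, factor_sd),
                n_datasets, max(k_true, 1))
    q <- matrix(rnorm(n_configs * max(k_true, 1), 0, factor_sd),
                n_configs, max(k_true, 1))
    if (k_true == 0) {
      p[] <- 0
      q[] <- 0
    }
    clean <- mu + outer(b_d, b_a, "+") + p %*% t(q)
    # separation by construction: the planted best configuration of each
    # dataset clears the runner-up by at least best_margin
    if (best_margin > 0 && n_configs >= 2) {
      for (i in seq_len(n_datasets)) {
        ord <- order(clean[i, ], decreasing = TRUE)
        gap <- clean[i, ord[1]] - clean[i, ord[2]]
        if (gap < best_margin) {
          clean[i, ord[1]] <- clean[i, ord[2]] + best_margin
        }
      }
    }
    cv <- clamp01(clean + matrix(rnorm(length(clean), 0, noise_sd),
                                 nrow(clean)))
    holdout <- clamp01(clean + matrix(rnorm(length(clean), 0, noise_sd),
                                      nrow(clean)))
    list(b_d = b_d, b_a = b_a, p = p, q = q, clean = clean,
         cv = cv, holdout = holdout)
  })
  dimnames(out$clean) <- dimnames(out$cv) <- dimnames(out$holdout) <-
    list(datasets, configs)
  cell <- expand.grid(dataset = datasets, config_id = configs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  alg_of <- sub("\\|.*$", "", cell$config_id)
  par_of <- sprintf('{"setting":%s}', sub("^.*=", "", cell$config_id))
  kb <- dplyr::bind_rows(
    tibble::tibble(dataset = cell$dataset, algorithm = alg_of,
                   parameters = par_of, config_id = cell$config_id,
                   metric = "balanced_accuracy",
                   score = as.numeric(out$cv), split = "cv"),
    tibble::tibble(dataset = cell$dataset, algorithm = alg_of,
                   parameters = par_of, config_id = cell$config_id,
                   metric = "balanced_accuracy",
                   score = as.numeric(out$holdout), split = "holdout")
  )
  truth <- list(mu = mu, b_d = setNames(out$b_d, datasets),
                b_a = setNames(out$b_a, configs),
                p = out$p, q = out$q, clean = out$clean,
                k_true = k_true, noise_sd = noise_sd, bias_sd = bias_sd,
                factor_sd = factor_sd, best_margin = best_margin, seed = seed)
  list(kb = as_kb(kb, quiet = TRUE), truth = truth)
}

#' Hide a fraction of knowledge-base cells
#'
#' Splits the (dataset, configuration) cells of a knowledge base into an
#' observed training part and a hidden test part by uniform sampling without
#' replacement — the standard held-out-cells protocol for rating-prediction
#' accuracy. The same cell partition is applied to every split tag, so a
#' retained cell keeps both its `cv` and `holdout` ratings.
#'
#' @param kb An `ml_kb`.
#' @param observed_fraction Fraction of cells to retain, in (0, 1\].
#' @param seed RNG seed.
#' @return A list with `train` (an `ml_kb` restricted to retained cells)
#'   and `test_cells` (tibble of hidden `dataset`, `config_id` pairs).
#' @export
hide_ratings <- function(kb, observed_fraction, seed = 1L) {
  if (observed_fraction <= 0 || observed_fraction > 1) {
    abort("`observed_fraction` must lie in (0, 1].")
  }
  cells <- dplyr::distinct(tibble::as_tibble(kb[c("dataset", "config_id")]))
  n_keep <- round(observed_fraction * nrow(cells))
  keep_idx <- with_seed(seed, sample.int(nrow(cells), n_keep))
  keep <- cells[keep_idx, ]
  key_all <- paste(kb$dataset, kb$config_id, sep = "\r")
  key_keep <- paste(keep$dataset, keep$config_id, sep = "\r")
  train <- kb[key_all %in% key_keep, ]
  class(train) <- class(kb)
  list(train = train, test_cells = cells[-keep_idx, ])
}

#' Simulate labeled classification tables with planted metafeatures
#'
#' Generates two-class Gaussian-blob tables whose basic metafeatures
#' (sample count, feature count, class imbalance) are planted exactly, for
#' testing the metalearning pipeline without downloading anything.
#'
#' @param n_datasets Number of tables.
#' @param rows,cols Rows (≥ 10) and feature columns per table.
#' @param class_sep Distance between class centroids, in feature-sd units.
#' @param imbalance Expected majority-class fraction, in \[0.5, 1).
#' @param seed RNG seed.
#' @return A named list of tibbles (`tab01`, `tab02`, ...), each with `cols`
#'   numeric feature columns and a two-level `class` column.
#' @export
simulate_tables <- function(n_datasets = 3L, rows = 100L, cols = 5L,
                            class_sep = 1, imbalance = 0.5, seed = 1L) {
  stopifnot(rows >= 10, cols >= 1, n_datasets >= 1)
  if (imbalance < 0.5 || imbalance >= 1) {
    abort("`imbalance` must lie in [0.5, 1).")
  }
  with_seed(seed, {
    out <- lapply(seq_len(n_datasets), function(i) {
      y <- rbinom(rows, 1, 1 - imbalance)
      centers <- matrix(rnorm(2 * cols, 0, class_sep), 2, cols)
      x <- centers[y + 1, , drop = FALSE] + matrix(rnorm(rows * cols), rows)
      tab <- tibble::as_tibble(as.data.frame(x), .name_repair = "minimal")
      names(tab) <- sprintf("x%02d", seq_len(cols))
      tab$class <- factor(ifelse(y == 1, "pos", "neg"))
      tab
    })
    names(out) <- sprintf("tab%02d", seq_len(n_datasets))
    out
  })
}
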