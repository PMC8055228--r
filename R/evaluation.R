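# The simulation framework: repeated trials in which a recommender proposes
# configurations for randomly chosen datasets, receives their cached
# cross-validation ratings as feedback, and is scored on held-out ratings it
# never sees. This is the reinforcement-style loop in which the
# recommendations a strategy makes determine what it gets to learn.

#' Run one simulation trial
#'
#' Seeds the recommender with `n_init` uniformly sampled cross-validation
#' results, then iterates: pick a dataset at random, request `n_recs`
#' recommendations, reveal their `cv` ratings to the recommender as
#' feedback, and log their `holdout` ratings — which the recommender never
#' observes — to the trajectory. Recommendation exclusivity holds across the
#' whole trial: no (dataset, configuration) pair is proposed twice.
#'
#' @param kb An `ml_kb` holding `cv` and `holdout` ratings (the cache the
#'   simulation draws from).
#' @param strategy Recommender strategy name (see [recommender()]); ignored
#'   when `rec` is supplied.
#' @param n_init Number of seed results (≥ 1, ≤ available `cv` results).
#' @param n_recs Recommendations per iteration.
#' @param n_iterations Iterations in the trial.
#' @param seed Trial seed; every random draw in the trial derives from it.
#' @param sample_mode `"replace"` draws the iteration's dataset uniformly
#'   with replacement; `"epoch"` cycles through a fresh shuffle of all
#'   datasets every `n_datasets` iterations, guaranteeing even coverage.
#' @param rec Optional pre-built [recommender()] (e.g. an `oracle`); when
#'   supplied, `strategy` and `rec_args` are ignored.
#' @param rec_args Extra options passed to [recommender()].
#' @return A tibble of class `ml_trajectory`: one row per recommendation
#'   with `iteration`, `dataset`, `rank`, `config_id`, `cv_score`,
#'   `holdout_score`, `delta_ba` (relative regret of this recommendation),
#'   `best_so_far` (best held-out score among the experiments held for this
#'   dataset so far — recommendations plus any `n_init` seed results, which
#'   block their cells from re-recommendation and therefore must count) and
#'   `delta_best` (its relative regret). Attributes: `kb_best`, `strategy`,
#'   `config`, `n_skipped`, `init_achieved`.
#' @export
run_trial <- function(kb, strategy = "svd", n_init = 1L, n_recs = 10L,
                      n_iterations = 100L, seed = 1L,
                      sample_mode = c("replace", "epoch"),
                      rec = NULL, rec_args = list()) {
  sample_mode <- match.arg(sample_mode)
  stopifnot(n_init >= 1, n_recs >= 1, n_iterations >= 0)
  cv <- kb[kb$split == "cv", ]
  if (nrow(cv) == 0) abort("`kb` has no 'cv' results.")
  if (n_init > nrow(cv)) {
    abort(sprintf("n_init = %d exceeds the %d available cv results.",
                  n_init, nrow(cv)))
  }
  kb_best <- kb_best_scores(kb, "holdout")
  if (nrow(kb_best) == 0) abort("`kb` has no 'holdout' results.")
  datasets <- sort(unique(cv$dataset))
  configs <- sort(unique(cv$config_id))
  m_cv <- kb_ratings_matrix(kb, "cv")
  m_ho <- kb_ratings_matrix(kb, "holdout")
  best <- setNames(kb_best$best_score, kb_best$dataset)

  if (is.null(rec)) {
    rec <- do.call(recommender,
                   c(list(strategy = strategy,
                          seed = derive_seed(seed, 1L, "rec")), rec_args))
  }
  strategy <- rec$strategy

  init_idx <- with_seed(derive_seed(seed, 0L, "init_sample"),
                        sample.int(nrow(cv), n_init))
  rec <- rec_update(rec, cv[init_idx, ])
  used <- matrix(FALSE, length(datasets), length(configs),
                 dimnames = list(datasets, configs))
  used[cbind(match(cv$dataset[init_idx], datasets),
             match(cv$config_id[init_idx], configs))] <- TRUE
  # seed results are experiments the system already holds: they count
  # toward the best result achieved per dataset (they also block their
  # cells from re-recommendation, so they must not hide an optimum)
  init_achieved <- tibble::tibble(dataset = cv$dataset[init_idx],
                                  score = m_ho[cbind(cv$dataset[init_idx],
                                                     cv$config_id[init_idx])]) |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")

  ds_order <- if (sample_mode == "replace") {
    with_seed(derive_seed(seed, 0L, "dataset_pick"),
              sample(datasets, n_iterations, replace = TRUE))
  } else {
    with_seed(derive_seed(seed, 0L, "dataset_pick"), {
      n_ep <- ceiling(n_iterations / length(datasets))
      head(unlist(lapply(seq_len(max(n_ep, 1)),
                         function(i) sample(datasets))), n_iterations)
    })
  }

  best_so_far <- setNames(rep(NA_real_, length(datasets)), datasets)
  best_so_far[init_achieved$dataset] <- init_achieved$score
  rows <- vector("list", n_iterations)
  n_skipped <- 0L
  for (it in seq_len(n_iterations)) {
    d <- ds_order[it]
    excl <- configs[used[d, ]]
    recs <- suppressWarnings(
      recommend(rec, d, n = n_recs, candidates = configs, exclude = excl,
                seed = derive_seed(seed, it, "randrec"))
    )
    if (nrow(recs) == 0) next
    used[d, match(recs$config_id, configs)] <- TRUE
    cv_score <- m_cv[d, recs$config_id]
    known <- !is.na(cv_score)
    n_skipped <- n_skipped + sum(!known)
    recs <- recs[known, ]
    if (nrow(recs) == 0) next
    cv_score <- cv_score[known]
    ho_score <- m_ho[d, recs$config_id]
    rec <- rec_update(rec, tibble::tibble(dataset = d,
                                          config_id = recs$config_id,
                                          score = cv_score))
    bsf <- cummax(ifelse(is.na(ho_score), -Inf, ho_score))
    prev <- best_so_far[[d]]
    if (!is.na(prev)) bsf <- pmax(bsf, prev)
    best_so_far[[d]] <- bsf[length(bsf)]
    rows[[it]] <- tibble::tibble(
      iteration = it, dataset = d, rank = recs$rank,
      config_id = recs$config_id, cv_score = unname(cv_score),
      holdout_score = unname(ho_score),
      delta_ba = delta_ba(best[[d]], unname(ho_score)),
      best_so_far = unname(bsf),
      delta_best = delta_ba(best[[d]], unname(bsf))
    )
  }
  traj <- dplyr::bind_rows(rows)
  attr(traj, "kb_best") <- kb_best
  attr(traj, "strategy") <- strategy
  attr(traj, "config") <- list(n_init = n_init, n_recs = n_recs,
                               n_iterations = n_iterations, seed = seed,
                               sample_mode = sample_mode)
  attr(traj, "n_skipped") <- n_skipped
  attr(traj, "init_achieved") <- init_achieved
  class(traj) <- c("ml_trajectory", class(traj))
  traj
}

# Per-trial, per-iteration quality of the recommendations made at that
# iteration (regret of the iteration's best recommendation).
trial_iteration_values <- function(traj, n_iterations) {
  out <- rep(NA_real_, n_iterations)
  if (nrow(traj) == 0) return(out)
  agg <- traj |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(delta_iter = min(.data$delta_ba), .groups = "drop")
  out[agg$iteration] <- agg$delta_iter
  out
}

# Per-iteration state of one trial: the system-level regret (mean over
# datasets of the best-so-far relative regret, over datasets with at least
# one recommendation) and the cumulative success-rate curve at each
# threshold (fraction of all datasets whose best recommended configuration
# so far sits within the threshold of the dataset's optimum).
trial_state_curves <- function(traj, kb_best, n_iterations, thresholds) {
  best <- setNames(kb_best$best_score, kb_best$dataset)
  achieved <- setNames(rep(NA_real_, length(best)), names(best))
  init <- attr(traj, "init_achieved")
  if (!is.null(init) && nrow(init) > 0) achieved[init$dataset] <- init$score
  succ <- matrix(0, n_iterations, length(thresholds))
  regret <- rep(NA_real_, n_iterations)
  gaps <- rep(Inf, length(best))
  by_iter <- split(traj, traj$iteration)
  for (it in seq_len(n_iterations)) {
    rows <- by_iter[[as.character(it)]]
    if (!is.null(rows)) {
      for (j in seq_len(nrow(rows))) {
        d <- rows$dataset[j]
        if (is.na(achieved[[d]]) || rows$holdout_score[j] > achieved[[d]]) {
          achieved[[d]] <- rows$holdout_score[j]
        }
      }
      gaps <- ifelse(is.na(achieved), Inf,
                     delta_ba(best, ifelse(is.na(achieved), 0, achieved)))
    }
    succ[it, ] <- vapply(thresholds, function(th) mean(gaps <= th), numeric(1))
    seen <- is.finite(gaps)
    regret[it] <- if (any(seen)) mean(gaps[seen]) else NA_real_
  }
  list(regret = regret, success = succ)
}

#' Run a repeated-trial experiment
#'
#' Runs `n_trials` independent trials of [run_trial()] under derived seeds
#' and aggregates them into the two views used to compare strategies: the
#' per-iteration median relative regret (with a bootstrap 95% confidence
#' band over trials) and cumulative success-rate curves at each optimality
#' threshold.
#'
#' The headline regret at iteration `t` (column `median_delta_ba`) is the
#' system-level regret: within each trial, the mean over datasets (with at
#' least one recommendation so far) of the relative gap of the best
#' configuration recommended for that dataset, then the median of that mean
#' across trials. It answers "how far from optimal is the model the system
#' could deliver right now, on a typical dataset". The raw quality of the
#' recommendations made at `t` itself is also reported
#' (`median_delta_iter`); see the methods vignette for why the best-so-far
#' view is the headline once the no-repeats rule starts exhausting a finite
#' configuration grid.
#'
#' @inheritParams run_trial
#' @param n_trials Number of independent trials.
#' @param thresholds Relative optimality thresholds for success rates.
#' @param n_boot Bootstrap resamples (of whole trials) for the confidence
#'   band.
#' @return An object of class `ml_experiment`: a list with `summary` (one
#'   row per iteration: `median_delta_ba`, `ci_lo`, `ci_hi`,
#'   `median_delta_iter`, `evals`, one `success_rate_*` column per
#'   threshold), `trajectories` (all trials, with a `trial` column),
#'   `kb_best` and `config`. Supports [tidy()], [glance()], [autoplot()].
#' @export
run_experiment <- function(kb, strategy = "svd", n_trials = 30L,
                           n_init = 1L, n_recs = 10L, n_iterations = 100L,
                           thresholds = c(0.01, 0.05), seed = 1L,
                           n_boot = 1000L, sample_mode = "replace",
                           rec = NULL, rec_args = list()) {
  stopifnot(n_trials >= 1)
  trajectories <- purrr::map(seq_len(n_trials), function(t) {
    tr <- tryCatch(
      run_trial(kb, strategy = strategy, n_init = n_init, n_recs = n_recs,
                n_iterations = n_iterations,
                seed = derive_seed(seed, t, "trial"),
                sample_mode = sample_mode, rec = rec, rec_args = rec_args),
      error = function(e) abort(sprintf("trial %d failed: %s", t,
                                        conditionMessage(e)))
    )
    tr
  })
  kb_best <- attr(trajectories[[1]], "kb_best")
  strategy <- attr(trajectories[[1]], "strategy")

  v_iter <- vapply(trajectories, function(tr) {
    trial_iteration_values(tr, n_iterations)
  }, numeric(n_iterations))
  v_iter <- matrix(v_iter, nrow = n_iterations)
  state <- lapply(trajectories, function(tr) {
    trial_state_curves(tr, kb_best, n_iterations, thresholds)
  })
  v_regret <- matrix(vapply(state, `[[`, numeric(n_iterations), "regret"),
                     nrow = n_iterations)

  med <- apply(v_regret, 1, median, na.rm = TRUE)
  ci <- boot_median_ci(v_regret, n_boot,
                       seed = derive_seed(seed, 0L, "boot"))
  succ_mean <- Reduce(`+`, lapply(state, `[[`, "success")) / length(state)
  colnames(succ_mean) <- sprintf("success_rate_%gpct", thresholds * 100)

  summary <- tibble::tibble(
    iteration = seq_len(n_iterations),
    evals = seq_len(n_iterations) * n_recs,
    median_delta_ba = med,
    ci_lo = ci[1, ],
    ci_hi = ci[2, ],
    median_delta_iter = apply(v_iter, 1, median, na.rm = TRUE)
  )
  summary <- dplyr::bind_cols(summary, tibble::as_tibble(succ_mean))

  init_achieved <- purrr::imap_dfr(trajectories, function(tr, t) {
    ia <- attr(tr, "init_achieved")
    if (is.null(ia) || nrow(ia) == 0) return(NULL)
    ia$trial <- t
    ia
  })
  trajectories <- purrr::imap(trajectories, function(tr, t) {
    tr <- tibble::as_tibble(tr)
    tr$trial <- t
    tr
  })
  structure(
    list(summary = summary,
         trajectories = dplyr::bind_rows(trajectories),
         init_achieved = init_achieved,
         kb_best = kb_best,
         config = list(strategy = strategy, n_trials = n_trials,
                       n_init = n_init, n_recs = n_recs,
                       n_iterations = n_iterations, thresholds = thresholds,
                       seed = seed, n_boot = n_boot,
                       sample_mode = sample_mode)),
    class = "ml_experiment"
  )
}

# Percentile bootstrap of the across-trial median, resampling whole trials
# so within-trial dependence is preserved.
boot_median_ci <- function(v, n_boot, seed, probs = c(0.025, 0.975)) {
  n_trials <- ncol(v)
  idx <- with_seed(seed, matrix(sample.int(n_trials, n_boot * n_trials,
                                           replace = TRUE), n_boot))
  meds <- apply(idx, 1, function(ii) {
    apply(v[, ii, drop = FALSE], 1, median, na.rm = TRUE)
  })
  meds <- matrix(meds, ncol = n_boot)
  apply(meds, 1, quantile, probs = probs, na.rm = TRUE, names = FALSE)
}

#' Leave-one-out deployment analysis
#'
#' Emulates deployment on a new dataset: the recommender is trained on the
#' cross-validation results of every *other* dataset, then iteratively
#' recommends for the held-out dataset with cross-validation feedback,
#' while held-out-test regret is logged per evaluation.
#'
#' @inheritParams run_trial
#' @param dataset The dataset to hold out and recommend for.
#' @param budget Maximum number of configuration evaluations.
#' @return An `ml_trajectory` tibble with one row per evaluation
#'   (`iteration` counts evaluations; `rank` is always 1).
#' @export
leave_one_out <- function(kb, dataset, budget, strategy = "svd", seed = 1L,
                          rec = NULL, rec_args = list()) {
  stopifnot(budget >= 1)
  if (!dataset %in% kb$dataset) {
    abort(sprintf("unknown dataset '%s'.", dataset))
  }
  cv <- kb[kb$split == "cv", ]
  train <- cv[cv$dataset != dataset, ]
  if (nrow(train) == 0) abort("no other datasets to train on.")
  if (is.null(rec)) {
    rec <- do.call(recommender,
                   c(list(strategy = strategy,
                          seed = derive_seed(seed, 1L, "rec")), rec_args))
  }
  rec <- rec_update(rec, train)
  configs <- sort(unique(cv$config_id))
  m_cv <- kb_ratings_matrix(kb, "cv")
  m_ho <- kb_ratings_matrix(kb, "holdout")
  best <- kb_best_score(kb, dataset, "holdout")
  revealed <- character(0)
  rows <- list()
  for (it in seq_len(budget)) {
    recs <- suppressWarnings(
      recommend(rec, dataset, n = 1L, candidates = configs,
                exclude = revealed, seed = derive_seed(seed, it, "randrec"))
    )
    if (nrow(recs) == 0) break
    cid <- recs$config_id[1]
    revealed <- c(revealed, cid)
    cv_score <- m_cv[dataset, cid]
    if (is.na(cv_score)) next
    ho_score <- m_ho[dataset, cid]
    rec <- rec_update(rec, tibble::tibble(dataset = dataset,
                                          config_id = cid,
                                          score = cv_score))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      iteration = it, dataset = dataset, rank = 1L, config_id = cid,
      cv_score = unname(cv_score), holdout_score = unname(ho_score),
      delta_ba = delta_ba(best, unname(ho_score))
    )
  }
  traj <- dplyr::bind_rows(rows)
  if (nrow(traj) > 0) {
    traj$best_so_far <- cummax(traj$holdout_score)
    traj$delta_best <- delta_ba(best, traj$best_so_far)
  }
  attr(traj, "kb_best") <- tibble::tibble(dataset = dataset,
                                          best_score = best)
  attr(traj, "strategy") <- rec$strategy
  attr(traj, "config") <- list(dataset = dataset, budget = budget,
                               seed = seed)
  class(traj) <- c("ml_trajectory", class(traj))
  traj
}

#' @export
print.ml_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ml_experiment: %s> %d trial(s) x %d iteration(s), n_init = %d, n_recs = %d\n",
    cfg$strategy, cfg$n_trials, cfg$n_iterations, cfg$n_init, cfg$n_recs))
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf("final median relative regret: %.4f [%.4f, %.4f]\n",
              last$median_delta_ba, last$ci_lo, last$ci_hi))
  invisible(x)
}

#' @export
tidy.ml_experiment <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(strategy = x$config$strategy), x$summary)
}

#' @export
glance.ml_experiment <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  out <- tibble::tibble(
    strategy = x$config$strategy,
    n_trials = x$config$n_trials,
    n_iterations = x$config$n_iterations,
    n_init = x$config$n_init,
    n_recs = x$config$n_recs,
    final_median_delta_ba = last$median_delta_ba,
    final_ci_lo = last$ci_lo,
    final_ci_hi = last$ci_hi
  )
  for (cl in grep("^success_rate_", names(last), value = TRUE)) {
    out[[paste0("final_", cl)]] <- last[[cl]]
  }
  out
}

#' Write experiment outputs as tidy delimited tables
#'
#' Writes `trajectory.csv` (per-recommendation rows) and `summary.csv`
#' (per-iteration aggregates) into a directory.
#'
#' @param x An `ml_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
experiment_write <- function(x, dir) {
  stopifnot(inherits(x, "ml_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$trajectories, file.path(dir, "trajectory.csv"))
  readr::write_csv(x$summary, file.path(dir, "summary.csv"))
  invisible(dir)
}
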