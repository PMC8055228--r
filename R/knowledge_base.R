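#' Canonical identifier for an algorithm configuration
#'
#' A configuration is an algorithm name plus a flat mapping of hyperparameter
#' names to scalar values. Its identifier is a pure function of that content:
#' parameters are serialized with lexicographically sorted keys into a compact
#' `key=value` string joined to the algorithm name, so key insertion order
#' never matters and equal content always yields an equal id.
#'
#' @param algorithm Non-empty algorithm name.
#' @param params Named list (or empty list) of scalar hyperparameter values
#'   (number, string, or logical).
#' @return A single identifier string.
#' @examples
#' config_id("rf", list(n_estimators = 100, max_depth = 5))
#' config_id("rf", list(max_depth = 5, n_estimators = 100)) # same id
#' @export
config_id <- function(algorithm, params = list()) {
  if (!is.character(algorithm) || length(algorithm) != 1 || !nzchar(algorithm)) {
    abort("`algorithm` must be a single non-empty string.")
  }
  if (length(params) == 0) {
    return(algorithm)
  }
  if (is.null(names(params)) || any(!nzchar(names(params)))) {
    abort("all `params` must be named.")
  }
  vals <- vapply(params, format_param_value, character(1))
  keys <- names(params)
  ord <- order(keys, method = "radix")
  paste0(algorithm, "|", paste0(keys[ord], "=", vals[ord], collapse = ";"))
}

# Deterministic scalar formatting: integers without decimal point, doubles at
# full precision, logicals in JSON spelling. Non-scalar values are an error
# rather than being silently flattened.
format_param_value <- function(x) {
  if (is.list(x) || length(x) != 1 || is.null(x)) {
    abort("hyperparameter values must be scalar (length-1, non-list).")
  }
  if (is.na(x)) {
    return("NA")
  }
  if (is.logical(x)) {
    return(if (x) "true" else "false")
  }
  if (is.numeric(x)) {
    if (is.finite(x) && x == round(x) && abs(x) < 1e15) {
      return(format(x, scientific = FALSE, nsmall = 0, trim = TRUE))
    }
    return(format(x, digits = 15, trim = TRUE))
  }
  as.character(x)
}

kb_required_cols <- c("dataset", "algorithm", "parameters", "score")
kb_all_cols <- c("dataset", "algorithm", "parameters", "config_id",
                 "metric", "score", "split")

#' Assemble a knowledge base of experiment results
#'
#' The knowledge base is the accumulated set of scored
#' (dataset, configuration) pairs that every recommender learns from: a tidy
#' tibble that doubles as a sparse ratings matrix in which datasets play the
#' role of users and algorithm configurations the role of items. Scores are
#' ratings in \[0, 1\] (typically cross-validated balanced accuracy). Each
#' result carries a `split` tag: `"cv"` ratings are fed to recommenders,
#' `"holdout"` ratings are reserved for assessment and never shown to them.
#'
#' Rows sharing the deduplication key (`dataset`, `config_id`, `split`) are
#' collapsed latest-wins, mirroring an online system receiving corrected
#' reruns; the number of replacements is reported and stored in the
#' `"n_replaced"` attribute. Out-of-range scores are an error here (use
#' [kb_read()] for tolerant row-rejecting ingestion).
#'
#' @param results Data frame with columns `dataset`, `algorithm`,
#'   `parameters` (JSON object string, may be missing or `"{}"`), `score`,
#'   and optionally `config_id`, `metric` (default `"balanced_accuracy"`),
#'   `split` (default `"cv"`).
#' @param quiet Suppress the replacement message.
#' @return A tibble of class `ml_kb` with columns `dataset`, `algorithm`,
#'   `parameters`, `config_id`, `metric`, `score`, `split`.
#' @seealso [kb_read()], [kb_write()], [kb_best_score()], [kb_ratings_matrix()]
#' @export
as_kb <- function(results, quiet = FALSE) {
  if (!is.data.frame(results)) {
    abort("`results` must be a data frame.")
  }
  results <- tibble::as_tibble(results)
  missing_cols <- setdiff(c("dataset", "algorithm", "score"), names(results))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"parameters" %in% names(results)) results$parameters <- "{}"
  results$parameters[is.na(results$parameters) | !nzchar(results$parameters)] <- "{}"
  if (!"metric" %in% names(results)) results$metric <- "balanced_accuracy"
  if (!"split" %in% names(results)) results$split <- "cv"
  if (!is.numeric(results$score)) abort("`score` must be numeric.")
  bad <- !is.finite(results$score) | results$score < 0 | results$score > 1
  if (any(bad)) {
    abort(sprintf("%d score(s) outside [0, 1]; scores are rejected, never clipped.",
                  sum(bad)))
  }
  if (!"config_id" %in% names(results)) {
    results$config_id <- vapply(seq_len(nrow(results)), function(i) {
      config_id(results$algorithm[i], parse_params(results$parameters[i]))
    }, character(1))
  }
  key <- paste(results$dataset, results$config_id, results$split, sep = "\r")
  dup <- duplicated(key, fromLast = TRUE)
  n_replaced <- sum(dup)
  if (n_replaced > 0 && !quiet) {
    inform(sprintf("knowledge base: %d duplicate key(s) replaced (latest wins).",
                   n_replaced))
  }
  kb <- results[!dup, kb_all_cols]
  attr(kb, "n_replaced") <- n_replaced
  class(kb) <- c("ml_kb", class(tibble::tibble()))
  kb
}

parse_params <- function(json) {
  if (is.na(json) || !nzchar(json)) {
    return(list())
  }
  out <- tryCatch(jsonlite::fromJSON(json, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(out)) abort(paste0("unparseable parameter payload: ", json))
  as.list(out)
}

#' Read a knowledge base from a delimited results file
#'
#' The file format is delimited text (comma or tab, auto-detected unless
#' `delim` is given) with a header naming at least `dataset`, `algorithm`,
#' `parameters` (a JSON object string) and `score`; `metric` and `split`
#' columns are optional. Invalid rows — scores outside \[0, 1\] or an
#' unparseable parameter payload — are rejected individually with a reason
#' rather than failing the load; rejected rows are reported and kept in the
#' `"rejected"` attribute. Duplicate (dataset, configuration, split) keys are
#' collapsed latest-wins.
#'
#' @param path Path to the results file.
#' @param delim Field delimiter; `NULL` auto-detects comma versus tab from
#'   the header line.
#' @param quiet Suppress the load report message.
#' @return An `ml_kb` tibble (see [as_kb()]) with attributes `n_replaced`,
#'   `n_rejected` and `rejected` (a tibble of dropped rows with reasons).
#' @export
kb_read <- function(path, delim = NULL, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing_cols <- setdiff(kb_required_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("results file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw$score <- suppressWarnings(as.numeric(raw$score))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(raw$score)] <- "non-numeric score"
  oob <- !is.na(raw$score) & (raw$score < 0 | raw$score > 1)
  reason[oob] <- "score outside [0, 1]"
  cid <- rep(NA_character_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (!is.na(reason[i])) next
    p <- tryCatch(parse_params(raw$parameters[i]), error = function(e) NULL)
    if (is.null(p)) {
      reason[i] <- "unparseable parameter payload"
    } else {
      cid[i] <- tryCatch(config_id(raw$algorithm[i], p),
                         error = function(e) NA_character_)
      if (is.na(cid[i])) reason[i] <- "invalid algorithm/parameters"
    }
  }
  keep <- is.na(reason)
  rejected <- tibble::as_tibble(raw[!keep, ])
  rejected$reason <- reason[!keep]
  good <- raw[keep, ]
  good$config_id <- cid[keep]
  kb <- as_kb(good, quiet = TRUE)
  if (!quiet) {
    inform(sprintf(
      "kb_read: %d row(s) loaded, %d duplicate(s) replaced, %d row(s) rejected.",
      nrow(kb), attr(kb, "n_replaced"), nrow(rejected)))
  }
  attr(kb, "n_rejected") <- nrow(rejected)
  attr(kb, "rejected") <- rejected
  kb
}

#' Write a knowledge base to a delimited results file
#'
#' Writes the same format [kb_read()] loads, so a save/load round trip
#' preserves every (key, rating) pair at the numeric precision written.
#'
#' @param kb Knowledge base (or any data frame accepted by [as_kb()]).
#' @param path Output path.
#' @param delim Field delimiter (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
kb_write <- function(kb, path, delim = ",") {
  kb <- as_kb(kb, quiet = TRUE)
  out <- kb
  out$score <- format(out$score, digits = 15, trim = TRUE, scientific = FALSE)
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Best stored score for a dataset
#'
#' The best-known score of any stored configuration on one dataset under one
#' split tag — the reference point `BA*` against which recommendation regret
#' is measured.
#'
#' @param kb Knowledge base.
#' @param dataset Dataset identifier.
#' @param split Split tag, `"holdout"` (default) or `"cv"`.
#' @return The maximum stored score (a single number).
#' @export
kb_best_score <- function(kb, dataset, split = "holdout") {
  sel <- kb$dataset == dataset & kb$split == split
  if (!any(sel)) {
    abort(sprintf("no '%s' results stored for dataset '%s'.", split, dataset))
  }
  max(kb$score[sel])
}

#' Best stored score per dataset
#'
#' @inheritParams kb_best_score
#' @return A tibble with columns `dataset` and `best_score`, one row per
#'   dataset that has results under `split`.
#' @export
kb_best_scores <- function(kb, split = "holdout") {
  kb |>
    dplyr::filter(.data$split == !!split) |>
    dplyr::group_by(.data$dataset) |>
    dplyr::summarise(best_score = max(.data$score), .groups = "drop")
}

#' Sparse ratings view of a knowledge base
#'
#' Datasets-by-configurations score matrix for one split tag, with `NA` for
#' unobserved cells. Exactly one cell is filled per stored key.
#'
#' @inheritParams kb_best_score
#' @return A numeric matrix with dataset ids as row names and configuration
#'   ids as column names.
#' @export
kb_ratings_matrix <- function(kb, split = "cv") {
  rows <- kb[kb$split == split, ]
  datasets <- sort(unique(rows$dataset))
  configs <- sort(unique(rows$config_id))
  m <- matrix(NA_real_, length(datasets), length(configs),
              dimnames = list(datasets, configs))
  m[cbind(match(rows$dataset, datasets), match(rows$config_id, configs))] <-
    rows$score
  m
}

#' @export
print.ml_kb <- function(x, ...) {
  cat(sprintf("# Knowledge base: %d result(s), %d dataset(s), %d configuration(s)\n",
              nrow(x), length(unique(x$dataset)), length(unique(x$config_id))))
  NextMethod()
}
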