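#' Metafeatures of a labeled classification table
#'
#' Computes a fixed-length numeric description of a dataset for use by the
#' metalearning (`knn-meta`) recommender, which recommends for a brand-new
#' dataset by finding previously seen datasets with similar descriptions.
#' The set is deliberately cheap and landmark-free: simple counts, class
#' balance, feature-variance summaries and feature-target association.
#'
#' Metafeatures, in order: `n_samples`, `n_features`, `n_classes`,
#' `log_n_samples`, `log_n_features`, `class_entropy` (natural log),
#' `class_imbalance` (majority-class fraction minus `1/n_classes`, zero for a
#' perfectly balanced target), `frac_categorical` (fraction of non-numeric
#' feature columns), `mean_feature_variance`, `median_feature_variance`,
#' `var_feature_variance` (over per-feature variances of numeric columns),
#' and `mean_abs_correlation` (mean absolute Pearson correlation between
#' numeric features and the integer-coded target). Missing values are
#' median-imputed per numeric column first, so every loadable table has
#' finite metafeatures.
#'
#' @param table Data frame with at least two rows, at least one feature
#'   column, and a target column with at least two classes.
#' @param target Name of the target column (default `"class"`).
#' @param dataset Optional dataset identifier to include in the result.
#' @return A one-row tibble: `dataset` (if given) followed by the twelve
#'   metafeatures in fixed order.
#' @export
compute_metafeatures <- function(table, target = "class", dataset = NULL) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    abort("`table` must be a non-empty data frame.")
  }
  if (!target %in% names(table)) {
    abort(sprintf("target column '%s' not found.", target))
  }
  y <- table[[target]]
  x <- table[setdiff(names(table), target)]
  if (ncol(x) < 1) abort("`table` must have at least one feature column.")
  if (nrow(table) < 2) abort("`table` must have at least two rows.")
  classes <- table(as.character(y))
  if (length(classes) < 2) {
    abort("target has a single class; need at least two.")
  }
  p <- as.numeric(classes) / sum(classes)
  is_num <- vapply(x, is.numeric, logical(1))
  xnum <- x[is_num]
  # median imputation per numeric column before any moment is computed
  xnum[] <- lapply(xnum, function(col) {
    col[is.na(col)] <- median(col, na.rm = TRUE)
    col
  })
  variances <- if (ncol(xnum) > 0) {
    vapply(xnum, function(col) var(col), numeric(1))
  } else {
    numeric(0)
  }
  y_int <- as.integer(factor(y))
  cors <- if (ncol(xnum) > 0) {
    vapply(xnum, function(col) {
      if (var(col) == 0 || var(y_int) == 0) return(0)
      abs(cor(col, y_int))
    }, numeric(1))
  } else {
    numeric(0)
  }
  finite0 <- function(v) if (length(v) == 0 || !is.finite(v)) 0 else v
  out <- tibble::tibble(
    n_samples = as.numeric(nrow(table)),
    n_features = as.numeric(ncol(x)),
    n_classes = as.numeric(length(classes)),
    log_n_samples = log(nrow(table)),
    log_n_features = log(ncol(x)),
    class_entropy = -sum(p * log(p)),
    class_imbalance = max(p) - 1 / length(classes),
    frac_categorical = mean(!is_num),
    mean_feature_variance = finite0(mean(variances)),
    median_feature_variance = finite0(median(variances)),
    var_feature_variance = finite0(var(variances)),
    mean_abs_correlation = finite0(mean(cors))
  )
  if (!is.null(dataset)) {
    out <- dplyr::bind_cols(tibble::tibble(dataset = dataset), out)
  }
  out
}

metafeature_names <- function() {
  c("n_samples", "n_features", "n_classes", "log_n_samples", "log_n_features",
    "class_entropy", "class_imbalance", "frac_categorical",
    "mean_feature_variance", "median_feature_variance",
    "var_feature_variance", "mean_abs_correlation")
}

#' Robust per-dimension scaling for a metafeature cache
#'
#' Count-type metafeatures span orders of magnitude, so distances are taken
#' on robust-scaled dimensions: each metafeature is centered by its median
#' and divided by its IQR across the cache's datasets (IQR zero falls back
#' to 1 so constant dimensions contribute nothing).
#'
#' @param cache Tibble with a `dataset` column and one column per
#'   metafeature (as written by [compute_metafeatures()] row-binding).
#' @return A tibble with columns `name`, `center`, `scale`.
#' @export
metafeature_scaling <- function(cache) {
  cols <- setdiff(names(cache), "dataset")
  tibble::tibble(
    name = cols,
    center = vapply(cols, function(cl) median(cache[[cl]]), numeric(1),
                    USE.NAMES = FALSE),
    scale = vapply(cols, function(cl) {
      s <- stats::IQR(cache[[cl]])
      if (s == 0 || !is.finite(s)) 1 else s
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Distance between two metafeature vectors
#'
#' Euclidean distance after per-dimension scaling. Symmetric, zero iff the
#' scaled vectors are equal. Vector names must align exactly: a distance
#' between differently described datasets is meaningless.
#'
#' @param a,b Named numeric vectors (or one-row data frames) of
#'   metafeatures with identical names in identical order.
#' @param scaling Optional scaling tibble from [metafeature_scaling()];
#'   `NULL` uses unscaled Euclidean distance.
#' @return A non-negative scalar.
#' @export
metafeature_distance <- function(a, b, scaling = NULL) {
  a <- mf_as_vector(a)
  b <- mf_as_vector(b)
  if (!identical(names(a), names(b))) {
    abort("metafeature names do not align between `a` and `b`.")
  }
  if (!is.null(scaling)) {
    idx <- match(names(a), scaling$name)
    if (anyNA(idx)) abort("`scaling` lacks entries for some metafeatures.")
    a <- (a - scaling$center[idx]) / scaling$scale[idx]
    b <- (b - scaling$center[idx]) / scaling$scale[idx]
  }
  sqrt(sum((a - b)^2))
}

mf_as_vector <- function(x) {
  if (is.data.frame(x)) {
    x <- x[setdiff(names(x), "dataset")]
    if (nrow(x) != 1) abort("expected a one-row metafeature data frame.")
    x <- unlist(x)
  }
  if (!is.numeric(x) || is.null(names(x))) {
    abort("metafeature vectors must be named numeric vectors.")
  }
  x
}

#' Read / write a metafeature cache
#'
#' The cache is delimited text with one row per dataset: a `dataset` column
#' followed by metafeature columns. Because the `knn-meta` recommender only
#' requires aligned names, a user-supplied cache with a different
#' metafeature set is accepted as-is.
#'
#' @param path Cache file path.
#' @param cache Cache tibble.
#' @param delim Field delimiter.
#' @return `metafeature_cache_read()` returns the cache tibble;
#'   `metafeature_cache_write()` returns `path` invisibly.
#' @export
metafeature_cache_read <- function(path, delim = ",") {
  readr::read_delim(path, delim = delim, col_types = readr::cols(
    dataset = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' @rdname metafeature_cache_read
#' @export
metafeature_cache_write <- function(cache, path, delim = ",") {
  readr::write_delim(cache, path, delim = delim)
  invisible(path)
}
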