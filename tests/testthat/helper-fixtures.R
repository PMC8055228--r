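# Fixtures are built in code: small dense rating matrices wrapped into
# knowledge bases, with independent cv/holdout layers where needed.

# Build an ml_kb from dense score matrices (rownames = datasets, colnames =
# config ids). `holdout` defaults to the cv matrix.
kb_from_matrix <- function(cv, holdout = cv) {
  stopifnot(identical(dimnames(cv), dimnames(holdout)))
  cells <- expand.grid(dataset = rownames(cv), config_id = colnames(cv),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  one <- function(m, tag) {
    sc <- m[cbind(cells$dataset, cells$config_id)]
    keep <- !is.na(sc)
    tibble::tibble(dataset = cells$dataset[keep],
                   algorithm = sub("\\|.*$", "", cells$config_id[keep]),
                   parameters = "{}",
                   config_id = cells$config_id[keep],
                   metric = "balanced_accuracy",
                   score = sc[keep], split = tag)
  }
  as_kb(dplyr::bind_rows(one(cv, "cv"), one(holdout, "holdout")),
        quiet = TRUE)
}

# A knowledge base in which one configuration dominates every dataset.
dominant_kb <- function(n_datasets = 4, n_configs = 5, dominant = "cfg1") {
  set.seed(99)
  m <- matrix(runif(n_datasets * n_configs, 0.4, 0.7), n_datasets,
              dimnames = list(sprintf("d%d", seq_len(n_datasets)),
                              sprintf("cfg%d", seq_len(n_configs))))
  m[, dominant] <- 0.95
  kb_from_matrix(m)
}

# Results tibble from vectors, for rec_update().
results_tbl <- function(dataset, config_id, score) {
  tibble::tibble(dataset = dataset, config_id = config_id, score = score)
}

expect_no_warning <- function(expr) expect_warning(expr, regexp = NA)
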