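#' Fit feature standardization parameters
#'
#' Computes the per-feature centre and scale used to bring every feature to
#' zero mean and unit spread before any distance or regression computation.
#' The scale is the population standard deviation (1/n denominator), so a
#' standardized column has population variance exactly 1.
#'
#' @param data a data frame or matrix of numeric feature columns (no label
#'   column).
#' @return A tibble of class `std_params` with columns `feature`, `center`,
#'   `scale`, one row per feature.
#' @seealso [standardize_apply()], [destandardize()]
#' @examples
#' p <- standardize_fit(data.frame(a = c(1, 2, 3)))
#' p$scale  # sqrt(2/3)
#' @export
standardize_fit <- function(data) {
  x <- as_feature_matrix(data)
  if (nrow(x) < 2) abort("need at least 2 samples to standardize")
  mu <- colMeans(x)
  sc <- sqrt(colMeans(sweep(x, 2, mu)^2))
  bad <- !is.finite(sc) | sc <= 0
  if (any(bad)) {
    abort(sprintf("constant feature (zero variance): %s",
                  paste(colnames(x)[bad], collapse = ", ")))
  }
  structure(
    tibble::tibble(feature = colnames(x), center = unname(mu),
                   scale = unname(sc)),
    class = c("std_params", "tbl_df", "tbl", "data.frame"))
}

#' Apply (or invert) a fitted standardization
#'
#' `standardize_apply()` maps each feature x to (x - center) / scale using
#' parameters from [standardize_fit()]; `destandardize()` undoes it. Columns
#' are matched by name when the input has names, by position otherwise.
#'
#' @param data a data frame or matrix of numeric features.
#' @param params a `std_params` tibble from [standardize_fit()].
#' @return A tibble with the same shape as `data`.
#' @export
standardize_apply <- function(data, params) {
  x <- match_features(data, params)
  out <- sweep(sweep(x, 2, params$center), 2, params$scale, "/")
  tibble::as_tibble(out)
}

#' @rdname standardize_apply
#' @export
destandardize <- function(data, params) {
  x <- match_features(data, params)
  out <- sweep(sweep(x, 2, params$scale, "*"), 2, params$center, "+")
  tibble::as_tibble(out)
}

match_features <- function(data, params) {
  stopifnot(inherits(params, "std_params"))
  x <- as_feature_matrix(data)
  if (ncol(x) != nrow(params)) {
    abort(sprintf("feature count mismatch: data has %d, params %d",
                  ncol(x), nrow(params)))
  }
  if (!is.null(colnames(x)) && all(params$feature %in% colnames(x))) {
    x <- x[, params$feature, drop = FALSE]
  }
  x
}

#' Split a dataset into leading training block and trailing simulation block
#'
#' Deterministic chronological split: the first `n_train` rows become the
#' training set, the remainder the simulation (test) set. This mirrors the
#' usual forecasting protocol for yearly field records (e.g. 45 of 60
#' seasons for training, the last 15 for simulation).
#'
#' @param data a data frame.
#' @param n_train number of leading rows for training; must leave both sets
#'   nonempty.
#' @return A named list with tibbles `train` and `sim`.
#' @examples
#' s <- split_leading(data.frame(x = 1:10), 7)
#' nrow(s$train); nrow(s$sim)
#' @export
split_leading <- function(data, n_train) {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  if (!is.numeric(n_train) || length(n_train) != 1 || n_train < 1 ||
      n_train >= n) {
    abort(sprintf(
      "n_train must select a nonempty proper leading block (got %s of %d rows)",
      format(n_train), n))
  }
  n_train <- as.integer(n_train)
  list(train = tibble::as_tibble(data[seq_len(n_train), , drop = FALSE]),
       sim = tibble::as_tibble(data[(n_train + 1L):n, , drop = FALSE]))
}

#' Read / write a labelled dataset from CSV
#'
#' The expected schema is a header row, one label column (named by `label`,
#' default `"class"`), and numeric feature columns; UTF-8, `.` decimal.
#' Missing values are rejected.
#'
#' @param path file path.
#' @param label name of the label column; must be present for `read_dataset`.
#' @param data a data frame to write.
#' @return `read_dataset()` returns a tibble; `write_dataset()` its input,
#'   invisibly.
#' @export
read_dataset <- function(path, label = "class") {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!label %in% names(data)) {
    abort(sprintf("label column '%s' not found in %s", label, path))
  }
  feats <- setdiff(names(data), c(label, "sample_id"))
  as_feature_matrix(data[feats], what = path)  # validates: numeric, no NA
  if (anyNA(data[[label]])) abort(sprintf("missing labels in %s", path))
  if (nrow(data) < 2) abort("dataset must have at least 2 samples")
  data
}

#' @rdname read_dataset
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}
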