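#' @importFrom rlang %||% abort warn .data
#' @importFrom stats cov dist mahalanobis prcomp predict runif rnorm var
#'   as.hclust
NULL

# Coerce a data frame / tibble / matrix of features to a numeric matrix,
# preserving column names. Errors on non-numeric columns or missing values.
as_feature_matrix <- function(data, what = "data") {
  if (is.matrix(data)) {
    x <- data
    storage.mode(x) <- "double"
  } else if (is.data.frame(data)) {
    ok <- vapply(data, is.numeric, logical(1))
    if (!all(ok)) {
      abort(sprintf("non-numeric feature column(s) in %s: %s", what,
                    paste(names(data)[!ok], collapse = ", ")))
    }
    x <- as.matrix(data)
  } else if (is.numeric(data)) {
    x <- matrix(as.double(data), ncol = 1)
  } else {
    abort(sprintf("%s must be a matrix or data frame of numeric features", what))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("missing or non-finite values in %s", what))
  }
  cn <- colnames(x)
  if (is.null(cn) || any(cn == "") || anyDuplicated(cn)) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  x
}

# Frobenius norm
fnorm <- function(m) sqrt(sum(m^2))

#' Rand index between two partitions
#'
#' Proportion of sample pairs on which two partitions agree (both together or
#' both apart). 1 means the partitions are identical up to label permutation.
#'
#' @param a,b integer or factor vectors of equal length assigning each sample
#'   to a cluster.
#' @return A number in \[0, 1\].
#' @examples
#' rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1: same partition, relabelled
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  tab <- table(a, b)
  n <- length(a)
  same_a <- sum(choose(rowSums(tab), 2))
  same_b <- sum(choose(colSums(tab), 2))
  same_ab <- sum(choose(tab, 2))
  agree <- choose(n, 2) + 2 * same_ab - same_a - same_b
  agree / choose(n, 2)
}

# Symmetric inverse with a pseudo-inverse fallback for singular matrices.
# method "pseudo": Moore-Penrose via MASS::ginv (default; covariance matrices
# become singular whenever p >= n or features are collinear);
# "solve": plain inverse, errors if singular; "ridge": (V + eps*I)^-1 with
# eps = ridge_eps * trace(V)/p.
safe_inverse <- function(v, method = c("pseudo", "solve", "ridge"),
                         ridge_eps = 1e-8) {
  method <- match.arg(method)
  v <- (v + t(v)) / 2
  switch(method,
    solve = solve(v),
    ridge = solve(v + diag(ridge_eps * sum(diag(v)) / ncol(v), ncol(v))),
    pseudo = {
      inv <- tryCatch(solve(v), error = function(e) NULL)
      if (is.null(inv) || !all(is.finite(inv)) ||
          rcond_est(v) < 1e-10) MASS::ginv(v) else inv
    })
}

rcond_est <- function(v) {
  tryCatch(rcond(v), error = function(e) 0)
}
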