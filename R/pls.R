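#' Fit a partial least squares model by NIPALS
#'
#' Decomposes the (standardized) feature matrix X and response Y into score
#' and loading factors, X = T P' + E and Y = U Q' + F, extracting one
#' component at a time by the alternating NIPALS iteration: each component's
#' X-weight vector w maximizes the covariance between the X-score t = Xw and
#' the current Y residual, Y is regressed on t (the inner relation u = b t),
#' and both matrices are deflated before the next component. The regression
#' coefficient matrix on the standardized scale is B = W (P' W)^-1 Q'.
#'
#' Unlike ordinary least squares, the fit is defined even when p >= n or X is
#' collinear — the property that makes the method suitable for small samples
#' with redundant features. With all `min(n - 1, p)` components (and X full
#' rank, n > p) the fitted values coincide with the OLS fit.
#'
#' Both X and Y are standardized internally (population standard deviation);
#' predictions are returned on the original Y scale.
#'
#' @param x matrix or data frame of features (n x p).
#' @param y numeric vector or matrix of responses (n x q).
#' @param ncomp number of components to extract; `NULL` (default) means
#'   `min(n - 1, p)`. If X runs out of rank earlier, extraction stops and the
#'   achieved count is recorded.
#' @param tol convergence tolerance on the change of the score vector in the
#'   inner NIPALS iteration.
#' @param max_iter inner-iteration cap per component; exceeding it is an
#'   error naming the component.
#' @param rank_tol X residual Frobenius norm (relative to the initial norm)
#'   below which X is considered rank-exhausted.
#' @return An object of class `pls_model`: a list with score matrix `scores`
#'   (T), X-loadings `x_loadings` (P), Y-scores `y_scores` (U), Y-loadings
#'   `y_loadings` (Q), weights `weights` (W), projection `projection`
#'   (R = W (P'W)^-1 such that T = X R), coefficients `coefficients` (B),
#'   `ncomp`, per-component residual norms, and the centring/scaling data.
#' @seealso [pls_select_ncomp()], [pls_scores()], [predict.pls_model()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20, 3)
#' y <- x %*% c(1, -1, 0.5) + rnorm(20, sd = 0.01)
#' fit <- pls_fit(x, y)
#' glance(fit)
#' @export
pls_fit <- function(x, y, ncomp = NULL, tol = 1e-10, max_iter = 500,
                    rank_tol = 1e-8) {
  x <- as_feature_matrix(x, "x")
  ym <- if (is.matrix(y)) y else matrix(as.double(y), ncol = 1)
  if (is.null(colnames(ym))) colnames(ym) <- paste0("y", seq_len(ncol(ym)))
  if (nrow(ym) != nrow(x)) abort("x and y must have the same number of rows")
  n <- nrow(x); p <- ncol(x); q <- ncol(ym)
  if (n < 2) abort("need at least 2 samples")

  xp <- standardize_fit(x)
  # a constant response is legal here (e.g. a single-label subclass): it
  # standardizes with unit scale and yields ~zero coefficients
  y_mu <- colMeans(ym)
  y_sc <- sqrt(colMeans(sweep(ym, 2, y_mu)^2))
  y_sc[y_sc <= 0 | !is.finite(y_sc)] <- 1
  yp <- structure(
    tibble::tibble(feature = colnames(ym), center = unname(y_mu),
                   scale = unname(y_sc)),
    class = c("std_params", "tbl_df", "tbl", "data.frame"))
  X <- as.matrix(standardize_apply(x, xp))
  Y <- as.matrix(standardize_apply(ym, yp))

  max_allowed <- min(n - 1L, p)
  ncomp <- as.integer(min(ncomp %||% max_allowed, max_allowed))
  if (ncomp < 1) abort("ncomp must be at least 1")

  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); U <- matrix(0, n, ncomp)
  Q <- matrix(0, q, ncomp); b_inner <- numeric(ncomp)
  x_res <- numeric(ncomp); y_res <- numeric(ncomp)
  x0 <- fnorm(X)
  achieved <- 0L

  for (a in seq_len(ncomp)) {
    if (fnorm(X) <= rank_tol * max(x0, 1)) break  # rank exhausted
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    if (all(u == 0)) u <- Y[, 1] + 0  # degenerate Y residual: fall back
    t_old <- rep(Inf, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(X, u))
      den <- sum(u^2)
      if (den > 0) w <- w / den
      nw <- sqrt(sum(w^2))
      if (nw == 0) {
        # Y residual orthogonal to X column space: take the dominant X
        # direction so the component is still well defined (B stays ~0).
        w <- drop(crossprod(X, X[, which.max(colSums(X^2))]))
        nw <- sqrt(sum(w^2))
        if (nw == 0) break
      }
      w <- w / nw
      t_new <- drop(X %*% w)
      cvec <- drop(crossprod(Y, t_new)) / sum(t_new^2)
      if (q == 1) {
        u <- Y[, 1]
      } else {
        cn <- sum(cvec^2)
        u <- if (cn > 0) drop(Y %*% cvec) / cn else Y[, 1]
      }
      if (sqrt(sum((t_new - t_old)^2)) < tol * max(1, sqrt(sum(t_new^2)))) {
        converged <- TRUE; t_old <- t_new; break
      }
      t_old <- t_new
    }
    if (!converged && q > 1) {
      abort(sprintf("NIPALS did not converge for component %d within %d iterations",
                    a, max_iter))
    }
    t_a <- t_old
    tt <- sum(t_a^2)
    if (tt == 0) break
    p_a <- drop(crossprod(X, t_a)) / tt
    c_a <- drop(crossprod(Y, t_a)) / tt
    X <- X - tcrossprod(t_a, p_a)
    Y <- Y - tcrossprod(t_a, c_a)
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; U[, a] <- u
    Q[, a] <- c_a; b_inner[a] <- sum(u * t_a) / tt
    x_res[a] <- fnorm(X); y_res[a] <- fnorm(Y)
    achieved <- a
  }
  if (achieved == 0L) abort("no PLS component could be extracted (X has no variance)")

  keep <- seq_len(achieved)
  W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
  Tm <- Tm[, keep, drop = FALSE]; U <- U[, keep, drop = FALSE]
  Q <- Q[, keep, drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  B <- R %*% t(Q)
  structure(list(
    scores = Tm, x_loadings = P, y_scores = U, y_loadings = Q,
    weights = W, projection = R, coefficients = B,
    ncomp = achieved, ncomp_requested = ncomp,
    x_residual_norm = x_res[keep], y_residual_norm = y_res[keep],
    inner_coef = b_inner[keep],
    x_params = xp, y_params = yp, press = NULL,
    feature_names = colnames(x)
  ), class = "pls_model")
}

#' Project new samples onto the latent components of a PLS model
#'
#' Returns the n_new x l score matrix computed with the stored weights and
#' loadings via the deflation-consistent projection T = X R,
#' R = W (P' W)^-1. Transforming the training data reproduces the stored
#' scores exactly.
#'
#' @param model a `pls_model`.
#' @param newdata matrix or data frame with the training feature columns.
#' @param ncomp number of leading components to return (default: all fitted).
#' @return A tibble of scores with columns `comp1..compl`.
#' @export
pls_scores <- function(model, newdata, ncomp = model$ncomp) {
  stopifnot(inherits(model, "pls_model"))
  ncomp <- min(ncomp, model$ncomp)
  X <- as.matrix(standardize_apply(newdata, model$x_params))
  sc <- X %*% model$projection[, seq_len(ncomp), drop = FALSE]
  colnames(sc) <- paste0("comp", seq_len(ncomp))
  tibble::as_tibble(sc)
}

#' Predict responses from a PLS model
#'
#' Computes Yhat = X B on the standardized scale and de-standardizes the
#' result to the original Y units.
#'
#' @param object a `pls_model`.
#' @param newdata matrix or data frame of features.
#' @param ncomp number of leading components to use (default: all fitted).
#' @param ... unused.
#' @return A tibble of predicted responses, one column per Y variable.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  ncomp <- min(ncomp, object$ncomp)
  keep <- seq_len(ncomp)
  X <- as.matrix(standardize_apply(newdata, object$x_params))
  B <- object$projection[, keep, drop = FALSE] %*%
    t(object$y_loadings[, keep, drop = FALSE])
  destandardize(X %*% B, object$y_params)
}

#' Choose the number of PLS components by cross-validated PRESS
#'
#' For each candidate component count l, the prediction residual sum of
#' squares PRESS(l) = sum over folds of the squared error of predictions for
#' held-out samples is computed by K-fold cross-validation, and the count
#' minimizing PRESS is returned (ties broken to the smallest l). Folds are
#' contiguous blocks by default — deterministic, and appropriate for
#' chronologically ordered records; set `shuffle = TRUE` (with a seed) for
#' randomized folds.
#'
#' @param x,y as in [pls_fit()].
#' @param k_folds number of folds (>= 2, each with >= 2 samples).
#' @param max_ncomp largest candidate count; defaults to the maximum
#'   extractable.
#' @param shuffle randomize fold membership.
#' @param seed RNG seed used when `shuffle = TRUE`.
#' @param rule `"min"` (global PRESS minimum, default) or
#'   `"first_local_min"` (smallest l whose PRESS is below both neighbours).
#' @return A list with `ncomp` (the selected count) and `press`, a tibble of
#'   candidate counts and their PRESS values.
#' @export
pls_select_ncomp <- function(x, y, k_folds = 10, max_ncomp = NULL,
                             shuffle = FALSE, seed = NULL,
                             rule = c("min", "first_local_min")) {
  rule <- match.arg(rule)
  x <- as_feature_matrix(x, "x")
  ym <- if (is.matrix(y)) y else matrix(as.double(y), ncol = 1)
  n <- nrow(x)
  if (k_folds < 2) abort("k_folds must be at least 2")
  if (n < k_folds) abort("more folds than samples")
  k_folds <- as.integer(k_folds)

  fold <- as.integer(cut(seq_len(n), breaks = k_folds, labels = FALSE))
  if (shuffle) {
    if (!is.null(seed)) set.seed(seed)
    fold <- sample(fold)
  }
  if (min(table(fold)) < 2) abort("each fold must contain at least 2 samples")

  min_train <- n - max(table(fold))
  max_allowed <- min(min_train - 1L, ncol(x))
  max_ncomp <- as.integer(min(max_ncomp %||% max_allowed, max_allowed))
  if (max_ncomp < 1) abort("no candidate component count is feasible")

  press <- numeric(max_ncomp)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    fit <- pls_fit(x[tr, , drop = FALSE], ym[tr, , drop = FALSE],
                   ncomp = max_ncomp)
    for (l in seq_len(max_ncomp)) {
      # counts beyond the achieved rank reuse the full achieved model,
      # leaving PRESS flat there (ties resolve to the smallest l)
      pr <- as.matrix(predict(fit, x[!tr, , drop = FALSE],
                              ncomp = min(l, fit$ncomp)))
      press[l] <- press[l] + sum((ym[!tr, , drop = FALSE] - pr)^2)
    }
  }
  ncomp <- if (rule == "min") {
    which.min(press)  # first index at the minimum = smallest l
  } else {
    first_local_min(press)
  }
  list(ncomp = as.integer(ncomp),
       press = tibble::tibble(ncomp = seq_len(max_ncomp), press = press))
}

first_local_min <- function(v) {
  if (length(v) == 1) return(1L)
  for (i in seq_along(v)) {
    left_ok <- i == 1 || v[i] < v[i - 1]
    right_ok <- i == length(v) || v[i] <= v[i + 1]
    if (left_ok && right_ok) return(as.integer(i))
  }
  as.integer(which.min(v))
}

#' Principal component baseline with an explained-variance threshold
#'
#' Fits PCA on standardized features and retains the smallest number of
#' components whose cumulative explained-variance ratio reaches `threshold`
#' (the conventional 80% rule by default). Used by the PCA-reduced network
#' baseline.
#'
#' @param x matrix or data frame of features.
#' @param threshold cumulative explained-variance ratio in (0, 1].
#' @return An object of class `pca_model` with the orthonormal `rotation`,
#'   `explained_ratio`, retained count `k`, and standardization parameters.
#' @export
pca_fit <- function(x, threshold = 0.8) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]")
  }
  x <- as_feature_matrix(x, "x")
  xp <- standardize_fit(x)
  Xs <- as.matrix(standardize_apply(x, xp))
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  rank_x <- sum(ev > max(ev) * 1e-12)
  ratio <- ev / sum(ev)
  k <- which(cumsum(ratio) >= threshold - 1e-12)[1]
  k <- min(k, rank_x)
  structure(list(rotation = pc$rotation, explained_ratio = ratio,
                 k = as.integer(k), threshold = threshold, x_params = xp),
            class = "pca_model")
}

#' @rdname pca_fit
#' @param model a `pca_model`.
#' @param newdata matrix or data frame of features.
#' @param k number of leading components to return (default: the retained
#'   count).
#' @export
pca_scores <- function(model, newdata, k = model$k) {
  stopifnot(inherits(model, "pca_model"))
  Xs <- as.matrix(standardize_apply(newdata, model$x_params))
  sc <- Xs %*% model$rotation[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("comp", seq_len(k))
  tibble::as_tibble(sc)
}
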