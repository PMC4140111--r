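#' Sample covariance matrix (pooled over all rows)
#'
#' The covariance with the usual n - 1 denominator, used to define the
#' Mahalanobis metric for clustering and routing.
#'
#' @param x matrix or data frame of numeric features, n >= 2 rows.
#' @return A symmetric p x p matrix.
#' @export
pooled_cov <- function(x) {
  x <- as_feature_matrix(x, "x")
  if (nrow(x) < 2) abort("need at least 2 samples for a covariance matrix")
  stats::cov(x)
}

#' Mahalanobis distance between two vectors
#'
#' d(x, y) = sqrt((x - y)' V^-1 (x - y)). With the identity for V^-1 this is
#' Euclidean distance; with the data covariance it is invariant under
#' invertible linear maps of the feature space.
#'
#' @param x,y numeric vectors of equal length.
#' @param v_inv the inverse (or pseudo-inverse) covariance matrix.
#' @return A nonnegative number.
#' @examples
#' mahalanobis_pair(c(0, 0), c(3, 4), diag(2))  # 5
#' @export
mahalanobis_pair <- function(x, y, v_inv) {
  x <- as.double(x); y <- as.double(y)
  if (length(x) != length(y) || length(x) != ncol(v_inv)) {
    abort("dimension mismatch in mahalanobis_pair")
  }
  d <- x - y
  sqrt(max(0, drop(t(d) %*% v_inv %*% d)))
}

#' Pairwise Mahalanobis distance matrix
#'
#' Factorizes V^-1 = M'M through its eigendecomposition (nonnegative
#' eigenvalues only, so a pseudo-inverse is handled), maps the data to
#' Z = X M', and returns Euclidean distances of the mapped rows.
#'
#' @param x matrix or data frame (n x p).
#' @param v_inv inverse (or pseudo-inverse) covariance; defaults to the
#'   pseudo-inverse of the covariance of `x`.
#' @return A symmetric n x n matrix of distances with zero diagonal.
#' @export
mahalanobis_matrix <- function(x, v_inv = NULL) {
  x <- as_feature_matrix(x, "x")
  v_inv <- v_inv %||% safe_inverse(pooled_cov(x))
  if (ncol(v_inv) != ncol(x)) abort("dimension mismatch in mahalanobis_matrix")
  e <- eigen((v_inv + t(v_inv)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- x %*% e$vectors %*% diag(sqrt(lam), length(lam))
  as.matrix(dist(z))
}

#' UPGMA agglomerative clustering
#'
#' Unweighted pair-group clustering with arithmetic averaging: starting from
#' singletons, the two clusters at smallest distance are merged repeatedly
#' until one class remains. The between-cluster measure is the square root of
#' the arithmetic mean of all squared cross-pair distances,
#' D_pq^2 = (1 / (n_p n_q)) * sum over i in G_p, j in G_q of d_ij^2,
#' maintained by the size-weighted Lance-Williams update
#' D_kr^2 = (n_p / n_r) D_kp^2 + (n_q / n_r) D_kq^2 after merging G_p and
#' G_q into G_r. Ties are broken deterministically to the smallest
#' (row, column) index pair in cluster-creation order.
#'
#' @param d a symmetric nonnegative distance matrix (or `dist`) with zero
#'   diagonal, e.g. from [mahalanobis_matrix()].
#' @return An object of class `upgma_tree`: a list with `merges` (a tibble
#'   with one row per merge: `step`, `a`, `b` in hclust encoding — negative
#'   numbers are leaves, positive numbers earlier merge steps — `height`,
#'   `size`), `n`, and `labels`. Convert with [as.hclust.upgma_tree()] for
#'   plotting or comparison with other linkage software.
#' @seealso [cut_upgma()], [partition_summarize()]
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("d must be a square matrix")
  if (max(abs(d - t(d))) > 1e-8) abort("distance matrix must be symmetric")
  if (any(d < 0)) abort("distances must be nonnegative")
  n <- nrow(d)
  if (n < 2) abort("need at least 2 samples to cluster")
  labels <- rownames(d) %||% as.character(seq_len(n))

  # active-cluster bookkeeping: clusters are indexed by creation order
  # (leaves 1..n, merged clusters n+1..2n-1); `code` holds hclust encoding
  D2 <- d^2
  diag(D2) <- Inf
  size <- rep(1L, n)
  code <- -seq_len(n)
  merge_a <- integer(n - 1); merge_b <- integer(n - 1)
  height <- numeric(n - 1); msize <- integer(n - 1)

  for (s in seq_len(n - 1)) {
    m <- min(D2)
    idx <- which(D2 == m, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]

    ni <- size[i]; nj <- size[j]; nr <- ni + nj
    merge_a[s] <- code[i]; merge_b[s] <- code[j]
    height[s] <- sqrt(max(0, m)); msize[s] <- nr

    new_row <- (ni * D2[i, ] + nj * D2[j, ]) / nr
    D2[i, ] <- new_row; D2[, i] <- new_row
    D2[i, i] <- Inf
    keep <- setdiff(seq_along(size), j)
    D2 <- D2[keep, keep, drop = FALSE]
    size[i] <- nr; size <- size[keep]
    code[i] <- s; code <- code[keep]
  }
  structure(list(
    merges = tibble::tibble(step = seq_len(n - 1), a = merge_a, b = merge_b,
                            height = height, size = msize),
    n = n, labels = labels), class = "upgma_tree")
}

#' Convert a UPGMA tree to an hclust object
#'
#' @param x an `upgma_tree`.
#' @param ... unused.
#' @return A `stats::hclust` object (plottable with `plot()`).
#' @export
as.hclust.upgma_tree <- function(x, ...) {
  merge <- cbind(x$merges$a, x$merges$b)
  structure(list(merge = merge, height = x$merges$height,
                 order = tree_leaf_order(merge, x$n), labels = x$labels,
                 method = "upgma", call = match.call(),
                 dist.method = "mahalanobis"), class = "hclust")
}

tree_leaf_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  expand(nrow(merge))
}

#' Cut a UPGMA tree into subclasses
#'
#' Either keep exactly `k` clusters (undo the last k - 1 merges) or undo all
#' merges above the dendrogram height `lambda` (the cutoff-value rule).
#' Subclass ids are 1..K in order of first member appearance.
#'
#' @param tree an `upgma_tree`.
#' @param k desired number of subclasses (1..n).
#' @param lambda height threshold (>= 0); merges at height <= lambda are
#'   applied. Exactly one of `k`, `lambda` must be given.
#' @return An integer vector of subclass ids, one per sample.
#' @export
cut_upgma <- function(tree, k = NULL, lambda = NULL) {
  stopifnot(inherits(tree, "upgma_tree"))
  if (is.null(k) == is.null(lambda)) {
    abort("give exactly one of k or lambda")
  }
  n <- tree$n
  if (!is.null(k)) {
    if (k < 1 || k > n) abort(sprintf("k must be in 1..%d", n))
    n_apply <- n - as.integer(k)
  } else {
    if (lambda < 0) abort("lambda must be nonnegative")
    n_apply <- sum(tree$merges$height <= lambda)
  }
  assign <- seq_len(n)
  if (n_apply > 0) {
    members <- c(as.list(seq_len(n)), vector("list", n - 1))
    for (s in seq_len(n_apply)) {
      a <- tree$merges$a[s]; b <- tree$merges$b[s]
      ma <- if (a < 0) -a else members[[n + a]]
      mb <- if (b < 0) -b else members[[n + b]]
      members[[n + s]] <- c(ma, mb)
      assign[c(ma, mb)] <- n + s
    }
  }
  relabel_first_appearance(assign)
}

relabel_first_appearance <- function(assign) {
  as.integer(factor(assign, levels = unique(assign)))
}

#' Summarize a subclass partition
#'
#' Computes the per-subclass mean centres and the pooled inverse covariance
#' of the full training matrix (pseudo-inverse when singular), the two
#' quantities needed to route new samples by nearest-centre Mahalanobis
#' distance.
#'
#' @param x training matrix or data frame (the working feature space — e.g.
#'   PLS scores).
#' @param assignment integer vector of subclass ids, one per row of `x`;
#'   every subclass must be nonempty (ids are relabelled 1..K by first
#'   appearance).
#' @param inverse method for inverting the pooled covariance; see
#'   `safe_inverse` methods `"pseudo"` (default), `"solve"`, `"ridge"`.
#' @param ridge_eps relative ridge magnitude for `inverse = "ridge"`.
#' @return An object of class `subclass_partition`: list with `assignment`,
#'   `centers` (K x p), `v_inv`, `sizes`, `k`.
#' @export
partition_summarize <- function(x, assignment,
                                inverse = c("pseudo", "solve", "ridge"),
                                ridge_eps = 1e-8) {
  inverse <- match.arg(inverse)
  x <- as_feature_matrix(x, "x")
  if (length(assignment) != nrow(x)) abort("assignment length must match rows of x")
  if (anyNA(assignment)) abort("assignment must not contain NA")
  assignment <- relabel_first_appearance(assignment)
  k <- max(assignment)
  sizes <- tabulate(assignment, k)
  if (any(sizes == 0)) abort("every subclass must be nonempty")
  centers <- rowsum(x, assignment) / sizes
  v <- pooled_cov(x)
  v_inv <- safe_inverse(v, method = inverse, ridge_eps = ridge_eps)
  structure(list(assignment = assignment, centers = centers, v_inv = v_inv,
                 sizes = sizes, k = as.integer(k)),
            class = "subclass_partition")
}
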