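test_that("covariance uses the n-1 denominator", {
  v <- pooled_cov(rbind(c(0, 0), c(2, 2)))
  expect_equal(unname(v), matrix(2, 2, 2))
  expect_error(pooled_cov(matrix(1, 1, 2)), "at least 2")
})

test_that("covariance of standardized uncorrelated data approaches identity", {
  set.seed(14)
  x <- scale(matrix(rnorm(5000 * 3), 5000, 3))
  expect_lt(max(abs(pooled_cov(x) - diag(3))), 0.1)
})

test_that("rank deficiency from repeated rows is detected and handled", {
  x <- rbind(c(1, 2), c(1, 2), c(3, 5))
  v <- pooled_cov(x)
  expect_lt(abs(det(v)) / max(abs(v))^2, 1e-10)  # singular
  vi <- elmanet:::safe_inverse(v)                # pseudo-inverse path
  expect_true(all(is.finite(vi)))
  expect_true(all(is.finite(mahalanobis_matrix(x, vi))))
})

test_that("Mahalanobis distance reduces to Euclidean under identity metric", {
  expect_equal(mahalanobis_pair(c(0, 0), c(3, 4), diag(2)), 5)
  expect_equal(mahalanobis_pair(c(1, 7), c(1, 7), diag(2)), 0)
  expect_error(mahalanobis_pair(c(1, 2, 3), c(1, 2), diag(2)), "mismatch")
})

test_that("Mahalanobis distances are invariant under invertible linear maps", {
  set.seed(20)
  x <- matrix(rnorm(80), 20, 4)
  d0 <- mahalanobis_matrix(x, solve(pooled_cov(x)))
  for (i in 1:5) {
    a <- matrix(rnorm(16), 4, 4) + diag(4)
    xt <- x %*% a
    dt <- mahalanobis_matrix(xt, solve(pooled_cov(xt)))
    expect_lt(max(abs(dt - d0)), 1e-8)
  }
})

test_that("UPGMA merges the closest pair and averages squared cross distances", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1
  d[1, 3] <- d[3, 1] <- 4
  d[2, 3] <- d[3, 2] <- 5
  tree <- upgma(d)
  expect_equal(tree$merges$height[1], 1)
  expect_equal(tree$merges$height[2], sqrt((16 + 25) / 2))  # 4.5277
  expect_equal(tree$merges$a[1], -1)
  expect_equal(tree$merges$b[1], -2)
})

test_that("equal distances give equal merge heights in any order", {
  d <- matrix(2, 5, 5)
  diag(d) <- 0
  tree <- upgma(d)
  expect_equal(tree$merges$height, rep(2, 4))
})

test_that("UPGMA agrees with the naive recompute-from-scratch oracle", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    z <- matrix(rnorm(n * 3), n, 3)
    d <- as.matrix(dist(z))
    tree <- upgma(d)
    oracle <- upgma_oracle(d)
    expect_lt(max(abs(tree$merges$height - oracle$heights)), 1e-10)
    for (k in 2:(n - 1)) {
      expect_equal(rand_index(cut_upgma(tree, k = k),
                              oracle$assignments[[k]]), 1)
    }
  }
})

test_that("merge heights are monotone non-decreasing", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 4), n, 4)))
    tree <- upgma(d)
    expect_true(all(diff(tree$merges$height) >= -1e-12))
  }
})

test_that("input validation rejects malformed distance matrices", {
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(upgma(matrix(c(0, -1, -1, 0), 2, 2)), "nonnegative")
  expect_error(upgma(matrix(0, 1, 1)), "at least 2")
})

test_that("tree cuts produce the requested number of subclasses", {
  set.seed(30)
  d <- as.matrix(dist(matrix(rnorm(8 * 2), 8, 2)))
  tree <- upgma(d)
  expect_equal(cut_upgma(tree, k = 8), 1:8)      # all singletons
  expect_equal(cut_upgma(tree, k = 1), rep(1L, 8))
  for (k in 2:7) {
    a <- cut_upgma(tree, k = k)
    expect_equal(length(unique(a)), k)
    expect_equal(sort(unique(a)), seq_len(k))    # first-appearance labels
  }
  expect_error(cut_upgma(tree, k = 9), "k must be")
  expect_error(cut_upgma(tree), "exactly one")
  expect_error(cut_upgma(tree, k = 2, lambda = 1), "exactly one")
})

test_that("lambda and k cuts agree when lambda separates the merge heights", {
  set.seed(31)
  d <- as.matrix(dist(matrix(rnorm(10 * 3), 10, 3)))
  tree <- upgma(d)
  h <- tree$merges$height
  for (k in c(2, 4, 6)) {
    lam <- mean(c(h[10 - k], h[10 - k + 1]))  # strictly between merges
    expect_equal(cut_upgma(tree, lambda = lam), cut_upgma(tree, k = k))
  }
})

test_that("well-separated blobs are recovered at k = 3", {
  blobs <- make_blobs(45, sep = 10, seed = 6)
  tree <- upgma(mahalanobis_matrix(blobs$x))
  a <- cut_upgma(tree, k = 3)
  expect_equal(rand_index(a, blobs$cluster), 1)
})

test_that("partition summaries hold member means and a usable metric", {
  x <- rbind(c(0, 0), c(2, 2), c(10, 10))
  part <- partition_summarize(x, c(1, 1, 2))
  expect_equal(unname(part$centers[1, ]), c(1, 1))
  expect_equal(unname(part$centers[2, ]), c(10, 10))  # singleton = itself
  expect_equal(part$sizes, c(2L, 1L))
  expect_error(partition_summarize(x, c(1, 1)), "length")

  # rank-deficient working space: pseudo-inverse distances stay finite and
  # close to a ridge-regularized oracle
  set.seed(40)
  z <- matrix(rnorm(30), 10, 3)
  xr <- cbind(z, z[, 1])  # exactly collinear extra column
  pr <- partition_summarize(xr, rep(1:2, 5))
  expect_true(all(is.finite(pr$v_inv)))
  d_pseudo <- assign_subclass(xr, pr)$distance
  v <- pooled_cov(xr)
  ridge <- solve(v + diag(1e-8 * sum(diag(v)) / ncol(v), ncol(v)))
  pr_ridge <- pr
  pr_ridge$v_inv <- ridge
  d_ridge <- assign_subclass(xr, pr_ridge)$distance
  expect_true(all(is.finite(d_pseudo)))
  expect_lt(max(abs(d_pseudo - d_ridge)), 1e-2)
})

test_that("as.hclust conversion round-trips heights and partitions", {
  set.seed(50)
  d <- as.matrix(dist(matrix(rnorm(12 * 2), 12, 2)))
  tree <- upgma(d)
  hc <- as.hclust(tree)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, tree$merges$height)
  for (k in c(2, 3, 5)) {
    expect_equal(rand_index(stats::cutree(hc, k = k),
                            cut_upgma(tree, k = k)), 1)
  }
})
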