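test_that("rank-1 system is recovered exactly with one component", {
  set.seed(1)
  t_true <- rnorm(20)
  x <- outer(t_true, c(1, -2, 0.5))
  y <- 3 * t_true + 1
  fit <- pls_fit(x, y)
  expect_equal(fit$ncomp, 1L)
  expect_lt(fit$x_residual_norm[1], 1e-8)
  expect_lt(max(abs(as.matrix(predict(fit, x)) - y)), 1e-8)
})

test_that("full-component PLS equals the least-squares fit", {
  for (s in 1:5) {
    set.seed(s)
    x <- matrix(rnorm(150), 30, 5)
    y <- x %*% rnorm(5) + rnorm(30)
    fit <- pls_fit(x, y, ncomp = 5)
    expect_lt(max(abs(as.matrix(predict(fit, x)) - ols_predict(x, y))), 1e-6)
  }
})

test_that("response orthogonal to the feature space gives ~zero coefficients", {
  set.seed(9)
  x <- matrix(rnorm(40), 20, 2)
  # project random y off the column space of centred x
  xc <- scale(x, scale = FALSE)
  y0 <- rnorm(20)
  y <- y0 - xc %*% solve(crossprod(xc), crossprod(xc, y0))
  fit <- pls_fit(x, y)
  expect_lt(max(abs(fit$coefficients)), 1e-6)
  expect_lt(max(abs(as.matrix(predict(fit, x)) - mean(y))), 1e-6)
})

test_that("scores are orthogonal and residual norms decrease to zero", {
  set.seed(21)
  x <- matrix(rnorm(240), 30, 8)
  y <- x %*% rnorm(8) + rnorm(30, sd = 0.3)
  fit <- pls_fit(x, y, ncomp = 8)
  g <- crossprod(fit$scores)
  nrm <- sqrt(diag(g))
  off <- abs(g - diag(diag(g))) / outer(nrm, nrm)
  expect_lt(max(off), 1e-8)
  expect_true(all(diff(fit$x_residual_norm) <= 1e-10))
  expect_true(all(diff(fit$y_residual_norm) <= 1e-10))
  expect_lt(fit$x_residual_norm[8], 1e-8)  # full rank exhausts X
})

test_that("NIPALS handles n < p where the covariance is singular", {
  set.seed(5)
  x <- matrix(rnorm(300), 10, 30)
  y <- x[, 1] - x[, 2] + rnorm(10, sd = 0.1)
  fit <- pls_fit(x, y)
  expect_lte(fit$ncomp, 9)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(is.finite(as.matrix(predict(fit, x)))))
})

test_that("score projection reproduces training scores and ignores orthogonal directions", {
  set.seed(33)
  x <- matrix(rnorm(200), 40, 5)
  y <- x %*% rnorm(5) + rnorm(40, sd = 0.2)
  fit <- pls_fit(x, y, ncomp = 3)
  sc <- as.matrix(pls_scores(fit, x))
  expect_lt(max(abs(sc - fit$scores)), 1e-8)

  # the training-mean row maps to the zero score
  z0 <- as.matrix(pls_scores(fit, matrix(colMeans(x), 1)))
  expect_lt(max(abs(z0)), 1e-10)

  # moving along a direction orthogonal to all weight vectors leaves the
  # scores unchanged (the projection is a combination of the weights)
  null_dir <- MASS::Null(fit$weights)[, 1]
  a <- matrix(rnorm(5), 1)
  b <- a + 2 * null_dir * fit$x_params$scale  # undo per-feature scaling
  expect_lt(max(abs(as.matrix(pls_scores(fit, a)) -
                    as.matrix(pls_scores(fit, b)))), 1e-8)
})

test_that("PRESS selection finds the generating dimension on rank-3 data", {
  d <- simulate_dataset(n_samples = 100, n_features = 14, n_latent = 3,
                        n_clusters = 1, separation = 0, redundancy = 0,
                        class_rule = "regression", seed = 4)
  sel <- pls_select_ncomp(features_of(d$data), d$data$class, k_folds = 10)
  expect_equal(sel$ncomp, 3L)
  # PRESS at the selected count is the global minimum of the sweep
  expect_equal(which.min(sel$press$press), 3L)
})

test_that("pure-noise responses select one component most of the time", {
  picks <- vapply(1:20, function(s) {
    set.seed(s)
    x <- matrix(rnorm(40 * 6), 40, 6)
    y <- rnorm(40)
    pls_select_ncomp(x, y, k_folds = 5)$ncomp
  }, integer(1))
  expect_gte(mean(picks == 1), 0.5)  # smallest-l tie-break dominates
})

test_that("PRESS selection is deterministic and respects max_ncomp", {
  set.seed(12)
  x <- matrix(rnorm(200), 40, 5)
  y <- x %*% rnorm(5) + rnorm(40)
  s1 <- pls_select_ncomp(x, y, k_folds = 4)
  s2 <- pls_select_ncomp(x, y, k_folds = 4)
  expect_identical(s1, s2)
  expect_equal(pls_select_ncomp(x, y, k_folds = 4, max_ncomp = 1)$ncomp, 1L)
  expect_error(pls_select_ncomp(x, y, k_folds = 1), "at least 2")
})

test_that("PCA retains the smallest count reaching the variance threshold", {
  # one dominant direction: all columns are noisy copies of one factor, so
  # it carries > 80% of the (standardized) variance
  set.seed(2)
  t1 <- rnorm(300)
  x <- sapply(1:4, function(i) t1 + rnorm(300, sd = 0.1))
  fit <- pca_fit(x, threshold = 0.8)
  expect_equal(fit$k, 1L)
  expect_gt(fit$explained_ratio[1], 0.8)

  # isotropic data needs all p components to reach 80%
  set.seed(3)
  iso <- matrix(rnorm(5000 * 4), 5000, 4)
  expect_equal(pca_fit(iso, threshold = 0.8)$k, 4L)

  # threshold 1 returns the rank
  expect_equal(pca_fit(iso, threshold = 1)$k, 4L)
  expect_error(pca_fit(iso, threshold = 0), "threshold")
  expect_error(pca_fit(iso, threshold = 1.2), "threshold")
})

test_that("tidy/glance expose the component diagnostics", {
  set.seed(8)
  x <- matrix(rnorm(120), 30, 4)
  y <- x %*% rnorm(4) + rnorm(30)
  sel <- pls_select_ncomp(x, y, k_folds = 5)
  fit <- pls_fit(x, y, ncomp = sel$ncomp)
  fit$press <- sel$press
  td <- tidy(fit)
  expect_equal(nrow(td), fit$ncomp)
  expect_true(all(c("x_residual_norm", "press") %in% names(td)))
  expect_equal(glance(fit)$ncomp, fit$ncomp)
})
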