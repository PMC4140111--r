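test_that("generation is bit-identical under a fixed seed", {
  a <- simulate_dataset(n_samples = 30, n_features = 6, n_latent = 2,
                        n_clusters = 2, separation = 5, seed = 9)
  b <- simulate_dataset(n_samples = 30, n_features = 6, n_latent = 2,
                        n_clusters = 2, separation = 5, seed = 9)
  expect_identical(a, b)
  c <- simulate_dataset(n_samples = 30, n_features = 6, n_latent = 2,
                        n_clusters = 2, separation = 5, seed = 10)
  expect_false(identical(a$data, c$data))
})

test_that("presets reproduce the reference dataset shapes", {
  m <- simulate_preset("midge_like")
  expect_equal(dim(features_of(m$data)), c(60, 14))
  expect_equal(sort(unique(m$data$class)), c(1, 2, 3))

  i <- simulate_preset("ionosphere_like")
  expect_equal(dim(features_of(i$data)), c(351, 34))
  expect_equal(sort(unique(i$data$class)), c(1, 2))

  expect_error(simulate_preset("nope"), "available: midge_like")
})

test_that("redundant columns are highly correlated noisy copies", {
  d <- simulate_dataset(n_samples = 80, n_features = 10, n_latent = 3,
                        n_clusters = 1, separation = 0, noise_sd = 0.1,
                        redundancy = 3, seed = 5)
  x <- as.matrix(features_of(d$data))
  cors <- vapply(8:10, function(j) max(abs(cor(x[, j], x[, 1:7]))), numeric(1))
  expect_true(all(cors > 0.9))
})

test_that("degenerate settings behave as documented", {
  # single cluster at separation 0: one blob, trivial k = 1 cut
  d <- simulate_dataset(n_samples = 20, n_features = 4, n_latent = 2,
                        n_clusters = 1, separation = 0, seed = 2)
  expect_true(all(d$truth$cluster == 1))
  a <- cut_upgma(upgma(mahalanobis_matrix(features_of(d$data))), k = 1)
  expect_true(all(a == 1))

  # infeasible specs are rejected
  expect_error(simulate_dataset(n_features = 4, redundancy = 4), "redundancy")
  expect_error(simulate_dataset(n_features = 4, n_latent = 4, redundancy = 1),
               "n_latent")
})

test_that("cluster centres respect the requested separation", {
  for (s in 1:5) {
    d <- simulate_dataset(n_samples = 30, n_features = 6, n_latent = 3,
                          n_clusters = 3, separation = 8, seed = s)
    z <- as.matrix(d$truth[paste0("z", 1:3)])
    centers <- rowsum(z, d$truth$cluster) /
      as.vector(table(d$truth$cluster))
    expect_gte(min(dist(centers)), 8 - 1.5)  # sample centres near spec
  }
})

test_that("binary rule maps clusters onto two classes", {
  d <- simulate_dataset(n_samples = 40, n_features = 6, n_latent = 3,
                        n_clusters = 3, separation = 6,
                        class_rule = "binary", seed = 4)
  expect_equal(sort(unique(d$data$class)), c(1, 2))
  tab <- table(d$truth$cluster, d$data$class)
  expect_true(all(rowSums(tab > 0) == 1))  # each cluster one label
})

test_that("end-to-end recovery holds at high separation, chance at zero", {
  # ceiling: separated data classify near-perfectly
  sim <- simulate_preset("separable_benchmark")
  sets <- split_leading(sim$data, 90)
  m <- plsca_fit(sets$train, seed = 1,
                 control = elman_control(max_epochs = 300))
  acc_hi <- plsca_evaluate(m, sets$sim)$accuracy
  expect_gte(acc_hi, 95)

  # floor: labels from unseparated clusters are unlearnable
  d0 <- simulate_dataset(n_samples = 120, n_features = 14, n_latent = 3,
                         n_clusters = 3, separation = 0, redundancy = 4,
                         seed = 31)
  sets0 <- split_leading(d0$data, 90)
  m0 <- plsca_fit(sets0$train, seed = 1,
                  control = elman_control(max_epochs = 100))
  acc_lo <- plsca_evaluate(m0, sets0$sim)$accuracy
  expect_lt(acc_lo, 75)  # near the majority-class rate, far from ceiling
})
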