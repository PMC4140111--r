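# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the UPGMA oracle recomputes every cross-pair
# average from scratch each merge step, the regression oracle uses the
# normal equations.

# O(n^3) naive UPGMA: between-cluster squared distance recomputed from the
# original matrix at every step.
upgma_oracle <- function(d) {
  d2 <- d^2
  n <- nrow(d2)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  assignments <- list()  # per remaining cluster count: membership vector
  for (s in seq_len(n - 1)) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        avg <- mean(d2[clusters[[i]], clusters[[j]]])
        if (avg < best[1]) best <- c(avg, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights[s] <- sqrt(best[1])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    assign <- integer(n)
    for (ci in seq_along(clusters)) assign[clusters[[ci]]] <- ci
    assignments[[length(clusters)]] <- assign
  }
  list(heights = heights, assignments = assignments)
}

# least-squares predictions via the normal equations (with intercept)
ols_predict <- function(x, y, newx = x) {
  xd <- cbind(1, x)
  beta <- solve(crossprod(xd), crossprod(xd, y))
  cbind(1, newx) %*% beta
}

# isotropic Gaussian blobs around an equilateral-triangle centre layout in
# 2-D (centres pairwise `sep` apart, unit within-cluster sd)
make_blobs <- function(n, sep, seed, k = 3) {
  set.seed(seed)
  ang <- 2 * pi * (0:(k - 1)) / k
  centers <- sep / sqrt(3) * cbind(cos(ang), sin(ang)) * sqrt(3) / sqrt(3)
  centers <- centers * sep / min(dist(centers))
  cl <- sample(rep(seq_len(k), length.out = n))
  x <- centers[cl, , drop = FALSE] + matrix(rnorm(n * 2), n)
  list(x = x, cluster = cl, centers = centers)
}

features_of <- function(df) df[grep("^x", names(df), value = TRUE)]
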