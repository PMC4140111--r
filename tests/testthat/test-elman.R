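test_that("hidden-size formula matches hand evaluation", {
  expect_equal(hidden_size(14, 1), 7L)
  expect_equal(hidden_size(6, 1), 5L)
  expect_equal(hidden_size(1, 1), 3L)
  expect_error(hidden_size(0, 1), "positive")
  expect_error(hidden_size(3, -1), "positive")
})

test_that("forward pass follows the recurrence equations", {
  # zero weights: hidden = f(0) = 0.5 everywhere, output = w3 * 0.5
  net <- elman_net(2, 3, 1, seed = 1)
  net$w1[] <- 0; net$w2[] <- 0; net$b1[] <- 0; net$b2[] <- 0
  net$w3[] <- 0; net$w3[1, 1] <- 1
  st <- elman_forward(net, c(9, -4))
  expect_equal(st$hidden, rep(0.5, 3))
  expect_equal(st$y, 0.5)

  # unit context through identity recurrent weights: f(1) per unit
  net2 <- elman_net(2, 3, 1, seed = 2)
  net2$w1[] <- 0; net2$b1[] <- 0
  net2$w2 <- diag(3)
  net2$context <- rep(1, 3)
  st2 <- elman_forward(net2, c(0, 0))
  expect_equal(st2$hidden, rep(1 / (1 + exp(-1)), 3), tolerance = 1e-12)

  # context contract: stored context equals the just-computed hidden vector
  expect_identical(st2$net$context, st2$hidden)
})

test_that("disabling the recurrence reproduces a plain feedforward net", {
  net <- elman_net(3, 4, 1, seed = 7)
  bp <- elman_net(3, 4, 1, seed = 7, recurrent = FALSE)
  # identical draws for w1/w3/biases under the same seed
  expect_identical(net$w1, bp$w1)
  expect_identical(net$w3, bp$w3)
  expect_identical(net$b1, bp$b1)
  expect_true(all(bp$w2 == 0))

  set.seed(99)
  x <- matrix(rnorm(15), 5, 3)
  net0 <- net
  net0$w2[] <- 0
  expect_equal(elman_predict(net0, x), elman_predict(bp, x))
  # and the manual single-pass MLP formula
  h <- 1 / (1 + exp(-(x %*% t(bp$w1) + matrix(bp$b1, 5, 4, byrow = TRUE))))
  expect_equal(elman_predict(bp, x),
               h %*% t(bp$w3) + matrix(bp$b2, 5, 1, byrow = TRUE))
})

test_that("sum of squared errors matches its definition", {
  expect_equal(elman_sse(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_equal(elman_sse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(elman_sse(2, -1), 9)
  expect_error(elman_sse(c(1, 2), c(1, 2, 3)), "equal shape")
})

test_that("analytic Jacobian matches central finite differences", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(2:4, 1); r <- sample(2:4, 1); m <- sample(1:2, 1)
    net <- elman_net(n, r, m, seed = s)
    x <- matrix(rnorm(5 * n), 5, n)
    hb <- elmanet:::elman_hidden_batch(net, x, 2L)
    J <- elmanet:::elman_jacobian(net, x, hb$h, hb$ctx)
    theta <- elmanet:::elman_pack(net)
    fwd <- function(th) {  # fixed-context map the Jacobian differentiates
      nt <- elmanet:::elman_unpack(net, th)
      z <- x %*% t(nt$w1) + hb$ctx %*% t(nt$w2) +
        matrix(nt$b1, 5, r, byrow = TRUE)
      h <- 1 / (1 + exp(-z))
      as.vector(h %*% t(nt$w3) + matrix(nt$b2, 5, m, byrow = TRUE))
    }
    jfd <- vapply(seq_along(theta), function(i) {
      up <- theta; up[i] <- up[i] + 1e-6
      dn <- theta; dn[i] <- dn[i] - 1e-6
      (fwd(up) - fwd(dn)) / 2e-6
    }, numeric(5 * m))
    expect_lt(max(abs(J - jfd)) / max(abs(jfd)), 1e-4)
  }
})

test_that("LM training decreases SSE monotonically and learns XOR", {
  x <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- c(0, 1, 1, 0)
  wins <- 0
  for (s in 1:10) {
    net <- elman_net(2, 4, 1, seed = s)
    fit <- elman_train_lm(net, x, y,
                          elman_control(max_epochs = 200, goal_sse = 1e-3))
    expect_true(all(diff(fit$sse_trace) <= 0))
    if (fit$final_sse < 0.01) wins <- wins + 1
  }
  expect_gte(wins, 8)
})

test_that("LM returns immediately when the goal is already met", {
  set.seed(3)
  net <- elman_net(2, 3, 1, seed = 3)
  x <- matrix(rnorm(10), 5, 2)
  y <- rnorm(5)
  fit <- elman_train_lm(net, x, y, elman_control(goal_sse = 1e12))
  expect_equal(fit$epochs_run, 0L)
  expect_identical(fit$net$w1, net$w1)
})

test_that("LM training is deterministic given seed and data", {
  x <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- c(0, 1, 1, 0)
  f1 <- elman_train_lm(elman_net(2, 3, 1, seed = 11), x, y,
                       elman_control(max_epochs = 50))
  f2 <- elman_train_lm(elman_net(2, 3, 1, seed = 11), x, y,
                       elman_control(max_epochs = 50))
  expect_identical(f1$sse_trace, f2$sse_trace)
  expect_identical(f1$net$w1, f2$net$w1)
})

test_that("gradient descent with momentum follows the analytic gradient", {
  set.seed(17)
  net <- elman_net(1, 1, 1, seed = 17)
  x <- matrix(c(0.3, -1, 2), 3, 1)
  y <- c(1, 0, 0.5)
  lr <- 1e-4
  theta0 <- elmanet:::elman_pack(net)
  hb <- elmanet:::elman_hidden_batch(net, x, 2L)
  yhat <- hb$h %*% t(net$w3) + matrix(net$b2, 3, 1)
  J <- elmanet:::elman_jacobian(net, x, hb$h, hb$ctx)
  grad <- -2 * drop(crossprod(J, as.vector(y - yhat)))
  fit <- elman_train_gdm(net, x, y, lr = lr, momentum = 0, epochs = 1)
  expect_equal(elmanet:::elman_pack(fit$net), theta0 - lr * grad,
               tolerance = 1e-12)

  # lr = 0 leaves weights untouched
  fit0 <- elman_train_gdm(net, x, y, lr = 0, momentum = 0, epochs = 5)
  expect_identical(elmanet:::elman_pack(fit0$net), theta0)

  # small steps descend
  fit2 <- elman_train_gdm(net, x, y, lr = 1e-3, momentum = 0, epochs = 50)
  expect_true(all(diff(fit2$sse_trace) <= 1e-12))
})

test_that("continuous outputs decode to the nearest class, ties to lower", {
  expect_equal(decode_labels(1.4, c(1, 2, 3)), 1)
  expect_equal(decode_labels(1.5, c(1, 2)), 1)
  expect_equal(decode_labels(-7, c(1, 2, 3)), 1)
  expect_equal(decode_labels(c(0.9, 2.6, 9), c(1, 2, 3)), c(1, 3, 3))
  expect_error(decode_labels(1, numeric(0)), "nonempty")
  expect_error(decode_labels(1, c(3, 1)), "sorted")
})

test_that("trained feedforward baseline separates linearly separable classes", {
  set.seed(23)
  x <- rbind(matrix(rnorm(40, mean = -2), 20, 2),
             matrix(rnorm(40, mean = 2), 20, 2))
  y <- rep(c(1, 2), each = 20)
  net <- elman_net(2, 3, 1, seed = 23, recurrent = FALSE)
  fit <- elman_train_lm(net, x, y, elman_control(max_epochs = 300))
  pred <- decode_labels(elman_predict(fit$net, x), c(1, 2))
  expect_equal(mean(pred == y), 1)
})
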