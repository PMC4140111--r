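#' Empirical hidden-layer size
#'
#' The empirical formula for the number of hidden (and context) neurons
#' given `n_in` inputs and `n_out` outputs:
#' s = round(sqrt(0.43 n m + 0.12 m^2 + 2.54 n + 0.77 m + 0.35) + 0.51),
#' floored at 1. The context ("undertake") layer always has the same number
#' of neurons as the hidden layer.
#'
#' @param n_in number of input neurons (>= 1).
#' @param n_out number of output neurons (>= 1).
#' @return An integer hidden-layer size.
#' @examples
#' hidden_size(14, 1)  # 7
#' hidden_size(6, 1)   # 5
#' @export
hidden_size <- function(n_in, n_out = 1) {
  if (!is.numeric(n_in) || !is.numeric(n_out) || n_in < 1 || n_out < 1) {
    abort("n_in and n_out must be positive")
  }
  n <- n_in; m <- n_out
  s <- round(sqrt(0.43 * n * m + 0.12 * m^2 + 2.54 * n + 0.77 * m + 0.35) + 0.51)
  max(1L, as.integer(s))
}

#' Construct an Elman (or feedforward baseline) network
#'
#' An Elman network is a feedforward net whose hidden layer receives, in
#' addition to the inputs, the previous hidden activation through a context
#' (undertake) layer of the same size:
#' x(k) = f(w2 xc(k) + w1 u(k-1) + b1), xc(k) = x(k-1), y(k) = w3 x(k) + b2,
#' with sigmoid f and linear output. Biases are included (a zero-bias
#' sigmoid layer cannot shift its activation; this is a documented addition
#' to the classical equations). With `recurrent = FALSE` the context weights
#' w2 are frozen at zero and never trained, giving the plain BP feedforward
#' baseline; its w1/w3 initialization is identical to the recurrent net's
#' under the same seed.
#'
#' Weights are initialized uniformly in \[-0.5, 0.5\] from `seed`.
#'
#' @param n_in,n_hidden,n_out layer sizes; `n_hidden` defaults to
#'   [hidden_size()].
#' @param seed RNG seed for the initialization.
#' @param recurrent `FALSE` freezes the context weights at zero (BP
#'   baseline).
#' @return An object of class `elman_net`: weight matrices `w1` (r x n),
#'   `w2` (r x r), `w3` (m x r), biases `b1`, `b2`, the context state, and
#'   sizes.
#' @seealso [elman_forward()], [elman_train_lm()], [elman_train_gdm()]
#' @export
elman_net <- function(n_in, n_hidden = hidden_size(n_in, n_out), n_out = 1,
                      seed = 1, recurrent = TRUE) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  set.seed(seed)
  r <- as.integer(n_hidden); n <- as.integer(n_in); m <- as.integer(n_out)
  w1 <- matrix(runif(r * n, -0.5, 0.5), r, n)
  w2 <- matrix(runif(r * r, -0.5, 0.5), r, r)
  w3 <- matrix(runif(m * r, -0.5, 0.5), m, r)
  b1 <- runif(r, -0.5, 0.5)
  b2 <- runif(m, -0.5, 0.5)
  if (!recurrent) w2[] <- 0
  structure(list(w1 = w1, w2 = w2, w3 = w3, b1 = b1, b2 = b2,
                 context = rep(0, r), n_in = n, n_hidden = r, n_out = m,
                 recurrent = isTRUE(recurrent), seed = seed),
            class = "elman_net")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Single-step Elman forward pass
#'
#' Computes the hidden activation x = f(w1 u + w2 xc + b1) from the current
#' context xc, the linear output y = w3 x + b2, and updates the stored
#' context to the new hidden activation (xc(k) = x(k - 1)). Use this for
#' sequential (carry-over) operation; [elman_predict()] handles batch static
#' classification.
#'
#' @param net an `elman_net`.
#' @param u input vector of length `n_in`.
#' @return A list with `y` (output vector), `hidden` (hidden activation),
#'   and `net` (the network with its context updated).
#' @export
elman_forward <- function(net, u) {
  stopifnot(inherits(net, "elman_net"))
  u <- as.double(u)
  if (length(u) != net$n_in) abort("input length must equal n_in")
  z <- drop(net$w1 %*% u + net$w2 %*% net$context + net$b1)
  h <- sigmoid(z)
  y <- drop(net$w3 %*% h + net$b2)
  if (any(!is.finite(h)) || any(!is.finite(y))) abort("non-finite activations")
  net$context <- h
  list(y = y, hidden = h, net = net)
}

# Batch hidden activations in reset-per-sample mode: pass 1 runs with zero
# context and seeds the context from the sample itself; the final pass
# produces the output. Returns the final hidden matrix H (N x r) and the
# context CTX (N x r) that fed the final pass (the quantity the truncated
# gradient treats as constant).
elman_hidden_batch <- function(net, x, passes = 2L) {
  z1 <- x %*% t(net$w1) + matrix(net$b1, nrow(x), net$n_hidden, byrow = TRUE)
  h <- sigmoid(z1)
  ctx <- matrix(0, nrow(x), net$n_hidden)
  if (net$recurrent && passes >= 2) {
    for (p in 2:passes) {
      ctx <- h
      h <- sigmoid(z1 + ctx %*% t(net$w2))
    }
  }
  list(h = h, ctx = ctx)
}

#' Batch network outputs
#'
#' Continuous (linear-layer) outputs for a matrix of samples. In `"reset"`
#' mode (the default, appropriate for non-sequential tabular samples) the
#' context is re-seeded per sample: a first pass with zero context computes
#' a hidden activation, which becomes the context for the pass that produces
#' the output — so the recurrent weights participate without making
#' predictions depend on sample order. `"carry"` mode runs the samples as a
#' sequence, carrying the context across rows.
#'
#' @param net an `elman_net`.
#' @param x matrix or data frame of inputs (N x n_in).
#' @param context_mode `"reset"` or `"carry"`.
#' @param passes forward passes per sample in reset mode (>= 1).
#' @return A numeric matrix of outputs (N x n_out).
#' @export
elman_predict <- function(net, x, context_mode = c("reset", "carry"),
                          passes = 2L) {
  context_mode <- match.arg(context_mode)
  x <- as_feature_matrix(x, "x")
  if (ncol(x) != net$n_in) abort("input width must equal n_in")
  if (context_mode == "reset") {
    hb <- elman_hidden_batch(net, x, passes)
    y <- hb$h %*% t(net$w3) +
      matrix(net$b2, nrow(x), net$n_out, byrow = TRUE)
  } else {
    y <- matrix(0, nrow(x), net$n_out)
    net$context <- rep(0, net$n_hidden)
    for (i in seq_len(nrow(x))) {
      st <- elman_forward(net, x[i, ])
      y[i, ] <- st$y
      net <- st$net
    }
  }
  y
}

#' Sum of squared errors
#'
#' E = sum over samples and outputs of (t - y)^2, the training and
#' evaluation error measure.
#'
#' @param targets,outputs numeric vectors or matrices of equal shape.
#' @return A nonnegative number.
#' @export
elman_sse <- function(targets, outputs) {
  t_m <- as.matrix(targets); y_m <- as.matrix(outputs)
  if (!all(dim(t_m) == dim(y_m))) abort("targets and outputs must have equal shape")
  sum((t_m - y_m)^2)
}

# --- parameter packing -------------------------------------------------------
# theta order: vec(w1), vec(w2) [recurrent only], b1, vec(w3), b2
# (column-major within each block).

elman_pack <- function(net) {
  if (net$recurrent) {
    unname(c(as.vector(net$w1), as.vector(net$w2), net$b1, as.vector(net$w3),
             net$b2))
  } else {
    unname(c(as.vector(net$w1), net$b1, as.vector(net$w3), net$b2))
  }
}

elman_unpack <- function(net, theta) {
  n <- net$n_in; r <- net$n_hidden; m <- net$n_out
  i <- 0
  take <- function(k) {
    out <- theta[(i + 1):(i + k)]
    i <<- i + k
    out
  }
  net$w1 <- matrix(take(r * n), r, n)
  if (net$recurrent) net$w2 <- matrix(take(r * r), r, r)
  net$b1 <- take(r)
  net$w3 <- matrix(take(m * r), m, r)
  net$b2 <- take(m)
  net
}

# Jacobian of the network outputs w.r.t. the packed parameters under the
# truncated gradient: the context fed to the final pass is treated as a
# constant (Elman's original simplification, which makes batch
# Gauss-Newton/LM well defined). h and ctx come from elman_hidden_batch.
# Rows are ordered output-block-major: all samples for output 1, then
# output 2, ... matching as.vector(residual matrix).
elman_jacobian <- function(net, x, h, ctx) {
  n <- net$n_in; r <- net$n_hidden; m <- net$n_out
  N <- nrow(x)
  g <- h * (1 - h)                       # f'(z) at the final pass
  blocks <- vector("list", m)
  for (o in seq_len(m)) {
    a <- g * matrix(net$w3[o, ], N, r, byrow = TRUE)   # N x r
    jw1 <- x[, rep(seq_len(n), each = r), drop = FALSE] *
      a[, rep(seq_len(r), n), drop = FALSE]
    jb1 <- a
    jw3 <- matrix(0, N, m * r)
    jw3[, o + (seq_len(r) - 1) * m] <- h
    jb2 <- matrix(0, N, m)
    jb2[, o] <- 1
    if (net$recurrent) {
      jw2 <- ctx[, rep(seq_len(r), each = r), drop = FALSE] *
        a[, rep(seq_len(r), r), drop = FALSE]
      blocks[[o]] <- cbind(jw1, jw2, jb1, jw3, jb2)
    } else {
      blocks[[o]] <- cbind(jw1, jb1, jw3, jb2)
    }
  }
  do.call(rbind, blocks)
}

#' Levenberg-Marquardt training control parameters
#'
#' @param max_epochs maximum accepted weight updates.
#' @param goal_sse stop once the sum of squared errors reaches this value.
#' @param mu_init initial damping; `mu_inc` (> 1) multiplies it after a
#'   rejected step, `mu_dec` (in (0, 1)) after an accepted one; training
#'   stops if damping exceeds `mu_max` without an acceptable step.
#' @param context_mode,passes forward-pass handling, see [elman_predict()].
#' @return A list of class `elman_control`.
#' @export
elman_control <- function(max_epochs = 2000, goal_sse = 1e-3,
                          mu_init = 1e-3, mu_inc = 10, mu_dec = 0.1,
                          mu_max = 1e10, context_mode = "reset",
                          passes = 2L) {
  stopifnot(mu_init > 0, mu_inc > 1, mu_dec > 0, mu_dec < 1,
            max_epochs >= 0, goal_sse >= 0, passes >= 1)
  structure(list(max_epochs = as.integer(max_epochs), goal_sse = goal_sse,
                 mu_init = mu_init, mu_inc = mu_inc, mu_dec = mu_dec,
                 mu_max = mu_max, context_mode = context_mode,
                 passes = as.integer(passes)),
            class = "elman_control")
}

#' Train a network by batch Levenberg-Marquardt
#'
#' Damped Gauss-Newton on the sum of squared errors: the Jacobian J of the
#' per-sample residuals with respect to all trainable weights and biases is
#' built analytically (with the context treated as constant — the truncated
#' Elman gradient), the step solves (J'J + mu I) delta = J'e, and a step is
#' accepted only if the full forward-pass SSE decreases (then mu shrinks by
#' `mu_dec`; otherwise mu grows by `mu_inc` and the step is retried). The
#' accepted-step SSE trace is therefore non-increasing by construction.
#' Training stops at `goal_sse`, `max_epochs`, or when no acceptable step
#' exists below `mu_max`.
#'
#' @param net an `elman_net`.
#' @param x input matrix (N x n_in).
#' @param y target vector or matrix (N x n_out), numerically encoded labels
#'   for classification.
#' @param control an [elman_control()] list.
#' @return An object of class `elman_fit`: list with the trained `net`,
#'   `epochs_run`, `final_sse`, and the accepted-step `sse_trace` (starting
#'   at the initial SSE).
#' @export
elman_train_lm <- function(net, x, y, control = elman_control()) {
  stopifnot(inherits(net, "elman_net"))
  x <- as_feature_matrix(x, "x")
  ym <- as.matrix(y)
  if (nrow(ym) != nrow(x)) abort("x and y must have the same number of rows")
  if (ncol(ym) != net$n_out) abort("target width must equal n_out")

  theta <- elman_pack(net)
  np <- length(theta)
  sse_cur <- elman_sse(ym, elman_predict(net, x, control$context_mode,
                                         control$passes))
  trace <- sse_cur
  mu <- control$mu_init
  epochs <- 0L

  while (epochs < control$max_epochs && sse_cur > control$goal_sse) {
    hb <- elman_hidden_batch(net, x, control$passes)
    yhat <- hb$h %*% t(net$w3) +
      matrix(net$b2, nrow(x), net$n_out, byrow = TRUE)
    e <- as.vector(ym - yhat)
    J <- elman_jacobian(net, x, hb$h, hb$ctx)
    H <- crossprod(J)
    grad <- drop(crossprod(J, e))

    improved <- FALSE
    while (mu <= control$mu_max) {
      delta <- tryCatch(solve(H + diag(mu, np), grad),
                        error = function(err) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        cand <- elman_unpack(net, theta + delta)
        sse_new <- elman_sse(ym, elman_predict(cand, x, control$context_mode,
                                               control$passes))
        if (is.finite(sse_new) && sse_new < sse_cur) {
          net <- cand
          theta <- theta + delta
          sse_cur <- sse_new
          mu <- max(mu * control$mu_dec, 1e-12)
          improved <- TRUE
          break
        }
      }
      mu <- mu * control$mu_inc
    }
    if (!improved) break  # damping exhausted: local optimum reached
    epochs <- epochs + 1L
    trace <- c(trace, sse_cur)
  }
  structure(list(net = net, epochs_run = epochs, final_sse = sse_cur,
                 sse_trace = trace, trainer = "lm"),
            class = "elman_fit")
}

#' Train a network by gradient descent with momentum
#'
#' Batch gradient descent with a momentum term on the same truncated
#' gradient as [elman_train_lm()]: delta = momentum * delta_prev -
#' lr * grad(SSE). Provided as the classical weight/bias learning rule and
#' as an alternative trainer for the feedforward baseline.
#'
#' @inheritParams elman_train_lm
#' @param lr learning rate (> 0).
#' @param momentum momentum coefficient in \[0, 1).
#' @param epochs number of epochs to run.
#' @param goal_sse optional early-stop target.
#' @return An `elman_fit` (the SSE trace here records every epoch and need
#'   not be monotone; divergence to non-finite SSE is an error).
#' @export
elman_train_gdm <- function(net, x, y, lr = 0.01, momentum = 0.9,
                            epochs = 500, goal_sse = 0) {
  stopifnot(inherits(net, "elman_net"), lr >= 0, momentum >= 0, momentum < 1)
  x <- as_feature_matrix(x, "x")
  ym <- as.matrix(y)
  theta <- elman_pack(net)
  velocity <- numeric(length(theta))
  sse_cur <- elman_sse(ym, elman_predict(net, x))
  trace <- sse_cur
  run <- 0L
  for (ep in seq_len(epochs)) {
    if (sse_cur <= goal_sse) break
    hb <- elman_hidden_batch(net, x, 2L)
    yhat <- hb$h %*% t(net$w3) + matrix(net$b2, nrow(x), net$n_out, byrow = TRUE)
    e <- as.vector(ym - yhat)
    J <- elman_jacobian(net, x, hb$h, hb$ctx)
    grad <- -2 * drop(crossprod(J, e))   # d SSE / d theta
    velocity <- momentum * velocity - lr * grad
    theta <- theta + velocity
    net <- elman_unpack(net, theta)
    sse_cur <- elman_sse(ym, elman_predict(net, x))
    if (!is.finite(sse_cur)) {
      abort(sprintf("gradient-descent training diverged at epoch %d", ep))
    }
    run <- ep
    trace <- c(trace, sse_cur)
  }
  structure(list(net = net, epochs_run = run, final_sse = sse_cur,
                 sse_trace = trace, trainer = "gdm"),
            class = "elman_fit")
}

#' Decode continuous network outputs to class labels
#'
#' Maps each continuous output to the nearest value in `class_values`
#' (ties to the lower class; outputs beyond the range clamp to the nearest
#' end).
#'
#' @param outputs numeric vector (or single-column matrix) of network
#'   outputs.
#' @param class_values sorted vector of numeric class codes.
#' @return A vector of class values, one per output.
#' @examples
#' decode_labels(c(1.4, 1.5, -7), c(1, 2, 3))  # 1 1 1
#' @export
decode_labels <- function(outputs, class_values) {
  if (length(class_values) == 0) abort("class_values must be nonempty")
  if (is.unsorted(class_values)) abort("class_values must be sorted")
  out <- as.vector(as.matrix(outputs))
  idx <- vapply(out, function(v) which.min(abs(class_values - v)), integer(1))
  class_values[idx]
}
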