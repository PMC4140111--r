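#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_segment geom_text labs theme_minimal facet_wrap scale_y_log10
#' @export
ggplot2::autoplot

#' Plot the PRESS curve of a PLS model
#'
#' Cross-validated prediction residual sum of squares against candidate
#' component count, with the selected count marked.
#'
#' @param object a `pls_model` (fitted with a PRESS curve attached) or the
#'   list returned by [pls_select_ncomp()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pls_model
#' @export
autoplot.pls_model <- function(object, ...) {
  press <- object$press
  if (is.null(press)) {
    abort("this model has no PRESS curve (component count was fixed)")
  }
  ggplot(press, aes(x = .data$ncomp, y = .data$press)) +
    geom_line() +
    geom_point() +
    geom_point(data = press[which.min(press$press), ], colour = "red",
               size = 3) +
    labs(x = "components", y = "PRESS",
         title = "Cross-validated PRESS by component count") +
    theme_minimal()
}

#' Plot a training SSE trace
#'
#' @param object an `elman_fit`.
#' @param ... unused.
#' @return A ggplot object (log-scale SSE against accepted epoch).
#' @method autoplot elman_fit
#' @export
autoplot.elman_fit <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$epoch, y = .data$sse)) +
    geom_line() +
    scale_y_log10() +
    labs(x = "accepted epoch", y = "SSE",
         title = sprintf("Training error (%s)", object$trainer)) +
    theme_minimal()
}

#' Plot a UPGMA dendrogram
#'
#' @param object an `upgma_tree`.
#' @param ... unused.
#' @return A ggplot dendrogram.
#' @method autoplot upgma_tree
#' @export
autoplot.upgma_tree <- function(object, ...) {
  hc <- as.hclust(object)
  n <- object$n
  # leaf x-positions follow the plotting order; merge node positions are
  # the mean of their children's
  xpos <- numeric(n)
  xpos[hc$order] <- seq_len(n)
  node_x <- numeric(n - 1); node_y <- hc$height
  segs <- vector("list", n - 1)
  child_pos <- function(v) {
    if (v < 0) c(xpos[-v], 0) else c(node_x[v], node_y[v])
  }
  for (s in seq_len(n - 1)) {
    a <- child_pos(hc$merge[s, 1]); b <- child_pos(hc$merge[s, 2])
    node_x[s] <- mean(c(a[1], b[1]))
    segs[[s]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], node_y[s], b[2]), yend = c(node_y[s], node_y[s], node_y[s]))
  }
  leaves <- tibble::tibble(x = xpos, label = object$labels)
  ggplot() +
    geom_segment(data = dplyr::bind_rows(segs),
                 aes(x = .data$x, xend = .data$xend, y = .data$y,
                     yend = .data$yend)) +
    geom_text(data = leaves, aes(x = .data$x, y = 0, label = .data$label),
              angle = 90, hjust = 1.1, size = 2.5) +
    labs(x = NULL, y = "merge height (Mahalanobis)", title = "UPGMA dendrogram") +
    theme_minimal()
}

#' Plot benchmark accuracies
#'
#' Seed-averaged recognition accuracy per variant, with the individual runs
#' overplotted.
#'
#' @param object a `plsca_benchmark` tibble.
#' @param metric column to plot: `"accuracy"` (default) or `"sse"`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot plsca_benchmark
#' @export
autoplot.plsca_benchmark <- function(object, metric = c("accuracy", "sse"),
                                     ...) {
  metric <- match.arg(metric)
  means <- dplyr::filter(object, .data$stat == "mean")
  runs <- dplyr::filter(object, .data$stat == "run")
  ggplot(means, aes(x = .data$variant, y = .data[[metric]])) +
    geom_col(fill = "grey70") +
    geom_point(data = runs, alpha = 0.5) +
    labs(x = NULL, y = metric,
         title = sprintf("Benchmark %s by variant (bars: seed means)",
                         metric)) +
    theme_minimal()
}
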