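#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a PLS model
#'
#' One row per extracted component: residual Frobenius norms of X and Y
#' after deflation, the inner-relation regression coefficient, and the PRESS
#' value when the component count was cross-validated.
#'
#' @param x a `pls_model`.
#' @param ... unused.
#' @return A tibble with columns `component`, `x_residual_norm`,
#'   `y_residual_norm`, `inner_coef`, and `press` (NA when unavailable).
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  out <- tibble::tibble(component = seq_len(x$ncomp),
                        x_residual_norm = x$x_residual_norm,
                        y_residual_norm = x$y_residual_norm,
                        inner_coef = x$inner_coef)
  if (!is.null(x$press)) {
    out <- dplyr::left_join(out,
                            dplyr::rename(x$press, component = "ncomp"),
                            by = "component")
  } else {
    out$press <- NA_real_
  }
  out
}

#' @rdname tidy.pls_model
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, ncomp_requested = x$ncomp_requested,
                 n_features = nrow(x$weights),
                 x_residual_norm = x$x_residual_norm[x$ncomp],
                 y_residual_norm = x$y_residual_norm[x$ncomp])
}

#' Tidy a fitted pipeline
#'
#' One row per subclass expert: member count, hidden size, accepted training
#' epochs, and final training SSE.
#'
#' @param x a `plsca_model`.
#' @param ... unused.
#' @return A tibble with one row per expert.
#' @method tidy plsca_model
#' @export
tidy.plsca_model <- function(x, ...) {
  sizes <- if (!is.null(x$partition)) x$partition$sizes else x$n_train
  tibble::tibble(
    subclass = as.integer(names(x$experts)),
    n_members = as.integer(sizes),
    n_inputs = purrr::map_int(x$experts, ~ .x$net$n_in),
    n_hidden = purrr::map_int(x$experts, ~ .x$net$n_hidden),
    epochs = purrr::map_int(x$experts, "epochs_run"),
    final_sse = purrr::map_dbl(x$experts, "final_sse"))
}

#' @rdname tidy.plsca_model
#' @method glance plsca_model
#' @export
glance.plsca_model <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    n_train = x$n_train,
    n_inputs = x$experts[[1]]$net$n_in,
    ncomp = if (!is.null(x$pls)) x$pls$ncomp
            else if (!is.null(x$pca)) x$pca$k else NA_integer_,
    k_subclasses = x$k_subclasses,
    training_steps = x$training_steps,
    training_sse = x$training_sse)
}

#' Tidy an Elman training report
#'
#' @param x an `elman_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per recorded SSE (epoch 0 is the initial
#'   state); `glance()`: a one-row summary.
#' @method tidy elman_fit
#' @export
tidy.elman_fit <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$sse_trace) - 1L, sse = x$sse_trace)
}

#' @rdname tidy.elman_fit
#' @method glance elman_fit
#' @export
glance.elman_fit <- function(x, ...) {
  tibble::tibble(trainer = x$trainer, epochs_run = x$epochs_run,
                 final_sse = x$final_sse,
                 n_hidden = x$net$n_hidden, recurrent = x$net$recurrent)
}

#' @export
print.plsca_model <- function(x, ...) {
  cat(sprintf("<plsca_model> variant=%s, %d training samples\n",
              x$variant, x$n_train))
  if (!is.null(x$pls)) {
    cat(sprintf("  PLS: %d component(s)\n", x$pls$ncomp))
  }
  if (!is.null(x$pca)) cat(sprintf("  PCA: %d component(s)\n", x$pca$k))
  if (!is.null(x$partition)) {
    cat(sprintf("  subclasses: %d (sizes %s)\n", x$k_subclasses,
                paste(x$partition$sizes, collapse = ", ")))
  }
  cat(sprintf("  experts: %d, total accepted epochs %d, training SSE %.4g\n",
              length(x$experts), x$training_steps, x$training_sse))
  invisible(x)
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d leaves, %d merges, height range [%.4g, %.4g]\n",
              x$n, nrow(x$merges), min(x$merges$height),
              max(x$merges$height)))
  invisible(x)
}

#' @export
print.elman_net <- function(x, ...) {
  cat(sprintf("<elman_net> %d-%d-%d (%s), seed %s\n", x$n_in, x$n_hidden,
              x$n_out, if (x$recurrent) "recurrent" else "feedforward (bp)",
              format(x$seed)))
  invisible(x)
}
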