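#' Fit a cluster-wise Elman classification pipeline
#'
#' The full optimized pipeline (default variant `"plsca_elman"`) on a
#' training set: standardize the features; compress them to l latent
#' components by NIPALS PLS with PRESS-selected l; partition the training
#' samples into subclasses by UPGMA clustering on pairwise Mahalanobis
#' distances in the compressed space; and train one Elman network expert per
#' subclass (hidden size from the empirical formula with n = l inputs) by
#' batch Levenberg-Marquardt on the numeric class codes. Prediction routes
#' each new sample to the nearest subclass centre and decodes that expert's
#' continuous output to the nearest class value.
#'
#' Baseline variants drop stages: `"pls_elman"` and `"pca_elman"` skip the
#' partition (one network on compressed features), `"ca_elman"` skips the
#' compression (clustering on standardized features), `"elman"` and `"bp"`
#' use a single network on standardized features (`"bp"` is the feedforward
#' net with frozen context weights).
#'
#' @param data training data frame: one label column plus numeric features.
#' @param label name of the label column.
#' @param variant one of `"plsca_elman"`, `"ca_elman"`, `"pls_elman"`,
#'   `"pca_elman"`, `"elman"`, `"bp"`.
#' @param k_subclasses number of subclasses for the clustering variants
#'   (3-6 is the recommended range; both reference experiments use 3).
#' @param min_subclass subclasses smaller than this are merged into the
#'   nearest-centre subclass before training (an untrainably small subclass
#'   guard).
#' @param ncomp PLS component count; `NULL` (default) selects it by K-fold
#'   cross-validated PRESS.
#' @param k_folds folds for the PRESS selection.
#' @param pca_threshold cumulative explained-variance threshold for
#'   `"pca_elman"`.
#' @param control an [elman_control()] list for the expert training.
#' @param seed base seed; expert s is initialized from `seed + s - 1`, so a
#'   fitted model replays identically from its recorded configuration.
#' @return An object of class `plsca_model` holding the standardization
#'   parameters, the PLS/PCA model (when used), the `subclass_partition`
#'   (when used), one trained expert per subclass with its training report,
#'   the class values, and the full provenance (variant, seeds, control).
#' @seealso [predict.plsca_model()], [plsca_evaluate()], [plsca_benchmark()]
#' @examples
#' sim <- simulate_preset("midge_like")
#' sets <- split_leading(sim$data, 45)
#' fit <- plsca_fit(sets$train, control = elman_control(max_epochs = 50))
#' glance(fit)
#' @export
plsca_fit <- function(data, label = "class",
                      variant = c("plsca_elman", "ca_elman", "pls_elman",
                                  "pca_elman", "elman", "bp"),
                      k_subclasses = 3, min_subclass = 3, ncomp = NULL,
                      k_folds = 10, pca_threshold = 0.8,
                      control = elman_control(), seed = 1) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(data))
  if (!label %in% names(data)) abort(sprintf("label column '%s' not found", label))
  y <- as.double(data[[label]])
  if (anyNA(y)) abort("missing labels")
  feats <- setdiff(names(data), c(label, "sample_id"))
  x <- as_feature_matrix(data[feats], "training features")
  class_values <- sort(unique(y))
  if (length(class_values) < 2) abort("need at least 2 classes to fit a classifier")

  uses_pls <- variant %in% c("plsca_elman", "pls_elman")
  uses_pca <- variant == "pca_elman"
  uses_ca <- variant %in% c("plsca_elman", "ca_elman")

  std <- standardize_fit(x)
  xs <- as.matrix(standardize_apply(x, std))

  pls <- NULL; pca <- NULL; press <- NULL
  z <- xs
  if (uses_pls) {
    if (is.null(ncomp)) {
      kf <- min(k_folds, floor(nrow(xs) / 2))
      sel <- pls_select_ncomp(xs, y, k_folds = kf)
      ncomp <- sel$ncomp
      press <- sel$press
    }
    pls <- pls_fit(xs, y, ncomp = ncomp)
    pls$press <- press
    z <- as.matrix(pls_scores(pls, xs))
  } else if (uses_pca) {
    pca <- pca_fit(xs, threshold = pca_threshold)
    z <- as.matrix(pca_scores(pca, xs))
  }

  partition <- NULL
  assignment <- rep(1L, nrow(z))
  if (uses_ca) {
    if (k_subclasses < 1 || k_subclasses > nrow(z)) {
      abort(sprintf("k_subclasses must be in 1..%d", nrow(z)))
    }
    v_inv <- safe_inverse(pooled_cov(z))
    tree <- upgma(mahalanobis_matrix(z, v_inv))
    assignment <- cut_upgma(tree, k = k_subclasses)
    assignment <- merge_small_subclasses(z, assignment, v_inv, min_subclass)
    partition <- partition_summarize(z, assignment)
    partition$tree <- tree
  }

  ids <- sort(unique(assignment))
  experts <- purrr::map(seq_along(ids), function(s) {
    members <- assignment == ids[s]
    if (sum(members) < 2) {
      abort(sprintf("subclass %d too small to train (%d sample[s])",
                    ids[s], sum(members)))
    }
    net <- elman_net(ncol(z), hidden_size(ncol(z), 1), 1,
                     seed = seed + s - 1, recurrent = variant != "bp")
    elman_train_lm(net, z[members, , drop = FALSE], y[members], control)
  })
  names(experts) <- as.character(ids)

  structure(list(
    variant = variant, label = label, feature_names = feats,
    class_values = class_values, std = std, pls = pls, pca = pca,
    partition = partition, experts = experts, control = control,
    seed = seed, k_subclasses = if (uses_ca) length(ids) else 1L,
    training_steps = sum(purrr::map_int(experts, "epochs_run")),
    training_sse = sum(purrr::map_dbl(experts, "final_sse")),
    n_train = nrow(x)
  ), class = "plsca_model")
}

# Whole small subclasses are moved to the subclass with the nearest centre
# (Mahalanobis metric), repeatedly, until every subclass has at least
# `floor` members or one subclass remains. Ids relabelled 1..K afterwards.
merge_small_subclasses <- function(z, assignment, v_inv, floor_size) {
  repeat {
    ids <- sort(unique(assignment))
    if (length(ids) <= 1) break
    sizes <- vapply(ids, function(s) sum(assignment == s), integer(1))
    small <- ids[sizes < floor_size]
    if (length(small) == 0) break
    victim <- small[which.min(sizes[match(small, ids)])]
    centers <- t(vapply(ids, function(s) {
      colMeans(z[assignment == s, , drop = FALSE])
    }, numeric(ncol(z))))
    others <- setdiff(ids, victim)
    dists <- vapply(others, function(s) {
      mahalanobis_pair(centers[match(victim, ids), ],
                       centers[match(s, ids), ], v_inv)
    }, numeric(1))
    assignment[assignment == victim] <- others[which.min(dists)]
  }
  relabel_first_appearance(assignment)
}

# project new samples into the model's working feature space
model_transform <- function(model, data) {
  x <- if (is.data.frame(data)) {
    missing <- setdiff(model$feature_names, names(data))
    if (length(missing) > 0) {
      abort(sprintf("missing feature column(s): %s",
                    paste(missing, collapse = ", ")))
    }
    as_feature_matrix(data[model$feature_names], "features")
  } else {
    as_feature_matrix(data, "features")
  }
  xs <- as.matrix(standardize_apply(x, model$std))
  if (!is.null(model$pls)) {
    as.matrix(pls_scores(model$pls, xs))
  } else if (!is.null(model$pca)) {
    as.matrix(pca_scores(model$pca, xs))
  } else {
    xs
  }
}

#' Predict class labels with a fitted pipeline
#'
#' Standardizes and compresses the new samples with the training-set
#' parameters, routes each to its subclass by nearest-centre Mahalanobis
#' distance, runs that subclass's expert network, and decodes the continuous
#' output to the nearest class value.
#'
#' @param object a `plsca_model`.
#' @param newdata data frame (the label column may be absent) or feature
#'   matrix.
#' @param ... unused.
#' @return A tibble with one row per sample: `.pred` (decoded class),
#'   `.pred_value` (continuous network output), `.subclass`, `.distance`
#'   (routing distance; 0/NA-free audit columns).
#' @export
predict.plsca_model <- function(object, newdata, ...) {
  z <- model_transform(object, newdata)
  n <- nrow(z)
  if (n < 1) abort("newdata is empty")
  if (!is.null(object$partition)) {
    route <- assign_subclass(z, object$partition)
  } else {
    route <- tibble::tibble(subclass = rep(1L, n), distance = rep(0, n))
  }
  value <- numeric(n)
  for (s in unique(route$subclass)) {
    members <- route$subclass == s
    expert <- object$experts[[as.character(s)]]
    value[members] <- elman_predict(expert$net, z[members, , drop = FALSE],
                                    object$control$context_mode,
                                    object$control$passes)[, 1]
  }
  tibble::tibble(.pred = decode_labels(value, object$class_values),
                 .pred_value = value,
                 .subclass = route$subclass,
                 .distance = route$distance)
}

#' Evaluate a fitted pipeline on a simulation set
#'
#' Computes the benchmark metrics on a labelled (or unlabelled) hold-out
#' set: recognition accuracy in percent, the sum of squared errors between
#' the numeric labels and the continuous network outputs, and the recorded
#' training steps (total accepted weight updates across experts).
#'
#' @param model a `plsca_model`.
#' @param newdata data frame; accuracy and SSE are `NA` if the label column
#'   is absent.
#' @param label label column name (defaults to the one used at fit time).
#' @return A one-row tibble: `variant`, `accuracy`, `sse`, `training_steps`,
#'   `n`.
#' @export
plsca_evaluate <- function(model, newdata, label = model$label) {
  stopifnot(inherits(model, "plsca_model"))
  pred <- predict(model, newdata)
  has_labels <- is.data.frame(newdata) && label %in% names(newdata)
  if (has_labels) {
    y <- as.double(newdata[[label]])
    acc <- 100 * mean(pred$.pred == y)
    sse <- sum((y - pred$.pred_value)^2)
  } else {
    acc <- NA_real_; sse <- NA_real_
  }
  tibble::tibble(variant = model$variant, accuracy = acc, sse = sse,
                 training_steps = model$training_steps, n = nrow(pred))
}

#' Benchmark pipeline variants on a train/simulation split
#'
#' Fits each requested variant for each seed, evaluates it on the
#' simulation set, and returns one row per (variant, seed) plus one
#' seed-averaged `"mean"` row per variant — the layout of the standard
#' comparison table (accuracy %, training steps, run time in seconds, SSE).
#' Training steps are reported as `NA` for the cluster-wise variants, whose
#' per-expert step counts are not comparable to a single network's (they
#' remain recorded inside each fitted model). A variant that errors yields
#' an NA row with the message; the remaining variants still run.
#'
#' @param train,sim labelled data frames.
#' @param label label column name.
#' @param variants character vector of variants (see [plsca_fit()]), or
#'   `"all"`.
#' @param seeds integer vector of seeds.
#' @param ... passed to [plsca_fit()] (e.g. `k_subclasses`, `control`).
#' @return A tibble of class `plsca_benchmark` with columns `variant`,
#'   `seed`, `stat` (`"run"` or `"mean"`), `accuracy`, `training_steps`,
#'   `run_time_s`, `sse`, `error`.
#' @export
plsca_benchmark <- function(train, sim, label = "class", variants = "all",
                            seeds = 1L, ...) {
  all_variants <- c("bp", "elman", "pca_elman", "pls_elman", "ca_elman",
                    "plsca_elman")
  if (identical(variants, "all")) variants <- all_variants
  if (length(variants) < 1) abort("at least one variant required")
  bad <- setdiff(variants, all_variants)
  if (length(bad) > 0) abort(sprintf("unknown variant(s): %s", paste(bad, collapse = ", ")))
  ca_variants <- c("ca_elman", "plsca_elman")

  grid <- tidyr::expand_grid(variant = variants, seed = as.integer(seeds))
  rows <- purrr::pmap(grid, function(variant, seed) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      model <- plsca_fit(train, label = label, variant = variant,
                         seed = seed, ...)
      ev <- plsca_evaluate(model, sim, label = label)
      ev$error <- NA_character_
      ev
    }, error = function(e) {
      tibble::tibble(variant = variant, accuracy = NA_real_, sse = NA_real_,
                     training_steps = NA_integer_, n = nrow(sim),
                     error = conditionMessage(e))
    })
    res$seed <- seed
    res$run_time_s <- proc.time()[["elapsed"]] - t0
    res
  })
  runs <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      stat = "run",
      training_steps = dplyr::if_else(.data$variant %in% ca_variants,
                                      NA_integer_,
                                      as.integer(.data$training_steps)))
  means <- runs |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(
      seed = NA_integer_, stat = "mean",
      accuracy = mean(.data$accuracy, na.rm = TRUE),
      training_steps = as.integer(round(mean(.data$training_steps))),
      run_time_s = mean(.data$run_time_s),
      sse = mean(.data$sse, na.rm = TRUE),
      n = sum(!is.na(.data$accuracy)),
      error = NA_character_, .groups = "drop")
  out <- dplyr::bind_rows(runs, means) |>
    dplyr::mutate(variant = factor(.data$variant, levels = all_variants)) |>
    dplyr::arrange(.data$variant, .data$stat == "mean", .data$seed) |>
    dplyr::mutate(variant = as.character(.data$variant)) |>
    dplyr::select("variant", "seed", "stat", "accuracy", "training_steps",
                  "run_time_s", "sse", "n", "error")
  class(out) <- c("plsca_benchmark", class(out))
  out
}
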