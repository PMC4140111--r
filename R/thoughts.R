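#' Fit an alternative stage ordering of the pipeline
#'
#' The reduction, clustering, and expert-training stages can be composed in
#' four orders; the shipped default ([plsca_fit()]) is ordering 4. The
#' others are provided because their documented failure modes are
#' instructive:
#' \describe{
#'   \item{1}{Cluster all samples (training + simulation together) on
#'     standardized features, then compress each subclass separately by
#'     PLS and train on its training members. Errors if any subclass
#'     contains no training samples — with the test samples taking part in
#'     the clustering, a subclass can be untrainable.}
#'   \item{2}{Cluster the training samples only, then fit an independent
#'     PLS per subclass. The per-subclass selections can disagree (a
#'     warning reports the differing component counts); simulation samples
#'     are routed in the standardized feature space and compressed by the
#'     winning subclass's own PLS.}
#'   \item{3}{Compress all samples once by PLS, then cluster training and
#'     simulation jointly in the compressed space. Same untrainable-subclass
#'     error as ordering 1.}
#'   \item{4}{Compress once globally, cluster the training set only, route
#'     test samples by discriminant — identical to
#'     `plsca_fit(train, ...)`.}
#' }
#'
#' @param train,sim labelled data frames (orderings 1 and 3 cluster both
#'   sets jointly; ordering 4 ignores `sim` at fit time).
#' @param thought stage ordering, 1-4.
#' @param label label column name.
#' @param k_subclasses subclass count.
#' @param ncomp PLS components (`NULL` = PRESS-selected).
#' @param k_folds folds for PRESS selection.
#' @param control an [elman_control()].
#' @param seed base seed.
#' @return For `thought = 4`, a `plsca_model`. Otherwise a
#'   `thought_model`: a list with the per-subclass models, the joint or
#'   training-set assignment, and `sim_pred`, the routed predictions for
#'   `sim` (tibble with `.pred`, `.pred_value`, `.subclass`).
#' @export
fit_thought <- function(train, sim, thought, label = "class",
                        k_subclasses = 3, ncomp = NULL, k_folds = 10,
                        control = elman_control(), seed = 1) {
  stopifnot(thought %in% 1:4)
  if (thought == 4) {
    return(plsca_fit(train, label = label, k_subclasses = k_subclasses,
                     ncomp = ncomp, k_folds = k_folds, control = control,
                     seed = seed))
  }
  y_tr <- as.double(train[[label]])
  class_values <- sort(unique(y_tr))
  feats <- setdiff(names(train), c(label, "sample_id"))
  x_tr <- as_feature_matrix(train[feats], "train")
  x_si <- as_feature_matrix(sim[feats], "sim")
  n_tr <- nrow(x_tr); n_si <- nrow(x_si)

  if (thought %in% c(1, 3)) {
    x_all <- rbind(x_tr, x_si)
    std <- standardize_fit(x_all)
    xs_all <- as.matrix(standardize_apply(x_all, std))
    pls_global <- NULL
    z_all <- xs_all
    if (thought == 3) {
      # labels of all samples drive the global compression in this ordering
      y_all <- c(y_tr, as.double(sim[[label]]))
      l <- ncomp %||% pls_select_ncomp(xs_all, y_all, k_folds = k_folds)$ncomp
      pls_global <- pls_fit(xs_all, y_all, ncomp = l)
      z_all <- as.matrix(pls_scores(pls_global, xs_all))
    }
    v_inv <- safe_inverse(pooled_cov(z_all))
    assignment <- cut_upgma(upgma(mahalanobis_matrix(z_all, v_inv)),
                            k = k_subclasses)
    is_train <- seq_len(n_tr + n_si) <= n_tr
    experts <- list()
    for (s in sort(unique(assignment))) {
      members <- assignment == s
      tr_members <- members & is_train
      if (!any(tr_members)) {
        abort(sprintf(
          "subclass %d contains no training samples; its network cannot be trained",
          s))
      }
      if (sum(tr_members) < 2) {
        abort(sprintf("subclass %d has only %d training sample(s); too small to train",
                      s, sum(tr_members)))
      }
      z_sub <- z_all[tr_members, , drop = FALSE]
      y_sub <- y_tr[which(tr_members)]
      sub_pls <- NULL
      z_fit <- z_sub
      if (thought == 1) {  # per-subclass compression in this ordering
        l_sub <- min(ncomp %||% ncol(z_sub), nrow(z_sub) - 1, ncol(z_sub))
        sub_pls <- pls_fit(z_sub, y_sub, ncomp = l_sub)
        z_fit <- as.matrix(pls_scores(sub_pls, z_sub))
      }
      net <- elman_net(ncol(z_fit), hidden_size(ncol(z_fit), 1), 1,
                       seed = seed + s - 1)
      experts[[as.character(s)]] <- list(
        pls = sub_pls, fit = elman_train_lm(net, z_fit, y_sub, control))
    }
    sim_assign <- assignment[!is_train]
    value <- numeric(n_si)
    for (s in unique(sim_assign)) {
      members <- sim_assign == s
      ex <- experts[[as.character(s)]]
      z_in <- z_all[!is_train, , drop = FALSE][members, , drop = FALSE]
      if (!is.null(ex$pls)) z_in <- as.matrix(pls_scores(ex$pls, z_in))
      value[members] <- elman_predict(ex$fit$net, z_in)[, 1]
    }
    sim_pred <- tibble::tibble(.pred = decode_labels(value, class_values),
                               .pred_value = value,
                               .subclass = as.integer(sim_assign))
    return(structure(list(thought = thought, assignment = assignment,
                          experts = experts, class_values = class_values,
                          sim_pred = sim_pred),
                     class = "thought_model"))
  }

  # thought 2: cluster training only, independent PLS per subclass
  std <- standardize_fit(x_tr)
  xs_tr <- as.matrix(standardize_apply(x_tr, std))
  xs_si <- as.matrix(standardize_apply(x_si, std))
  v_inv <- safe_inverse(pooled_cov(xs_tr))
  assignment <- cut_upgma(upgma(mahalanobis_matrix(xs_tr, v_inv)),
                          k = k_subclasses)
  assignment <- merge_small_subclasses(xs_tr, assignment, v_inv, 3)
  partition <- partition_summarize(xs_tr, assignment)
  experts <- list()
  for (s in sort(unique(assignment))) {
    members <- assignment == s
    z_sub <- xs_tr[members, , drop = FALSE]
    y_sub <- y_tr[members]
    l_sub <- if (is.null(ncomp)) {
      kf <- max(2, min(k_folds, floor(nrow(z_sub) / 2)))
      tryCatch(pls_select_ncomp(z_sub, y_sub, k_folds = kf)$ncomp,
               error = function(e) min(nrow(z_sub) - 1L, ncol(z_sub)))
    } else {
      min(ncomp, nrow(z_sub) - 1L, ncol(z_sub))
    }
    sub_pls <- pls_fit(z_sub, y_sub, ncomp = l_sub)
    z_fit <- as.matrix(pls_scores(sub_pls, z_sub))
    net <- elman_net(ncol(z_fit), hidden_size(ncol(z_fit), 1), 1,
                     seed = seed + s - 1)
    experts[[as.character(s)]] <- list(
      pls = sub_pls, fit = elman_train_lm(net, z_fit, y_sub, control))
  }
  dims <- vapply(experts, function(e) e$pls$ncomp, integer(1))
  if (length(unique(dims)) > 1) {
    warn(sprintf(
      "per-subclass compression is out of step: component counts %s differ across subclasses",
      paste(dims, collapse = ", ")))
  }
  route <- assign_subclass(xs_si, partition)
  value <- numeric(n_si)
  for (s in unique(route$subclass)) {
    members <- route$subclass == s
    ex <- experts[[as.character(s)]]
    z_in <- as.matrix(pls_scores(ex$pls, xs_si[members, , drop = FALSE]))
    value[members] <- elman_predict(ex$fit$net, z_in)[, 1]
  }
  structure(list(thought = 2, assignment = assignment, experts = experts,
                 class_values = class_values,
                 sim_pred = tibble::tibble(
                   .pred = decode_labels(value, class_values),
                   .pred_value = value,
                   .subclass = route$subclass)),
            class = "thought_model")
}
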