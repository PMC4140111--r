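#' Route samples to subclasses by nearest-centre Mahalanobis distance
#'
#' Each sample is assigned to the subclass whose centre is closest in the
#' Mahalanobis metric defined by the partition's pooled inverse covariance;
#' ties go to the lowest subclass id. This is the discriminant step that
#' sends each simulation sample to the expert network trained on its
#' subclass.
#'
#' @param data matrix or data frame of samples in the same working feature
#'   space as the partition (e.g. PLS scores).
#' @param partition a `subclass_partition` from [partition_summarize()].
#' @return A tibble with one row per sample: `subclass` (integer id) and
#'   `distance` (the Mahalanobis distance to the winning centre, for audit).
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
#' part <- partition_summarize(x, rep(1:2, each = 10))
#' assign_subclass(x[1:3, ], part)
#' @export
assign_subclass <- function(data, partition) {
  stopifnot(inherits(partition, "subclass_partition"))
  x <- as_feature_matrix(data, "data")
  if (partition$k < 1) abort("empty partition")
  if (ncol(x) != ncol(partition$centers)) {
    abort(sprintf("feature dimension mismatch: samples have %d, partition %d",
                  ncol(x), ncol(partition$centers)))
  }
  d2 <- vapply(seq_len(partition$k), function(s) {
    mahalanobis(x, partition$centers[s, ], partition$v_inv, inverted = TRUE)
  }, numeric(nrow(x)))
  d2 <- matrix(pmax(d2, 0), nrow = nrow(x))
  pick <- max.col(-d2, ties.method = "first")  # lowest id wins ties
  tibble::tibble(subclass = as.integer(pick),
                 distance = sqrt(d2[cbind(seq_len(nrow(x)), pick)]))
}
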