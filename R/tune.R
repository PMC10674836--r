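#' ROC grid over feature-threshold pairs
#'
#' Evaluates the step-1 classifier "AF iff `count_rr <= a` and
#' `svd_ratio <= b`" for every candidate pair (a, b) and computes its
#' sensitivity, specificity and Euclidean distance to the perfect ROC corner,
#' `sqrt((1 - Se)^2 + (1 - Sp)^2)` (the corner (0, 1) in (1 - Sp, Se)
#' coordinates). By default the grids are the sorted unique observed feature
#' values plus `Inf`, which covers every threshold-equivalence class, so the
#' global optimum over all possible cutoffs is always in the grid.
#'
#' @param features Data frame with columns `count_rr`, `svd_ratio`, and the
#'   truth: either logical `is_af` or a `label` column (`"AF"` = positive).
#' @param grid_count_rr,grid_svd Optional explicit threshold grids.
#' @return A tibble with columns `count_rr_thr`, `svd_ratio_thr`,
#'   `sensitivity`, `specificity`, `distance`; one row per grid pair.
#' @export
#' @examples
#' feats <- rr_features(simulate_cohort(5, seed = 1))
#' roc <- roc_grid(feats)
#' select_thresholds(roc)
roc_grid <- function(features, grid_count_rr = NULL, grid_svd = NULL) {
  stopifnot(all(c("count_rr", "svd_ratio") %in% names(features)))
  is_af <- if ("is_af" %in% names(features)) {
    as.logical(features$is_af)
  } else if ("label" %in% names(features)) {
    features$label == "AF"
  } else {
    stop("features must carry an is_af or label column")
  }
  if (length(unique(is_af)) < 2) {
    stop("degenerate labels: both classes must be present")
  }
  ga <- grid_count_rr %||% sort(unique(c(features$count_rr, Inf)))
  gb <- grid_svd %||% sort(unique(c(features$svd_ratio, Inf)))
  n_pos <- sum(is_af)
  n_neg <- sum(!is_af)
  svd_pos <- sort(features$svd_ratio[is_af])
  svd_neg <- sort(features$svd_ratio[!is_af])
  out <- purrr::map_dfr(ga, function(a) {
    in_a <- features$count_rr <= a
    # counts of records with count_rr <= a and svd_ratio <= b, for all b at once
    tp <- findInterval(gb, sort(features$svd_ratio[is_af & in_a]))
    fp <- findInterval(gb, sort(features$svd_ratio[!is_af & in_a]))
    tibble::tibble(
      count_rr_thr = a, svd_ratio_thr = gb,
      sensitivity = tp / n_pos,
      specificity = (n_neg - fp) / n_neg
    )
  })
  out$distance <- sqrt((1 - out$sensitivity)^2 + (1 - out$specificity)^2)
  out
}

#' Select the threshold pair closest to the perfect ROC corner
#'
#' Picks the grid pair with minimal distance; exact ties are broken toward
#' the smaller `count_rr_thr`, then the smaller `svd_ratio_thr`, so the
#' selection is deterministic.
#'
#' @param roc Output of [roc_grid()].
#' @return The selected one-row tibble.
#' @export
select_thresholds <- function(roc) {
  stopifnot(nrow(roc) >= 1)
  ord <- order(roc$distance, roc$count_rr_thr, roc$svd_ratio_thr)
  roc[ord[1], ]
}

#' Tune step-1 thresholds on a labelled feature set
#'
#' Convenience wrapper: full ROC grid search plus corner-distance selection,
#' returning a ready-to-use [decision_thresholds()] object.
#'
#' @inheritParams roc_grid
#' @param cluster_params Cluster-search geometry carried into the returned
#'   thresholds (the cluster constants are configuration, not tuned).
#' @return A [decision_thresholds()] object with the selected cutoffs, plus
#'   attribute `roc_point` (the selected row).
#' @export
tune_thresholds <- function(features, cluster_params = irregularAF::cluster_params()) {
  best <- select_thresholds(roc_grid(features))
  thr <- decision_thresholds(
    count_rr_max = best$count_rr_thr,
    svd_ratio_max = best$svd_ratio_thr,
    cluster_params = cluster_params
  )
  attr(thr, "roc_point") <- best
  thr
}
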