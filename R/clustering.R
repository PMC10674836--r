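#' Find regular clusters in a Lorenz plot
#'
#' Searches for "regularity within irregularity": well-separated, tight
#' clusters of Lorenz points such as those produced by repetitive premature
#' beats. For k from `k_max` down to 2 a k-means partition (best of
#' `n_restarts` seeded restarts) is computed and accepted as VALID only when
#' \enumerate{
#'   \item every pair of clusters is separated by more than
#'     `min_centroid_distance` (by default the single-linkage gap, the
#'     smallest member-to-member distance between the two clusters - see
#'     [cluster_params()]);
#'   \item every cluster's width (largest member-to-own-centroid distance) is
#'     at most `max_cluster_width`;
#'   \item every cluster has at least `min_cluster_size` members.
#' }
#' The cluster count is the largest valid k, or 1 when no partition is valid.
#' A diffuse AF cloud fails the separation condition for every split, so it
#' reports a single cluster; fewer than 4 points trivially count as one
#' cluster.
#'
#' @param pts Lorenz points ([lorenz()] output, an RR series, or a two-column
#'   matrix).
#' @param params A [cluster_params()] object.
#' @return A `cluster_result`: list with `cluster_count`, `accepted_k`
#'   (`NA` when no k was valid), `centroids` tibble, integer `assignments`,
#'   the `points` analysed, and `params`.
#' @export
#' @examples
#' rr <- simulate_rr("PAC", params = rhythm_params("PAC", ectopy_period = 2), seed = 3)
#' find_clusters(lorenz(rr))$cluster_count
find_clusters <- function(pts, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  m <- lorenz_matrix(pts)
  if (!all(is.finite(m))) stop("non-finite coordinates in Lorenz points")
  n <- nrow(m)
  trivial <- function() {
    new_cluster_result(
      cluster_count = 1L, accepted_k = NA_integer_,
      centroids = tibble::tibble(rr_n = mean(m[, 1]), rr_next = mean(m[, 2])),
      assignments = rep(1L, n), points = m, params = params
    )
  }
  if (n < 4) return(trivial())
  D <- as.matrix(stats::dist(m))
  for (k in seq(params$k_max, 2L)) {
    if (n < k * params$min_cluster_size || nrow(unique(m)) < k) next
    km <- withr::with_seed(
      params$seed,
      suppressWarnings(stats::kmeans(m, centers = k, nstart = params$n_restarts))
    )
    if (partition_valid(m, D, km, params)) {
      return(new_cluster_result(
        cluster_count = as.integer(k), accepted_k = as.integer(k),
        centroids = tibble::tibble(rr_n = km$centers[, 1],
                                   rr_next = km$centers[, 2]),
        assignments = as.integer(km$cluster), points = m, params = params
      ))
    }
  }
  trivial()
}

partition_valid <- function(m, D, km, params) {
  k <- nrow(km$centers)
  groups <- split(seq_len(nrow(m)), km$cluster)
  if (length(groups) < k) return(FALSE)
  for (g in groups) {
    if (length(g) < params$min_cluster_size) return(FALSE)
  }
  for (j in seq_len(k)) {
    g <- groups[[j]]
    width <- max(sqrt((m[g, 1] - km$centers[j, 1])^2 +
                        (m[g, 2] - km$centers[j, 2])^2))
    if (width > params$max_cluster_width) return(FALSE)
  }
  for (a in seq_len(k - 1L)) {
    for (b in seq(a + 1L, k)) {
      sep <- if (params$distance_method == "gap") {
        min(D[groups[[a]], groups[[b]]])
      } else {
        sqrt(sum((km$centers[a, ] - km$centers[b, ])^2))
      }
      if (sep <= params$min_centroid_distance) return(FALSE)
    }
  }
  TRUE
}

new_cluster_result <- function(cluster_count, accepted_k, centroids,
                               assignments, points, params) {
  structure(
    list(cluster_count = cluster_count, accepted_k = accepted_k,
         centroids = centroids, assignments = assignments,
         points = points, params = params),
    class = "cluster_result"
  )
}

#' Per-cluster diagnostic summary
#'
#' @param result A `cluster_result` from [find_clusters()].
#' @param pts Optional Lorenz points; defaults to those stored in `result`.
#' @return A tibble with one row per cluster: `cluster`, `size`, centroid
#'   coordinates, and `width` (max member-to-centroid distance).
#' @export
cluster_report <- function(result, pts = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  m <- if (is.null(pts)) result$points else lorenz_matrix(pts)
  stopifnot("points do not match the assignments" =
              nrow(m) == length(result$assignments))
  purrr::map_dfr(seq_len(result$cluster_count), function(j) {
    g <- which(result$assignments == j)
    cx <- result$centroids$rr_n[j]
    cy <- result$centroids$rr_next[j]
    tibble::tibble(
      cluster = j, size = length(g),
      centroid_rr_n = cx, centroid_rr_next = cy,
      width = max(sqrt((m[g, 1] - cx)^2 + (m[g, 2] - cy)^2))
    )
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", x$cluster_count,
      if (x$cluster_count == 1) "cluster" else "clusters",
      if (is.na(x$accepted_k)) "(no valid k-means partition)" else
        sprintf("(accepted k = %d)", x$accepted_k), "\n")
  invisible(x)
}
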