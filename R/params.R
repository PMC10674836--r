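#' Rhythm generator parameters
#'
#' Bundles the tunable parameters of the synthetic rhythm generator
#' ([simulate_rr()]). Defaults depend on the rhythm class and encode the
#' qualitative RR-interval phenomenology of each rhythm: near-constant
#' intervals with respiratory modulation for sinus rhythm, i.i.d. uniform
#' intervals for AF ("irregularly irregular": no lag structure), a short
#' coupling interval followed by a longer pause for premature complexes,
#' grouped beating with a dropped-beat double interval for AV block, and
#' a bradycardic base with occasional long pauses for sick-sinus syndrome.
#'
#' @param label Rhythm class, one of `rhythm_classes()`.
#' @param mean_rr Mean base RR interval in seconds.
#' @param rr_jitter_sd Gaussian beat-to-beat jitter SD, seconds.
#' @param af_low,af_high Bounds of the uniform AF interval distribution,
#'   seconds; requires `0 < af_low < af_high`.
#' @param coupling_fraction Premature-beat coupling interval as a fraction of
#'   `mean_rr`; must lie in (0, 1).
#' @param pause_fraction Post-ectopic pause as a fraction of `mean_rr`; must
#'   exceed 1. Defaults: 1.25 for PAC (non-compensatory: the premature atrial
#'   beat resets the sinus node) and 1.50 for PVC (full compensatory pause).
#' @param ectopy_period Every `ectopy_period`-th beat is premature (2 =
#'   bigeminy, 3 = trigeminy). Ignored when `ectopy_prob` is given.
#' @param ectopy_prob Optional per-beat probability of a premature beat,
#'   used instead of the fixed period when non-`NULL`.
#' @param wenckebach_ratio Conducted:dropped group size for AV block; a ratio
#'   of `k` yields `k - 1` base intervals followed by one dropped-beat
#'   interval of about twice the base.
#' @param resp_amp,resp_period Amplitude (seconds) and period (seconds) of the
#'   slow sinusoidal respiratory modulation applied to sinus-conducted beats.
#' @param sss_pause_prob Per-beat probability of a sinus pause in SSS.
#' @param sss_pause_range Length-2 numeric, pause duration bounds in seconds
#'   (pauses of at least 2 s are characteristic).
#' @param af_model `"uniform"` (default) or `"gamma"`; the gamma option keeps
#'   the same mean and range-matched spread but adds a right tail.
#' @return A list of class `"rhythm_params"`.
#' @export
#' @examples
#' rhythm_params("AF")
#' rhythm_params("PAC", ectopy_period = 3)
rhythm_params <- function(label = "SINUS",
                          mean_rr = 0.8,
                          rr_jitter_sd = 0.02,
                          af_low = 0.4,
                          af_high = 1.2,
                          coupling_fraction = if (label == "PVC") 0.50 else 0.55,
                          pause_fraction = if (label == "PVC") 1.50 else 1.25,
                          ectopy_period = 3L,
                          ectopy_prob = NULL,
                          wenckebach_ratio = 5L,
                          resp_amp = 0.03,
                          resp_period = 4,
                          sss_pause_prob = 0.04,
                          sss_pause_range = c(2.0, 2.6),
                          af_model = c("uniform", "gamma")) {
  label <- match.arg(label, rhythm_classes())
  af_model <- match.arg(af_model)
  if (label == "SSS" && missing(mean_rr)) mean_rr <- 1.3
  stopifnot(
    "mean_rr must be positive" = is.numeric(mean_rr) && mean_rr > 0,
    "rr_jitter_sd must be non-negative" = rr_jitter_sd >= 0,
    "need 0 < af_low < af_high" = af_low > 0 && af_low < af_high,
    "need 0 < coupling_fraction < 1 < pause_fraction" =
      coupling_fraction > 0 && coupling_fraction < 1 && pause_fraction > 1,
    "ectopy_period must be >= 2" = is.null(ectopy_period) || ectopy_period >= 2,
    "wenckebach_ratio must be >= 2" = wenckebach_ratio >= 2,
    "sss_pause_range must be increasing and >= 2 s" =
      length(sss_pause_range) == 2 && sss_pause_range[1] >= 2 &&
        diff(sss_pause_range) >= 0
  )
  structure(
    list(
      label = label, mean_rr = mean_rr, rr_jitter_sd = rr_jitter_sd,
      af_low = af_low, af_high = af_high,
      coupling_fraction = coupling_fraction, pause_fraction = pause_fraction,
      ectopy_period = if (is.null(ectopy_period)) NULL else as.integer(ectopy_period),
      ectopy_prob = ectopy_prob,
      wenckebach_ratio = as.integer(wenckebach_ratio),
      resp_amp = resp_amp, resp_period = resp_period,
      sss_pause_prob = sss_pause_prob, sss_pause_range = sss_pause_range,
      af_model = af_model
    ),
    class = "rhythm_params"
  )
}

#' Supported rhythm class labels
#'
#' @return Character vector: sinus rhythm (SINUS), atrial fibrillation (AF),
#'   premature atrial/ventricular complexes (PAC/PVC), second/third-degree AV
#'   block with grouped beating (AVB), and sick-sinus bradycardia with pauses
#'   (SSS).
#' @export
rhythm_classes <- function() c("SINUS", "AF", "PAC", "PVC", "AVB", "SSS")

#' Cluster-search parameters
#'
#' Geometry constraints under which a k-means partition of the Lorenz plot is
#' accepted as genuine cluster structure. A candidate partition is valid only
#' if every cluster is tight (width at most `max_cluster_width`), every pair
#' of clusters is separated by more than `min_centroid_distance`, and no
#' cluster is a single stray point. These guards exist to prevent the
#' accidental "detection" of clusters in the diffuse cloud of an irregularly
#' irregular (AF) rhythm.
#'
#' @param min_centroid_distance Minimum between-cluster separation, seconds.
#' @param max_cluster_width Maximum cluster width, seconds; width is the
#'   radius: the largest member-to-own-centroid distance.
#' @param k_max Largest number of clusters tried.
#' @param min_cluster_size Minimum points per cluster (rejects singleton
#'   "clusters" so one aberrant interval cannot veto AF).
#' @param n_restarts Random restarts per k-means fit (best inertia kept).
#' @param seed Integer seed making the k-means search reproducible.
#' @param distance_method How between-cluster separation is measured:
#'   `"gap"` (default) is the single-linkage gap, the smallest
#'   member-to-member distance between two clusters; `"centroid"` is the
#'   distance between centroids. The gap is the strictly stronger condition:
#'   a contiguous cloud split in two always has a near-zero gap even though
#'   its centroids may be far apart, so the gap rule is what keeps AF safe
#'   from false cluster detection (see the methods vignette).
#' @return A list of class `"cluster_params"`.
#' @export
cluster_params <- function(min_centroid_distance = 0.4,
                           max_cluster_width = 0.5,
                           k_max = 4L,
                           min_cluster_size = 2L,
                           n_restarts = 10L,
                           seed = 1L,
                           distance_method = c("gap", "centroid")) {
  distance_method <- match.arg(distance_method)
  stopifnot(
    "min_centroid_distance must be positive" = min_centroid_distance > 0,
    "max_cluster_width must be positive" = max_cluster_width > 0,
    "k_max must be >= 2" = k_max >= 2,
    "min_cluster_size must be >= 1" = min_cluster_size >= 1,
    "n_restarts must be >= 1" = n_restarts >= 1
  )
  structure(
    list(
      min_centroid_distance = min_centroid_distance,
      max_cluster_width = max_cluster_width,
      k_max = as.integer(k_max),
      min_cluster_size = as.integer(min_cluster_size),
      n_restarts = as.integer(n_restarts),
      seed = as.integer(seed),
      distance_method = distance_method
    ),
    class = "cluster_params"
  )
}

#' Decision thresholds of the two-step AF rule
#'
#' A strip is flagged irregular (step 1) when `count_rr <= count_rr_max` and
#' `svd_ratio <= svd_ratio_max` (both comparisons inclusive). A flagged strip
#' is called AF only when the Lorenz-plot cluster search finds exactly
#' `required_cluster_count` cluster(s); finding two or more clusters reveals
#' regularity within the irregularity and vetoes the AF verdict.
#'
#' The validated defaults are `count_rr_max = 0.158` and
#' `svd_ratio_max = 13.31`. An alternative count-RR cutoff of 0.146 arises
#' from tuning with the irregularity step alone; it is retained here as
#' `count_rr_max_step1_only` for reference but the combined-rule value is the
#' default.
#'
#' @param count_rr_max Inclusive upper cutoff on the count-RR statistic.
#' @param svd_ratio_max Inclusive upper cutoff on the Lorenz SVD ratio.
#' @param required_cluster_count Cluster count required for an AF verdict
#'   (default 1: a single diffuse cloud).
#' @param cluster_params A [cluster_params()] object.
#' @return A list of class `"decision_thresholds"`.
#' @export
decision_thresholds <- function(count_rr_max = 0.158,
                                svd_ratio_max = 13.31,
                                required_cluster_count = 1L,
                                cluster_params = irregularAF::cluster_params()) {
  stopifnot(
    "count_rr_max must be positive" = count_rr_max > 0,
    "svd_ratio_max must be positive" = svd_ratio_max > 0,
    "required_cluster_count must be >= 1" = required_cluster_count >= 1,
    "cluster_params must come from cluster_params()" =
      inherits(cluster_params, "cluster_params")
  )
  structure(
    list(
      count_rr_max = count_rr_max,
      svd_ratio_max = svd_ratio_max,
      count_rr_max_step1_only = 0.146,
      required_cluster_count = as.integer(required_cluster_count),
      cluster_params = cluster_params
    ),
    class = "decision_thresholds"
  )
}

#' @export
print.rhythm_params <- function(x, ...) {
  cat("<rhythm_params>", x$label, "\n")
  flds <- x[setdiff(names(x), "label")]
  flds <- flds[!vapply(flds, is.null, logical(1))]
  cat(paste0("  ", names(flds), ": ",
             vapply(flds, function(v) paste(format(v), collapse = ", "),
                    character(1))), sep = "\n")
  invisible(x)
}

#' @export
print.decision_thresholds <- function(x, ...) {
  cat("<decision_thresholds>\n")
  cat("  count_rr <=", x$count_rr_max, " AND  svd_ratio <=", x$svd_ratio_max, "\n")
  cat("  AF iff cluster_count ==", x$required_cluster_count, "\n")
  invisible(x)
}

#' @export
print.cluster_params <- function(x, ...) {
  cat("<cluster_params> separation(", x$distance_method, ") >",
      x$min_centroid_distance, "s, width <=", x$max_cluster_width,
      "s, k <=", x$k_max, "\n")
  invisible(x)
}
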