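# Irregularity features of the two-step AF rule: the count-RR statistic and
# the singular-value ratio of the Lorenz plot.

# accept an RR tibble (rr_seconds column) or a bare numeric vector
rr_intervals <- function(rr) {
  x <- if (is.data.frame(rr)) {
    stopifnot("data frame must have an rr_seconds column" =
                "rr_seconds" %in% names(rr))
    rr$rr_seconds
  } else {
    as.numeric(rr)
  }
  if (!all(is.finite(x)) || any(x <= 0)) {
    stop("RR intervals must be finite and positive")
  }
  x
}

#' Mean heart rate of a strip
#'
#' Defined as `60 / mean(rr)` beats per minute over the detected beats, so a
#' 30-beat, 30-second sinus strip gives 60 bpm.
#'
#' @param rr RR series (tibble with `rr_seconds`, or numeric seconds).
#' @return Beats per minute.
#' @export
heart_rate <- function(rr) {
  x <- rr_intervals(rr)
  if (length(x) < 1) stop("empty RR series")
  60 / mean(x)
}

#' Count-RR irregularity statistic
#'
#' The number of RR intervals equal to the strip's median RR within an
#' inclusive tolerance (15 ms by default), divided by the heart rate. Regular
#' rhythms concentrate their intervals at the median and score high; AF, with
#' no repeating interval, scores low. The tolerance window is absolute, so
#' the statistic is deliberately not scale-invariant.
#'
#' @inheritParams heart_rate
#' @param tolerance Half-width of the match window, seconds.
#' @return Dimensionless value in `[0, n_intervals / heart_rate]`.
#' @export
#' @examples
#' count_rr(rep(1, 30)) # 30 matches / 60 bpm = 0.5
count_rr <- function(rr, tolerance = 0.015) {
  x <- rr_intervals(rr)
  if (length(x) < 5) stop("insufficient intervals: need at least 5")
  matches <- sum(abs(x - stats::median(x)) <= tolerance)
  matches / heart_rate(x)
}

#' Lorenz (Poincare) plot of an RR series
#'
#' The lag-1 embedding: point i is (RR_i, RR_(i+1)). Regular rhythms collapse
#' onto the diagonal, AF forms a diffuse cloud, and repetitive premature
#' beats form discrete off-diagonal clusters.
#'
#' @inheritParams heart_rate
#' @return A tibble of class `lorenz_points` with columns `rr_n`, `rr_next`
#'   (one row fewer than there are intervals, order preserved).
#' @export
lorenz <- function(rr) {
  x <- rr_intervals(rr)
  if (length(x) < 2) stop("need at least 2 intervals for a Lorenz plot")
  out <- tibble::tibble(rr_n = x[-length(x)], rr_next = x[-1])
  class(out) <- c("lorenz_points", class(out))
  out
}

#' Singular-value ratio of the Lorenz plot
#'
#' Ratio s1/s2 of the singular values of the raw (uncentred) n x 2 matrix of
#' Lorenz coordinates. The two singular values measure the extent of the
#' point set along its two principal directions through the origin: a regular
#' rhythm lies on the diagonal far from the origin, so its second singular
#' value collapses and the ratio explodes; an AF cloud is wide in both
#' directions and the ratio stays small. The matrix is deliberately not
#' mean-centred - centring would send regular rhythms toward a ratio of 1
#' and destroy the contrast.
#'
#' @param pts [lorenz()] output, an RR series, or a two-column matrix/data
#'   frame of Lorenz coordinates.
#' @param cap Finite sentinel returned for rank-degenerate (perfectly
#'   regular) inputs, keeping threshold comparisons well-defined.
#' @return Dimensionless ratio, `>= 1` and `<= cap`.
#' @export
#' @examples
#' svd_ratio(lorenz(c(0.8, 1.2, 0.7, 1.1, 0.9, 0.6)))
svd_ratio <- function(pts, cap = 1e6) {
  m <- lorenz_matrix(pts)
  if (nrow(m) < 3) stop("insufficient points: need at least 3 Lorenz points")
  s <- svd(m, nu = 0, nv = 0)$d
  if (s[2] < 1e-12 * s[1]) return(cap)
  min(s[1] / s[2], cap)
}

lorenz_matrix <- function(pts) {
  if (is.matrix(pts) && ncol(pts) == 2) return(pts)
  if (is.data.frame(pts)) {
    if (all(c("rr_n", "rr_next") %in% names(pts))) {
      return(cbind(pts$rr_n, pts$rr_next))
    }
    if ("rr_seconds" %in% names(pts)) {
      lp <- lorenz(pts)
      return(cbind(lp$rr_n, lp$rr_next))
    }
  }
  if (is.numeric(pts)) {
    lp <- lorenz(pts)
    return(cbind(lp$rr_n, lp$rr_next))
  }
  stop("cannot interpret input as Lorenz points")
}

#' Feature vector(s) for one or many RR series
#'
#' Computes `count_rr`, `svd_ratio`, `heart_rate` and `n_intervals`. Given a
#' cohort tibble with list-column `rr` (as from [simulate_cohort()]) or a
#' long RR table with a `record_id` column, one row per record is returned.
#'
#' @param rr An RR series, a cohort tibble with an `rr` list-column, or a
#'   long tibble with `record_id` and `rr_seconds` columns.
#' @param tolerance Passed to [count_rr()].
#' @return A tibble with columns `count_rr`, `svd_ratio`, `heart_rate`,
#'   `n_intervals` (plus `record_id`/`label` when present in the input).
#' @export
#' @examples
#' rr_features(simulate_rr("AF", seed = 1))
rr_features <- function(rr, tolerance = 0.015) {
  one <- function(x) {
    iv <- rr_intervals(x)
    tibble::tibble(
      count_rr = count_rr(iv, tolerance),
      svd_ratio = svd_ratio(iv),
      heart_rate = heart_rate(iv),
      n_intervals = length(iv)
    )
  }
  if (is.data.frame(rr) && "rr" %in% names(rr) && is.list(rr$rr)) {
    keep <- intersect(c("record_id", "label"), names(rr))
    return(dplyr::bind_cols(rr[keep],
                            dplyr::bind_rows(purrr::map(rr$rr, one))))
  }
  if (is.data.frame(rr) && "record_id" %in% names(rr)) {
    split_rr <- split(rr$rr_seconds, rr$record_id)
    out <- dplyr::bind_rows(purrr::map(split_rr, one))
    return(dplyr::bind_cols(tibble::tibble(record_id = names(split_rr)), out))
  }
  one(rr)
}
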