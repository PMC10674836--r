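#' R-peak detector configuration
#'
#' @param threshold_frac Detection threshold as a fraction of the rolling
#'   envelope maximum. The envelope is a squared signal, so the default
#'   0.0625 corresponds to 0.25 of the rolling maximum on the amplitude
#'   scale; anything lower would start admitting in-band T-wave residue,
#'   anything much higher misses wide (low-frequency) ventricular-ectopic
#'   QRS complexes whose energy is attenuated by the 10-40 Hz band.
#' @param rolling_window Window of the rolling envelope maximum, seconds.
#' @param refractory Minimum spacing between peaks, seconds (0.25 s guards
#'   against counting anything above 240 bpm).
#' @param gap_factor Inter-peak gaps longer than `gap_factor` times the
#'   running median RR are re-searched with the threshold halved.
#' @param snap_window Half-width of the raw-signal snap window, seconds.
#' @param band QRS energy band in Hz; wavelet detail levels whose passband
#'   intersects this band are retained.
#' @param min_sampling_rate Smallest supported sampling rate, Hz.
#' @return A list of class `"peak_config"`.
#' @export
peak_config <- function(threshold_frac = 0.0625, rolling_window = 2,
                        refractory = 0.25, gap_factor = 1.5,
                        snap_window = 0.06, band = c(10, 40),
                        min_sampling_rate = 128) {
  stopifnot(threshold_frac > 0, threshold_frac < 1, refractory > 0,
            gap_factor > 1, length(band) == 2, band[1] < band[2])
  structure(list(threshold_frac = threshold_frac,
                 rolling_window = rolling_window, refractory = refractory,
                 gap_factor = gap_factor, snap_window = snap_window,
                 band = band, min_sampling_rate = min_sampling_rate),
            class = "peak_config")
}

# MODWT detail levels whose nominal passband [fs/2^(j+1), fs/2^j] intersects band
qrs_levels <- function(sampling_rate, band = c(10, 40)) {
  j <- 1:12
  lo <- sampling_rate / 2^(j + 1)
  hi <- sampling_rate / 2^j
  j[hi > band[1] & lo < band[2]]
}

#' Wavelet QRS enhancement
#'
#' Computes the MODWT of the signal, keeps only the detail levels whose
#' passband covers the QRS energy band (about 10-40 Hz at the given sampling
#' rate), reconstructs, and squares the result. Baseline wander and T/P-wave
#' energy fall outside the retained levels, so the envelope is large only at
#' QRS complexes. The signal is reflection-padded before the (circular)
#' transform so record edges do not leak across the strip.
#'
#' @param samples Numeric voltage series (mV), or an `ecg_record`.
#' @param sampling_rate Hz; taken from the record if omitted.
#' @param config A [peak_config()].
#' @return Non-negative envelope, same length as the input.
#' @export
enhance_qrs <- function(samples, sampling_rate = NULL, config = peak_config()) {
  if (inherits(samples, "ecg_record")) {
    sampling_rate <- sampling_rate %||% attr(samples, "sampling_rate")
    samples <- samples$mv
  }
  stopifnot("sampling_rate is required" = !is.null(sampling_rate))
  if (sampling_rate < config$min_sampling_rate) {
    stop("sampling_rate below the supported minimum of ",
         config$min_sampling_rate, " Hz")
  }
  if (!all(is.finite(samples))) stop("invalid signal: non-finite samples")
  n <- length(samples)
  if (n < 2 * sampling_rate) stop("too short: need at least 2 s of signal")
  levels <- qrs_levels(sampling_rate, config$band)
  jmax <- max(levels)
  pad <- min(n, 8L * 2L^(jmax - 1L))
  padded <- c(rev(samples[seq_len(pad)]), samples,
              rev(samples[(n - pad + 1L):n]))
  d <- modwt(padded, jmax)
  for (j in seq_len(jmax)) if (!(j %in% levels)) d$W[[j]][] <- 0
  d$V[] <- 0
  rec <- imodwt(d)[(pad + 1L):(pad + n)]
  rec^2
}

# windowed maximum via block maxima of `w` samples: reference at i is the max
# over the block holding i and its two neighbours (window between w and 3w)
block_rolling_max <- function(x, w) {
  n <- length(x)
  b <- ceiling(seq_len(n) / w)
  m <- tapply(x, b, max)
  nb <- length(m)
  ref <- pmax(m, c(m[-1], m[nb]), c(m[1], m[-nb]))
  ref[b]
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# greedy refractory enforcement: among peaks closer than `gap` samples, keep
# the one with the larger envelope value
enforce_refractory <- function(idx, env, gap) {
  if (length(idx) < 2) return(idx)
  idx <- sort(unique(idx))
  keep <- idx[1]
  out <- integer(0)
  for (i in idx[-1]) {
    if (i - keep < gap) {
      if (env[i] > env[keep]) keep <- i
    } else {
      out <- c(out, keep)
      keep <- i
    }
  }
  c(out, keep)
}

#' Detect R-peak times in a single-lead ECG
#'
#' Three-pass detection on the wavelet envelope of [enhance_qrs()]:
#' \enumerate{
#'   \item peaks of the envelope above an adaptive threshold (a fraction of
#'     the rolling envelope maximum), with refractory spacing;
#'   \item within any inter-peak gap longer than `gap_factor` times the
#'     running median RR, re-search with the threshold halved, rescuing
#'     low-amplitude beats;
#'   \item snap each detection to the extremum of `|raw signal|` within the
#'     snap window (polarity-aware).
#' }
#' The adaptive threshold is relative, so detection is invariant to positive
#' rescaling of the signal. A flat or empty-energy record yields zero peaks,
#' not an error.
#'
#' @inheritParams enhance_qrs
#' @return A tibble with columns `time_s` (strictly increasing) and
#'   `confidence` (envelope peak relative to the local rolling maximum, 0-1).
#' @export
#' @examples
#' ecg <- simulate_ecg(simulate_rr("SINUS", seed = 1), sampling_rate = 256, seed = 1)
#' detect_r_peaks(ecg)
detect_r_peaks <- function(samples, sampling_rate = NULL, config = peak_config()) {
  raw <- if (inherits(samples, "ecg_record")) {
    sampling_rate <- sampling_rate %||% attr(samples, "sampling_rate")
    samples$mv
  } else {
    samples
  }
  env <- enhance_qrs(raw, sampling_rate, config)
  fs <- sampling_rate
  n <- length(env)
  w <- max(3L, round(config$rolling_window * fs))
  ref <- block_rolling_max(env, w)
  thr <- config$threshold_frac * ref
  gap_samp <- round(config$refractory * fs)

  # pass 1: thresholded envelope maxima with refractory spacing
  cand <- local_maxima(env)
  cand <- cand[env[cand] > thr[cand] & env[cand] > 0]
  peaks <- enforce_refractory(cand, env, gap_samp)

  # pass 2: halve the threshold inside anomalously long gaps
  if (length(peaks) >= 3) {
    med_rr <- stats::median(diff(peaks))
    bounds <- c(0L, peaks, n + 1L)
    extra <- integer(0)
    for (i in seq_len(length(bounds) - 1L)) {
      lo <- bounds[i]
      hi <- bounds[i + 1L]
      if (hi - lo > config$gap_factor * med_rr) {
        span <- (lo + gap_samp):(hi - gap_samp)
        span <- span[span >= 1 & span <= n]
        if (length(span) < 3) next
        c2 <- local_maxima(env[span]) + span[1] - 1L
        c2 <- c2[env[c2] > thr[c2] / 2 & env[c2] > 0]
        extra <- c(extra, c2)
      }
    }
    peaks <- enforce_refractory(c(peaks, extra), env, gap_samp)
  }

  # pass 3: snap to the raw-signal absolute extremum
  if (length(peaks) > 0) {
    half <- round(config$snap_window * fs)
    peaks <- vapply(peaks, function(i) {
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      lo + which.max(abs(raw[lo:hi])) - 1L
    }, numeric(1))
    peaks <- enforce_refractory(peaks, env, gap_samp)
  }

  tibble::tibble(
    time_s = (peaks - 1L) / fs,
    confidence = if (length(peaks)) pmin(1, env[peaks] / pmax(ref[peaks], 1e-300)) else numeric(0)
  )
}

#' RR intervals from detected peaks
#'
#' @param peaks Tibble from [detect_r_peaks()] (column `time_s`) or a numeric
#'   vector of peak times in seconds.
#' @param duration Optional source-record duration, carried through as an
#'   attribute.
#' @return RR-series tibble (`idx`, `rr_seconds`) with attributes `n_beats`
#'   and `duration`.
#' @export
rr_from_peaks <- function(peaks, duration = NULL) {
  times <- if (is.data.frame(peaks)) peaks$time_s else as.numeric(peaks)
  if (length(times) < 6) {
    stop("insufficient beats: need at least 6 peaks (5 intervals)")
  }
  if (any(diff(times) <= 0)) stop("peak times must be strictly increasing")
  out <- tibble::tibble(idx = seq_len(length(times) - 1L),
                        rr_seconds = diff(times))
  attr(out, "n_beats") <- length(times)
  attr(out, "duration") <- duration
  out
}
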