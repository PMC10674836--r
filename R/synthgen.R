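#' Simulate an RR-interval series for one rhythm class
#'
#' Draws a labelled sequence of RR intervals (seconds) with the beat-to-beat
#' structure of the requested rhythm. The series fills `duration` seconds;
#' the last partial interval is dropped (not truncated) so interval
#' statistics are not biased by an artificial short interval. Unless a
#' sick-sinus pause is generated, all intervals are clamped to the
#' physiological range 0.24-3.0 s.
#'
#' @param label Rhythm class, one of [rhythm_classes()].
#' @param duration Strip duration in seconds; at least 10 s (a smartwatch
#'   strip is 30 s).
#' @param params A [rhythm_params()] object; defaults to the class defaults.
#' @param seed Optional integer seed; when given the draw is reproducible.
#' @return A tibble with columns `idx`, `rr_seconds` and `beat_type`
#'   (`"base"`, `"af"`, `"coupling"`, `"pause"`, `"dropped"` or
#'   `"sss_pause"`), with attributes `label` and `duration`.
#' @export
#' @examples
#' simulate_rr("AF", seed = 1)
#' simulate_rr("PAC", params = rhythm_params("PAC", ectopy_period = 3), seed = 2)
simulate_rr <- function(label, duration = 30,
                        params = rhythm_params(label), seed = NULL) {
  label <- match.arg(label, rhythm_classes())
  stopifnot(inherits(params, "rhythm_params"))
  if (duration < 10) stop("insufficient duration: need at least 10 s")
  draw <- function() gen_rr_intervals(label, duration, params)
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (nrow(out) < 5) stop("insufficient duration: fewer than 5 intervals fit")
  attr(out, "label") <- label
  attr(out, "duration") <- duration
  out
}

# interval engine; assumes RNG state is set by the caller
gen_rr_intervals <- function(label, duration, p) {
  resp <- function(t) p$resp_amp * sin(2 * pi * t / p$resp_period)
  clamp <- function(x) pmin(pmax(x, 0.24), 3.0)
  rr <- numeric(0)
  type <- character(0)
  t <- 0
  ph <- 0L # beat-pattern phase for PAC/PVC/AVB
  repeat {
    if (label == "SINUS") {
      x <- clamp(p$mean_rr + stats::rnorm(1, 0, p$rr_jitter_sd) + resp(t))
      ty <- "base"
    } else if (label == "AF") {
      x <- if (p$af_model == "uniform") {
        stats::runif(1, p$af_low, p$af_high)
      } else {
        # gamma with the same mean and SD as the uniform default
        mu <- (p$af_low + p$af_high) / 2
        sd <- (p$af_high - p$af_low) / sqrt(12)
        clamp(stats::rgamma(1, shape = (mu / sd)^2, rate = mu / sd^2))
      }
      ty <- "af"
    } else if (label %in% c("PAC", "PVC")) {
      pos <- if (is.null(p$ectopy_prob)) {
        per <- p$ectopy_period
        c("coupling", "pause", "base")[
          if (ph %% per == per - 2L) 1L else if (ph %% per == per - 1L) 2L else 3L]
      } else {
        # stochastic ectopy: a coupling interval is always followed by its pause
        if (ph == -1L) "pause"
        else if (stats::runif(1) < p$ectopy_prob) "coupling" else "base"
      }
      base <- p$mean_rr
      x <- switch(pos,
        base     = base + resp(t),
        coupling = p$coupling_fraction * base,
        pause    = p$pause_fraction * base
      ) + stats::rnorm(1, 0, p$rr_jitter_sd)
      x <- clamp(x)
      ty <- pos
      if (!is.null(p$ectopy_prob)) ph <- if (pos == "coupling") -2L else 0L
    } else if (label == "AVB") {
      # grouped beating: (ratio - 1) conducted intervals then a dropped beat
      dropped <- (ph %% p$wenckebach_ratio) == (p$wenckebach_ratio - 1L)
      x <- clamp((if (dropped) 2 else 1) * p$mean_rr +
                   (if (dropped) 0 else resp(t)) +
                   stats::rnorm(1, 0, p$rr_jitter_sd))
      ty <- if (dropped) "dropped" else "base"
    } else { # SSS
      if (stats::runif(1) < p$sss_pause_prob) {
        x <- stats::runif(1, p$sss_pause_range[1], p$sss_pause_range[2])
        ty <- "sss_pause"
      } else {
        x <- clamp(p$mean_rr + stats::rnorm(1, 0, p$rr_jitter_sd) + resp(t))
        ty <- "base"
      }
    }
    if (t + x > duration) break # drop the partial last interval
    rr <- c(rr, x)
    type <- c(type, ty)
    t <- t + x
    ph <- ph + 1L
  }
  tibble::tibble(idx = seq_along(rr), rr_seconds = rr, beat_type = type)
}

# Gaussian-bump morphology templates (times s relative to R, amplitudes mV).
# PVC beats: wide QRS, no P wave, discordant (inverted) T.
beat_template <- function(wide = FALSE, with_p = TRUE) {
  if (wide) {
    list(center = c(-0.05, 0, 0.07, 0.30),
         amp    = c(-0.25, 1.3, -0.45, -0.40),
         sd     = c(0.020, 0.028, 0.025, 0.060),
         qrs_width = 6 * 0.028)
  } else {
    ctr <- c(-0.17, -0.035, 0, 0.03, 0.26)
    amp <- c(0.12, -0.10, 1.0, -0.20, 0.35)
    sd  <- c(0.020, 0.008, 0.011, 0.009, 0.050)
    if (!with_p) { ctr <- ctr[-1]; amp <- amp[-1]; sd <- sd[-1] }
    list(center = ctr, amp = amp, sd = sd, qrs_width = 6 * 0.011)
  }
}

#' Synthesize a sampled single-lead ECG from an RR series
#'
#' Places one beat template (a sum of Gaussian bumps for the P wave, QRS
#' complex and T wave) at each beat time implied by the RR series. Beats of
#' type `"coupling"` in a PVC series receive a wide-QRS, no-P, inverted-T
#' template; AF records receive no P waves at all. Optional additive Gaussian
#' noise and a sinusoidal baseline wander complete the signal. Beat times are
#' offset by half the first interval so no R wave sits on a record edge; the
#' record duration equals the sum of the intervals, so the tail of the final
#' interval is cut by the recording window as in a real strip.
#'
#' @param rr RR series: the tibble from [simulate_rr()] (or any data frame
#'   with an `rr_seconds` column), or a bare numeric vector of seconds.
#' @param sampling_rate Samples per second; at least 128 Hz (a smartwatch
#'   exports 512 Hz).
#' @param noise_sd SD of additive Gaussian noise, mV.
#' @param wander_amp,wander_freq Baseline-wander amplitude (mV) and frequency
#'   (Hz); set `wander_amp = 0` for none.
#' @param label Rhythm class; defaults to the `label` attribute of `rr`.
#' @param seed Optional integer seed for the noise draw.
#' @return An `ecg_record`: a tibble with columns `t_seconds`, `mv` and
#'   attributes `sampling_rate`, `true_r_times`, `label`, `duration`.
#' @export
#' @examples
#' rr <- simulate_rr("SINUS", seed = 1)
#' ecg <- simulate_ecg(rr, sampling_rate = 256, seed = 1)
simulate_ecg <- function(rr, sampling_rate = 512, noise_sd = 0.03,
                         wander_amp = 0.05, wander_freq = 0.3,
                         label = NULL, seed = NULL) {
  if (sampling_rate < 128) stop("sampling_rate must be at least 128 Hz")
  label <- label %||% attr(rr, "label") %||% "SINUS"
  intervals <- rr_intervals(rr)
  types <- if (is.data.frame(rr) && "beat_type" %in% names(rr)) {
    rr$beat_type
  } else {
    rep("base", length(intervals))
  }
  n <- length(intervals)
  tpl_narrow <- beat_template(wide = FALSE, with_p = label != "AF")
  tpl_wide <- beat_template(wide = TRUE)
  if (min(intervals) <= tpl_wide$qrs_width) {
    stop("morphology overlap: template width >= shortest RR interval")
  }
  duration <- sum(intervals)
  n_samples <- round(duration * sampling_rate)
  tt <- (seq_len(n_samples) - 1) / sampling_rate
  # beat i sits at half the first interval plus the preceding intervals
  r_times <- cumsum(c(intervals[1] / 2, intervals[-n]))
  # a premature beat ends its coupling interval, so the beat *after* each
  # coupling interval is the ectopic one
  ectopic <- c(FALSE, types[-n] == "coupling")
  mv <- numeric(n_samples)
  for (i in seq_len(n)) {
    tpl <- if (label == "PVC" && ectopic[i]) tpl_wide else tpl_narrow
    dt <- tt - r_times[i]
    keep <- which(abs(dt) < 0.45)
    for (j in seq_along(tpl$amp)) {
      mv[keep] <- mv[keep] +
        tpl$amp[j] * exp(-0.5 * ((dt[keep] - tpl$center[j]) / tpl$sd[j])^2)
    }
  }
  add_noise <- function(v) {
    if (wander_amp > 0) v <- v + wander_amp * sin(2 * pi * wander_freq * tt)
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    v
  }
  mv <- if (is.null(seed)) add_noise(mv) else withr::with_seed(seed, add_noise(mv))
  out <- tibble::tibble(t_seconds = tt, mv = mv)
  class(out) <- c("ecg_record", class(out))
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "true_r_times") <- r_times
  attr(out, "label") <- label
  attr(out, "duration") <- duration
  out
}

#' Simulate a labelled, class-balanced cohort
#'
#' Generates `n_per_class` records for each rhythm class with per-record seeds
#' derived deterministically from `seed`, so the whole cohort is reproducible.
#' PAC records draw their ectopy period from \{2, 3\} (bigeminy/trigeminy,
#' the repetitive patterns that produce the multi-cluster Lorenz signature);
#' PVC records draw from \{2, 3, 15, 18, 21\} weighted 30:70 toward the
#' sparse periods, mixing repetitive ectopy with the isolated PVCs (one or
#' two per strip) that dominate clinical PVC cohorts and keep most of the
#' Lorenz mass on the diagonal.
#'
#' @param n_per_class Records per rhythm class (>= 1).
#' @param seed Integer cohort seed.
#' @param classes Rhythm classes to include.
#' @param duration Strip duration, seconds.
#' @param ecg If `TRUE`, also synthesize the sampled ECG for each record.
#' @param sampling_rate,noise_sd Passed to [simulate_ecg()] when `ecg = TRUE`.
#' @return A tibble with columns `record_id`, `label`, `seed`, `rr` (list of
#'   RR tibbles) and, when requested, `ecg` (list of `ecg_record`s).
#' @export
#' @examples
#' cohort <- simulate_cohort(2, seed = 7)
#' table(cohort$label)
simulate_cohort <- function(n_per_class, seed, classes = rhythm_classes(),
                            duration = 30, ecg = FALSE,
                            sampling_rate = 512, noise_sd = 0.03) {
  stopifnot("n_per_class must be >= 1" = n_per_class >= 1)
  n_total <- n_per_class * length(classes)
  meta <- withr::with_seed(seed, {
    tibble::tibble(
      record_id = sprintf("rec%04d", seq_len(n_total)),
      label = rep(classes, each = n_per_class),
      seed = sample.int(.Machine$integer.max %/% 2L, n_total),
      pac_period = sample(c(2L, 3L), n_total, replace = TRUE),
      pvc_period = sample(c(2L, 3L, 15L, 18L, 21L), n_total, replace = TRUE,
                          prob = c(0.15, 0.15, 0.24, 0.23, 0.23))
    )
  })
  meta$rr <- purrr::pmap(
    meta[c("label", "seed", "pac_period", "pvc_period")],
    function(label, seed, pac_period, pvc_period) {
      params <- if (label == "PAC") {
        rhythm_params(label, ectopy_period = pac_period)
      } else if (label == "PVC") {
        rhythm_params(label, ectopy_period = pvc_period)
      } else {
        rhythm_params(label)
      }
      simulate_rr(label, duration = duration, params = params, seed = seed)
    }
  )
  if (ecg) {
    meta$ecg <- purrr::pmap(
      meta[c("rr", "label", "seed")],
      function(rr, label, seed) {
        simulate_ecg(rr, sampling_rate = sampling_rate, noise_sd = noise_sd,
                     label = label, seed = seed + 1L)
      }
    )
  }
  meta$pac_period <- NULL
  meta$pvc_period <- NULL
  meta
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %.1f s at %g Hz, %d beats\n",
              attr(x, "label") %||% "?", attr(x, "duration"),
              attr(x, "sampling_rate"), length(attr(x, "true_r_times"))))
  NextMethod()
}
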