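test_that("all-zero input yields an all-zero envelope", {
  env <- enhance_qrs(numeric(2000), sampling_rate = 256)
  expect_true(all(env == 0))
})

test_that("the envelope localizes every R peak of a clean record", {
  rr <- simulate_rr("SINUS", seed = 1)
  ecg <- simulate_ecg(rr, noise_sd = 0, wander_amp = 0)
  env <- enhance_qrs(ecg)
  fs <- attr(ecg, "sampling_rate")
  tr <- attr(ecg, "true_r_times")
  hits <- vapply(tr, function(t) {
    win <- round((t + c(-0.1, 0.1)) * fs) + 1L
    i <- which.max(env[win[1]:win[2]]) + win[1] - 1L
    abs((i - 1) / fs - t) <= 0.020
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("the retained band rejects baseline wander", {
  rr <- simulate_rr("SINUS", seed = 2)
  clean <- simulate_ecg(rr, noise_sd = 0, wander_amp = 0)
  wander <- simulate_ecg(rr, noise_sd = 0, wander_amp = 0.2, wander_freq = 0.3)
  e1 <- enhance_qrs(clean)
  e2 <- enhance_qrs(wander)
  expect_lt(sqrt(mean((e1 - e2)^2)) / sqrt(mean(e1^2)), 0.01)
})

test_that("a clean record yields one accurate peak per beat", {
  rr <- simulate_rr("SINUS", seed = 3)
  ecg <- simulate_ecg(rr, noise_sd = 0, wander_amp = 0)
  pk <- detect_r_peaks(ecg)
  tr <- attr(ecg, "true_r_times")
  expect_equal(nrow(pk), length(tr))
  expect_true(all(vapply(
    tr, function(t) min(abs(pk$time_s - t)) <= 0.020, logical(1))))
  expect_true(all(diff(pk$time_s) >= 0.25))
  expect_true(all(pk$confidence >= 0 & pk$confidence <= 1))
})

test_that("a flat line yields zero peaks, not an error", {
  expect_equal(nrow(detect_r_peaks(numeric(3000), sampling_rate = 256)), 0L)
  expect_error(detect_r_peaks(c(numeric(2999), NA), sampling_rate = 256),
               "invalid signal")
})

test_that("low-amplitude beats are rescued", {
  rr <- rr_tbl(rep(0.9, 32))
  ecg <- simulate_ecg(rr, noise_sd = 0, wander_amp = 0)
  fs <- attr(ecg, "sampling_rate")
  tr <- attr(ecg, "true_r_times")
  for (atten in c(0.5, 0.2)) { # pass 1 catches 0.5; 0.2 needs the gap rescue
    mv <- ecg$mv
    third <- seq(3, length(tr), by = 3)
    for (t in tr[third]) {
      win <- round((t + c(-0.06, 0.06)) * fs) + 1L
      mv[win[1]:win[2]] <- mv[win[1]:win[2]] * atten
    }
    pk <- detect_r_peaks(mv, sampling_rate = fs)
    found <- vapply(tr, function(t) min(abs(pk$time_s - t)) <= 0.020,
                    logical(1))
    expect_true(all(found), label = paste("attenuation", atten))
  }
})

test_that("detection is invariant to amplitude scale and equivariant to time shift", {
  rr <- simulate_rr("SINUS", seed = 4)
  ecg <- simulate_ecg(rr, noise_sd = 0.02, wander_amp = 0, seed = 4)
  fs <- attr(ecg, "sampling_rate")
  base <- detect_r_peaks(ecg)
  scaled <- detect_r_peaks(ecg$mv * 17.3, sampling_rate = fs)
  expect_equal(scaled$time_s, base$time_s)
  k <- round(0.37 * fs)
  shifted <- detect_r_peaks(c(numeric(k), ecg$mv), sampling_rate = fs)
  # interior peaks (1 s from the edges) move by exactly k samples
  interior <- base$time_s > 1 & base$time_s < max(base$time_s) - 1
  expected <- base$time_s[interior] + k / fs
  matched <- vapply(expected,
                    function(t) min(abs(shifted$time_s - t)) <= 1 / fs,
                    logical(1))
  expect_true(all(matched))
})

test_that("rr_from_peaks differences peaks and enforces the beat minimum", {
  rr <- rr_from_peaks(0:30)
  expect_equal(rr$rr_seconds, rep(1, 30))
  expect_equal(attr(rr, "n_beats"), 31L)
  expect_error(rr_from_peaks(seq(0, 4)), "insufficient beats")
})

test_that("detected PAC intervals contain the coupling and pause intervals", {
  p <- rhythm_params("PAC", mean_rr = 0.8, coupling_fraction = 0.65,
                     pause_fraction = 1.35, ectopy_period = 3)
  rr <- simulate_rr("PAC", params = p, seed = 6)
  ecg <- simulate_ecg(rr, noise_sd = 0.02, wander_amp = 0.05, seed = 6)
  detected <- rr_from_peaks(detect_r_peaks(ecg))
  truth <- rr$rr_seconds[-nrow(rr)] # last interval is cut by the window
  expect_equal(nrow(detected), length(truth))
  expect_true(all(abs(detected$rr_seconds - truth) <= 0.020))
})

test_that("beat-level accuracy holds across the default cohort", {
  co <- simulate_cohort(5, seed = 42, ecg = TRUE)
  tallies <- purrr::map2_dfr(co$ecg, co$label, function(ecg, label) {
    pk <- detect_r_peaks(ecg)
    m <- match_beats(pk$time_s, attr(ecg, "true_r_times"))
    tibble::tibble(label = label, tp = m$tp, fn = m$fn, fp = m$fp)
  })
  pvc <- tallies$label == "PVC"
  sens <- function(d) sum(d$tp) / sum(d$tp + d$fn)
  prec <- function(d) sum(d$tp) / sum(d$tp + d$fp)
  expect_gte(sens(tallies[!pvc, ]), 0.99)
  expect_gte(prec(tallies[!pvc, ]), 0.99)
  expect_gte(sens(tallies[pvc, ]), 0.97)
  expect_gte(prec(tallies[pvc, ]), 0.97)
})
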