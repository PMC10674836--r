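test_that("zero-noise sinus rhythm produces exactly constant intervals", {
  p <- rhythm_params("SINUS", mean_rr = 1.0, rr_jitter_sd = 0, resp_amp = 0)
  rr <- simulate_rr("SINUS", duration = 30, params = p, seed = 1)
  expect_equal(nrow(rr), 30L)
  expect_true(all(rr$rr_seconds == 1.0))
})

test_that("AF intervals have no lag-1 structure and stay in their bounds", {
  rr <- simulate_rr("AF", duration = 60,
                    params = rhythm_params("AF", af_low = 0.4, af_high = 1.2),
                    seed = 1)
  x <- rr$rr_seconds
  expect_true(all(x >= 0.4 & x <= 1.2))
  expect_lt(abs(stats::cor(x[-length(x)], x[-1])), 0.15)
})

test_that("PAC trigeminy yields well-separated Lorenz point groups", {
  # default coupling 0.55: the three interval types sit at pairwise
  # distances of at least 0.36 * sqrt(2) > 0.4 s in the Lorenz plane
  p <- rhythm_params("PAC", mean_rr = 0.8, ectopy_period = 3,
                     rr_jitter_sd = 0, resp_amp = 0)
  rr <- simulate_rr("PAC", params = p, seed = 2)
  pts <- lorenz(rr)
  # pairwise-distance oracle: group points greedily at 0.2 s linkage
  m <- cbind(pts$rr_n, pts$rr_next)
  groups <- list()
  for (i in seq_len(nrow(m))) {
    placed <- FALSE
    for (j in seq_along(groups)) {
      if (min(sqrt(colSums((t(m[groups[[j]], , drop = FALSE]) - m[i, ])^2))) < 0.2) {
        groups[[j]] <- c(groups[[j]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) groups <- c(groups, list(i))
  }
  expect_gte(length(groups), 3)
  centers <- t(vapply(groups, function(g) colMeans(m[g, , drop = FALSE]),
                      numeric(2)))
  d <- as.matrix(stats::dist(centers))
  expect_true(all(d[upper.tri(d)] > 0.4))
})

test_that("generated intervals respect physiological bounds", {
  for (label in setdiff(rhythm_classes(), "SSS")) {
    for (s in 1:10) {
      x <- simulate_rr(label, seed = s)$rr_seconds
      expect_true(all(x >= 0.24 & x <= 3.0), label = paste(label, s))
    }
  }
  # SSS pauses are allowed to exceed the ceiling that jitter clamping uses
  x <- simulate_rr("SSS", params = rhythm_params(
    "SSS", sss_pause_prob = 0.2), seed = 3)
  expect_true(any(x$rr_seconds >= 2.0))
})

test_that("frequent ectopy shows every interval type at least twice in 30 s", {
  for (label in c("PAC", "PVC")) {
    for (per in 2:5) {
      rr <- simulate_rr(label, params = rhythm_params(
        label, ectopy_period = per), seed = per)
      counts <- table(rr$beat_type)
      for (ty in c(if (per > 2) "base", "coupling", "pause")) {
        expect_gte(counts[[ty]], 2)
      }
    }
  }
})

test_that("interval generation is deterministic given the seed and errors on short strips", {
  a <- simulate_rr("AF", seed = 9)
  b <- simulate_rr("AF", seed = 9)
  expect_identical(a, b)
  expect_error(simulate_rr("SINUS", duration = 5), "insufficient duration")
})

test_that("stochastic ectopy couples each premature beat to a pause", {
  rr <- simulate_rr("PVC", duration = 60, params = rhythm_params(
    "PVC", ectopy_period = NULL, ectopy_prob = 0.1), seed = 4)
  ty <- rr$beat_type
  after_coupling <- ty[which(ty == "coupling") + 1]
  expect_true(all(after_coupling == "pause", na.rm = TRUE))
})

test_that("sampled ECG has the right length and ground-truth beat count", {
  rr <- rr_tbl(rep(1.0, 30))
  ecg <- simulate_ecg(rr, sampling_rate = 512, noise_sd = 0, wander_amp = 0)
  expect_equal(nrow(ecg), 15360L)
  expect_length(attr(ecg, "true_r_times"), 30L)
  tr <- attr(ecg, "true_r_times")
  expect_true(all(tr >= 0 & tr <= attr(ecg, "duration")))
  expect_true(all(diff(tr) > 0))
})

test_that("noise changes the samples but not the annotations", {
  rr <- simulate_rr("SINUS", seed = 5)
  clean <- simulate_ecg(rr, noise_sd = 0, wander_amp = 0)
  noisy <- simulate_ecg(rr, noise_sd = 0.05, wander_amp = 0, seed = 11)
  expect_identical(attr(clean, "true_r_times"), attr(noisy, "true_r_times"))
  expect_false(identical(clean$mv, noisy$mv))
})

test_that("AF records carry no P wave", {
  rr <- rr_tbl(rep(0.8, 20))
  with_p <- simulate_ecg(rr, noise_sd = 0, wander_amp = 0, label = "SINUS")
  no_p <- simulate_ecg(rr, noise_sd = 0, wander_amp = 0, label = "AF")
  # voltage in the P-wave window before each QRS is flat only without P
  tr <- attr(no_p, "true_r_times")
  fs <- attr(no_p, "sampling_rate")
  p_idx <- round((tr[5] - 0.17) * fs) + 1
  expect_gt(with_p$mv[p_idx], 0.05)
  expect_lt(abs(no_p$mv[p_idx]), 0.02)
})

test_that("overlapping morphology is rejected", {
  expect_error(simulate_ecg(rr_tbl(rep(0.1, 60))), "morphology overlap")
})

test_that("cohorts are balanced, reproducible, and ordered like clinical medians", {
  a <- simulate_cohort(2, seed = 7)
  b <- simulate_cohort(2, seed = 7)
  expect_identical(a, b)
  co <- simulate_cohort(10, seed = 1)
  expect_equal(nrow(co), 60L)
  expect_true(all(table(co$label) == 10))
  feats <- rr_features(simulate_cohort(50, seed = 42))
  med <- tapply(feats$count_rr, feats$label, stats::median)
  expect_lt(med[["AF"]], min(med[setdiff(names(med), "AF")]))
})
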