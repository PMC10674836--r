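test_that("confusion tallies match a brute-force loop", {
  expect_equal(
    unclass(confusion(rep(c("AF", "NOT_AF"), c(10, 10)),
                      rep(c(TRUE, FALSE), c(10, 10))))[c("tp", "fp", "fn", "tn")],
    list(tp = 10L, fp = 0L, fn = 0L, tn = 10L)
  )
  allneg <- confusion(rep("NOT_AF", 8), c(rep(TRUE, 3), rep(FALSE, 5)))
  expect_equal(allneg$tp + allneg$fp, 0L)
  withr::with_seed(5, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      pred <- sample(c("AF", "NOT_AF"), n, replace = TRUE)
      truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
      cm <- confusion(pred, truth)
      tp <- fp <- fn <- tn <- 0L
      for (j in seq_len(n)) {
        p <- pred[j] == "AF"
        if (p && truth[j]) tp <- tp + 1L
        if (p && !truth[j]) fp <- fp + 1L
        if (!p && truth[j]) fn <- fn + 1L
        if (!p && !truth[j]) tn <- tn + 1L
      }
      expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
                   list(tp = tp, fp = fp, fn = fn, tn = tn))
    }
  })
  expect_error(confusion("AF", c(TRUE, FALSE)), "equal length")
})

test_that("inconclusive verdicts are scored as false results", {
  cm <- confusion(c("INCONCLUSIVE", "INCONCLUSIVE"), c(TRUE, FALSE))
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 0L, fp = 1L, fn = 1L, tn = 0L))
})

test_that("metrics are computed exactly from the confusion matrix", {
  m <- metrics_from_cm(confusion_matrix(tp = 26, fp = 9, fn = 3, tn = 106))
  expect_equal(m$sensitivity, 26 / 29)
  expect_equal(m$specificity, 106 / 115)
  expect_equal(m$ppv, 26 / 35)
  expect_equal(m$npv, 106 / 109)
  expect_equal(m$f2, 130 / 151)
  expect_equal(m$accuracy, 132 / 144)
})

test_that("zero-denominator metrics are NA, never 0", {
  m <- metrics_from_cm(confusion_matrix(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_equal(m$specificity, 1)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$ppv))
})

test_that("the F2 identity holds whenever all terms are defined", {
  withr::with_seed(6, {
    for (i in 1:50) {
      cm <- confusion_matrix(tp = sample(1:30, 1), fp = sample(0:30, 1),
                             fn = sample(0:30, 1), tn = sample(1:120, 1))
      m <- metrics_from_cm(cm)
      expect_lt(abs(m$f2 * (4 * m$ppv + m$sensitivity) -
                      5 * m$ppv * m$sensitivity), 1e-12)
    }
  })
})

test_that("metrics are invariant to permuting the record order", {
  withr::with_seed(7, {
    pred <- sample(c("AF", "NOT_AF"), 30, replace = TRUE)
    truth <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    o <- sample(30)
    expect_equal(glance(metrics_from_cm(confusion(pred, truth))),
                 glance(metrics_from_cm(confusion(pred[o], truth[o]))))
  })
})

test_that("McNemar's statistic and p-value follow the discordant counts", {
  r <- mcnemar_test(10, 10)
  expect_equal(r$chi2, 0)
  expect_equal(r$p_value, 1)
  r <- mcnemar_test(25, 8)
  expect_equal(r$chi2, 289 / 33)
  expect_equal(r$p_value, stats::pchisq(289 / 33, 1, lower.tail = FALSE))
  # independent cross-check against the stats implementation
  ref <- stats::mcnemar.test(matrix(c(40, 8, 25, 40), 2, 2), correct = FALSE)
  expect_equal(r$chi2, unname(ref$statistic))
  expect_equal(r$p_value, unname(ref$p.value))
  rc <- mcnemar_test(25, 8, continuity = TRUE)
  expect_equal(rc$chi2, 256 / 33)
  expect_lt(rc$chi2, r$chi2)
  expect_error(mcnemar_test(0, 0), "no discordant pairs")
})

test_that("the chi-square tail agrees with the exact binomial oracle", {
  for (b in 0:30) {
    for (c in 0:30) {
      if (b + c < 10) next
      p_exact <- exact_mcnemar_p(b, c)
      # corrected chi-square approximates the exact test closely
      expect_lt(abs(mcnemar_test(b, c, continuity = TRUE)$p_value - p_exact),
                0.01)
      # uncorrected stays within the approximation's worst-case error,
      # which peaks near b = c where the exact two-sided p saturates at 1
      expect_lt(abs(mcnemar_test(b, c)$p_value - p_exact), 0.24)
    }
  }
})

test_that("continuity correction never lowers the p-value", {
  for (b in seq(0, 50, by = 7)) {
    for (c in seq(1, 50, by = 7)) {
      if (b == c || b + c == 0) next
      expect_gte(mcnemar_test(b, c, continuity = TRUE)$p_value,
                 mcnemar_test(b, c)$p_value)
    }
  }
})

test_that("discordant pairs count records where exactly one test is right", {
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  a <- c("AF", "AF", "NOT_AF", "NOT_AF", "AF", "NOT_AF")
  b <- c("AF", "NOT_AF", "AF", "NOT_AF", "NOT_AF", "INCONCLUSIVE")
  d <- discordant_pairs(a, b, truth)
  # record 2: only A right; record 6: A right, B inconclusive -> wrong
  # record 3: only B right; record 5: only B right
  expect_equal(unname(d), c(2L, 2L))
})
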