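#' Confusion matrix with AF as the positive class
#'
#' Tallies paired predictions against gold-standard truth. Predictions may
#' contain `"INCONCLUSIVE"` (the no-diagnosis verdict of a commercial watch
#' algorithm being scored): with `inconclusive_as_false = TRUE` such records
#' are counted as wrong, i.e. a false negative when the truth is AF and a
#' false positive otherwise. The two-step algorithm itself never emits
#' inconclusive verdicts.
#'
#' @param predictions,truth Character (`"AF"` / `"NOT_AF"`, predictions may
#'   also be `"INCONCLUSIVE"`) or logical vectors of equal length.
#' @param inconclusive_as_false Score inconclusive predictions as false
#'   results (the evaluation-time relabelling rule).
#' @return A `confusion_matrix`: list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion(c("AF", "NOT_AF", "INCONCLUSIVE"), c("AF", "NOT_AF", "AF"))
confusion <- function(predictions, truth, inconclusive_as_false = TRUE) {
  if (length(predictions) != length(truth) || length(truth) < 1) {
    stop("predictions and truth must have equal length >= 1")
  }
  pos_t <- as_af_logical(truth, allow_inconclusive = FALSE)
  if (is.character(predictions) &&
      any(predictions == "INCONCLUSIVE") && !inconclusive_as_false) {
    stop("inconclusive predictions present; set inconclusive_as_false = TRUE")
  }
  inc <- is.character(predictions) & predictions == "INCONCLUSIVE"
  pos_p <- as_af_logical(predictions, allow_inconclusive = TRUE)
  # inconclusive counts as the wrong verdict for that record
  pos_p[inc] <- !pos_t[inc]
  confusion_matrix(
    tp = sum(pos_p & pos_t), fp = sum(pos_p & !pos_t),
    fn = sum(!pos_p & pos_t), tn = sum(!pos_p & !pos_t)
  )
}

as_af_logical <- function(x, allow_inconclusive = FALSE) {
  if (is.logical(x)) return(x)
  ok <- c("AF", "NOT_AF", if (allow_inconclusive) "INCONCLUSIVE")
  if (!all(x %in% ok)) {
    stop("verdicts must be one of: ", paste(ok, collapse = ", "))
  }
  x == "AF"
}

#' Construct a confusion matrix from counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts; at least one record.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot("cell counts must be non-negative integers" =
              all(cells >= 0 & cells == round(cells)),
            "need at least one record" = sum(cells) >= 1)
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
            class = "confusion_matrix")
}

#' Diagnostic-accuracy metrics from a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive value, F2 score
#' and accuracy, as fractions. The F2 score weights sensitivity four times as
#' heavily as PPV: `F2 = 5 * PPV * Se / (4 * PPV + Se)`, equivalently
#' `5 tp / (5 tp + 4 fn + fp)`. A ratio with a zero denominator is reported
#' as `NA`, never as 0.
#'
#' @param cm A `confusion_matrix`.
#' @return A `metrics_report`: list of the six fractions plus the `cm`.
#' @export
#' @examples
#' metrics_from_cm(confusion_matrix(tp = 26, fp = 9, fn = 3, tn = 106))
metrics_from_cm <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  with(cm, structure(
    list(
      sensitivity = frac(tp, tp + fn),
      specificity = frac(tn, tn + fp),
      ppv = frac(tp, tp + fp),
      npv = frac(tn, tn + fn),
      f2 = frac(5 * tp, 5 * tp + 4 * fn + fp),
      accuracy = frac(tp + tn, tp + fp + fn + tn),
      cm = cm
    ),
    class = "metrics_report"
  ))
}

#' McNemar's test on discordant pairs
#'
#' Compares two paired classifiers through the records on which exactly one
#' of them is correct: `b` (first correct, second wrong) and `c` (first
#' wrong, second correct). The statistic `(|b - c| - cc)^2 / (b + c)` (cc = 1
#' with continuity correction, else 0) is referred to the chi-squared
#' distribution with 1 degree of freedom. No correction is applied by
#' default.
#'
#' @param b,c Discordant-pair counts; `b + c` must be at least 1.
#' @param continuity Apply the continuity correction.
#' @return A `mcnemar_result`: list with `b`, `c`, `chi2`, `p_value`,
#'   `continuity_corrected`.
#' @export
#' @examples
#' mcnemar_test(25, 8)
mcnemar_test <- function(b, c, continuity = FALSE) {
  stopifnot(b >= 0, c >= 0, b == round(b), c == round(c))
  if (b + c == 0) stop("no discordant pairs")
  cc <- if (continuity) 1 else 0
  chi2 <- (max(abs(b - c) - cc, 0))^2 / (b + c)
  structure(
    list(b = as.integer(b), c = as.integer(c), chi2 = chi2,
         p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
         continuity_corrected = continuity),
    class = "mcnemar_result"
  )
}

#' Discordant-pair counts of two paired classifiers
#'
#' @param pred_a,pred_b Paired verdict vectors of the two classifiers.
#' @param truth Gold-standard verdicts.
#' @param inconclusive_as_false Passed to the correctness scoring.
#' @return Integer vector `c(b = , c = )`: records where only classifier A,
#'   respectively only classifier B, is correct.
#' @export
discordant_pairs <- function(pred_a, pred_b, truth,
                             inconclusive_as_false = TRUE) {
  correct <- function(p) {
    pos_t <- as_af_logical(truth)
    inc <- is.character(p) & p == "INCONCLUSIVE"
    pos_p <- as_af_logical(p, allow_inconclusive = inconclusive_as_false)
    pos_p[inc] <- !pos_t[inc]
    pos_p == pos_t
  }
  a <- correct(pred_a)
  b <- correct(pred_b)
  c(b = sum(a & !b), c = sum(!a & b))
}

# round half up, matching clinical-report formatting
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (AF positive)\n")
  print(matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
               dimnames = list(pred = c("AF", "NOT_AF"),
                               truth = c("AF", "NOT_AF"))))
  invisible(x)
}

#' @export
print.metrics_report <- function(x, ...) {
  vals <- unlist(x[c("sensitivity", "specificity", "ppv", "npv",
                     "f2", "accuracy")])
  cat("<metrics_report> (percent)\n")
  print(round_half_up(100 * vals, 2))
  invisible(x)
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("<mcnemar_result> b = %d, c = %d, chi2(1) = %.4g, p = %.4g%s\n",
              x$b, x$c, x$chi2, x$p_value,
              if (x$continuity_corrected) " (continuity corrected)" else ""))
  invisible(x)
}
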