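# broom-style tidiers

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.af_decision <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(verdict = x$verdict, step1_irregular = x$step1_irregular,
                   cluster_count = x$cluster_count),
    x$features
  )
}

#' @export
glance.af_decision <- function(x, ...) tidy(x)

#' @export
tidy.cluster_result <- function(x, ...) cluster_report(x)

#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(cluster_count = x$cluster_count, accepted_k = x$accepted_k,
                 n_points = nrow(x$points))
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' @export
tidy.metrics_report <- function(x, ...) {
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "f2", "accuracy")
  tibble::tibble(
    metric = metrics,
    estimate = unlist(x[metrics], use.names = FALSE),
    percent = round_half_up(100 * unlist(x[metrics], use.names = FALSE), 2)
  )
}

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::as_tibble(x[c("sensitivity", "specificity", "ppv", "npv",
                        "f2", "accuracy")])
}

#' @export
tidy.mcnemar_result <- function(x, ...) {
  tibble::tibble(b = x$b, c = x$c, chi2 = x$chi2, p_value = x$p_value,
                 continuity_corrected = x$continuity_corrected)
}

#' @export
glance.mcnemar_result <- function(x, ...) tidy(x)
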