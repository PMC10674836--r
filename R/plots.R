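# ggplot2 visualisations

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Lorenz (Poincare) plot of an RR series
#'
#' @param rr RR series or [lorenz()] output.
#' @param title Optional plot title.
#' @return A ggplot: consecutive-interval pairs with the identity diagonal
#'   along which a perfectly regular rhythm would lie.
#' @export
plot_lorenz <- function(rr, title = NULL) {
  pts <- if (inherits(rr, "lorenz_points")) rr else lorenz(rr)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$rr_n, y = .data$rr_next)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(RR[n] ~ "(s)"),
                  y = expression(RR[n + 1] ~ "(s)"), title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lorenz_points <- function(object, ...) plot_lorenz(object, ...)

#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tibble::tibble(
    rr_n = object$points[, 1], rr_next = object$points[, 2],
    cluster = factor(object$assignments)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rr_n, y = .data$rr_next,
                                        colour = .data$cluster)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(RR[n] ~ "(s)"), y = expression(RR[n + 1] ~ "(s)"),
      title = sprintf("%d cluster%s found", object$cluster_count,
                      if (object$cluster_count == 1) "" else "s")
    ) +
    ggplot2::theme_minimal()
  if (object$cluster_count > 1) {
    p <- p + ggplot2::geom_point(
      data = object$centroids, colour = "black", shape = 4, size = 3,
      inherit.aes = FALSE,
      mapping = ggplot2::aes(x = .data$rr_n, y = .data$rr_next)
    )
  }
  p
}

#' @export
autoplot.ecg_record <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$t_seconds, y = .data$mv)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "voltage (mV)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
  if (!is.null(peaks)) {
    times <- if (is.data.frame(peaks)) peaks$time_s else peaks
    p <- p + ggplot2::geom_vline(xintercept = times, colour = "red",
                                 alpha = 0.4, linetype = "dotted")
  }
  p
}
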