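# Maximal overlap discrete wavelet transform (MODWT) and its inverse,
# pyramid algorithm with circular boundary. Filters are the Daubechies
# least-asymmetric 8-tap pair ("sym4"). Hand-implemented because the
# transform is central to the QRS enhancement step; correctness is pinned by
# perfect-reconstruction and energy-preservation property tests.

sym4_filters <- function() {
  g <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
         0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
         -0.012603967262037833, 0.0322231006040427)
  h <- c(-0.0322231006040427, -0.012603967262037833, 0.09921954357684722,
         0.29785779560527736, -0.8037387518059161, 0.49761866763201545,
         0.02963552764599851, -0.07576571478927333)
  # MODWT uses the DWT filters rescaled by sqrt(2)
  list(g = g / sqrt(2), h = h / sqrt(2))
}

# circular filter with dilation step 2^(j-1); direction +1 analyses, -1 synthesizes
modwt_filt <- function(x, f, step, synth = FALSE) {
  n <- length(x)
  out <- numeric(n)
  idx0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    shift <- step * (l - 1L)
    idx <- if (synth) (idx0 + shift) %% n else (idx0 - shift) %% n
    out <- out + f[l] * x[idx + 1L]
  }
  out
}

#' Maximal overlap discrete wavelet transform
#'
#' Undecimated, shift-invariant wavelet decomposition of a signal into
#' `n_levels` detail series plus a final smooth, each the length of the
#' input, using sym4 filters with circular boundary handling.
#'
#' @param x Numeric signal.
#' @param n_levels Decomposition depth.
#' @return A list with `W` (list of detail vectors, level 1 = finest), `V`
#'   (smooth at the final level) and `n_levels`.
#' @seealso [imodwt()], [enhance_qrs()]
#' @export
modwt <- function(x, n_levels) {
  stopifnot(is.numeric(x), n_levels >= 1)
  flt <- sym4_filters()
  if (length(x) < length(flt$g) * 2^(n_levels - 1)) {
    stop("too short: signal shorter than the level-", n_levels, " filter support")
  }
  W <- vector("list", n_levels)
  V <- x
  for (j in seq_len(n_levels)) {
    step <- 2L^(j - 1L)
    W[[j]] <- modwt_filt(V, flt$h, step)
    V <- modwt_filt(V, flt$g, step)
  }
  list(W = W, V = V, n_levels = n_levels)
}

#' Inverse maximal overlap discrete wavelet transform
#'
#' Reconstructs the signal from a [modwt()] decomposition. Zeroing selected
#' detail levels (or the smooth) before inverting yields a zero-phase
#' band-limited version of the signal.
#'
#' @param d A decomposition from [modwt()].
#' @return Numeric vector, same length as the analysed signal.
#' @export
imodwt <- function(d) {
  flt <- sym4_filters()
  V <- d$V
  for (j in rev(seq_len(d$n_levels))) {
    step <- 2L^(j - 1L)
    V <- modwt_filt(d$W[[j]], flt$h, step, synth = TRUE) +
      modwt_filt(V, flt$g, step, synth = TRUE)
  }
  V
}
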