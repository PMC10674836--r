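# shared fixtures, all generated in code

# an RR tibble from a bare numeric vector
rr_tbl <- function(x) tibble::tibble(idx = seq_along(x), rr_seconds = x)

# beat-level detection tally against ground truth at a time tolerance
match_beats <- function(peak_times, true_times, tol = 0.020) {
  hits <- vapply(true_times,
                 function(t) any(abs(peak_times - t) <= tol), logical(1))
  false_pos <- vapply(peak_times,
                      function(t) all(abs(true_times - t) > tol), logical(1))
  list(tp = sum(hits), fn = sum(!hits), fp = sum(false_pos))
}

# closed-form singular values of an n x 2 matrix via the 2 x 2 Gram matrix
gram_svd_ratio <- function(m) {
  g <- crossprod(m)
  tr <- g[1, 1] + g[2, 2]
  det_g <- g[1, 1] * g[2, 2] - g[1, 2]^2
  lam <- (tr + c(1, -1) * sqrt(max(tr^2 - 4 * det_g, 0))) / 2
  sqrt(lam[1] / lam[2])
}

# exact two-sided binomial test on discordant pairs, X ~ Bin(b + c, 1/2)
exact_mcnemar_p <- function(b, c) {
  n <- b + c
  m <- min(b, c)
  min(1, stats::pbinom(m, n, 0.5) +
        stats::pbinom(n - m - 1, n, 0.5, lower.tail = FALSE))
}
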