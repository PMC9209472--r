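# Independent brute-force oracles used by unit and acceptance tests.

# Mutual information by explicit double sum over a joint count table, with
# its own scalar binning loop (independent of the estimator's vectorized
# tabulate path). Conventions mirror the estimator's definitions: Sturges
# ceiling bin count, equal-width y edges over the data range, top edge
# assigned to the last bin.
mi_oracle <- function(yvals, xbin) {
  n <- length(yvals)
  ny <- ceiling(1 + log2(n))
  lo <- min(yvals); hi <- max(yvals)
  if (lo == hi) return(0)
  edges <- seq(lo, hi, length.out = ny + 1)
  ybin <- integer(n)
  for (t in seq_len(n)) {
    b <- ny
    for (k in seq_len(ny)) {
      if (yvals[t] >= edges[k] && yvals[t] < edges[k + 1]) { b <- k; break }
    }
    ybin[t] <- b
  }
  xs <- sort(unique(xbin)); ys <- sort(unique(ybin))
  total <- 0
  for (xv in xs) {
    for (yv in ys) {
      pxy <- sum(xbin == xv & ybin == yv) / n
      if (pxy > 0) {
        px <- sum(xbin == xv) / n
        py <- sum(ybin == yv) / n
        total <- total + pxy * log2(pxy / (px * py))
      }
    }
  }
  total
}

# Two-sided binomial 95% normal-approximation interval around rate p0.
binom_ci <- function(p0, n) {
  half <- 1.96 * sqrt(p0 * (1 - p0) / n)
  c(p0 - half, p0 + half)
}
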