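# Internal numerical helpers shared across modules.

#' Centered moving average with edge truncation
#'
#' Windows are truncated at the series boundaries, so the output has the same
#' length as the input and interior windows are exact means of `window`
#' consecutive samples. For even window lengths the window extends one sample
#' further into the past than into the future.
#'
#' @param x numeric vector.
#' @param window window length in samples (>= 1).
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n == 0L) {
    return(x)
  }
  hb <- ceiling((window - 1L) / 2)   # samples reaching back
  hf <- floor((window - 1L) / 2)     # samples reaching forward
  s <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - hb, 1L)
  hi <- pmin(i + hf, n)
  (s[hi + 1L] - s[lo]) / (hi - lo + 1L)
}

#' Circularly shift a vector
#'
#' @param x vector.
#' @param k shift in samples; positive shifts move `x[t]` to `x[t + k]`
#'   (wrapping), i.e. the output at time `t` is `x[t - k]`.
#' @return shifted vector, same length.
#' @keywords internal
circular_shift <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[seq_len(n - k)])
}

#' Evenly spaced circular-shift offsets for permutation nulls
#'
#' Offsets are `round(k * n / n_shifts)` for `k = 1..n_shifts`. The final
#' offset equals `n`, i.e. the identity shift, so the observed statistic is a
#' member of its own null; with the strict `>` percentile rule this makes the
#' permutation test exact at the nominal level.
#'
#' @param n series length in samples.
#' @param n_shifts number of shifts (default 100).
#' @return integer vector of offsets, length `n_shifts`.
#' @keywords internal
shift_offsets <- function(n, n_shifts = 100L) {
  if (n < n_shifts) {
    stop("series too short for ", n_shifts, " distinct circular shifts")
  }
  as.integer(round(seq_len(n_shifts) * n / n_shifts))
}

#' Spearman rank correlation
#'
#' Thin wrapper over [stats::cor()] with pairwise-complete observations.
#'
#' @param x,y numeric vectors.
#' @return Spearman correlation coefficient.
#' @keywords internal
spearman <- function(x, y) {
  suppressWarnings(stats::cor(x, y, method = "spearman",
                              use = "pairwise.complete.obs"))
}

#' Derive a reproducible sub-seed
#'
#' All stochastic stages draw sub-seeds from one master seed with this rule so
#' that per-cell or per-iteration randomness is stable under reordering.
#' Results stay inside the 32-bit integer range R requires of seeds.
#'
#' @param seed master seed (integer).
#' @param k stream index (integer >= 0).
#' @return integer sub-seed.
#' @keywords internal
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 30269) %% 2147483629)
}

# Quantile used by every percentile rule in the package (R's default type 7).
pctl <- function(x, p) as.numeric(stats::quantile(x, p, type = 7, names = FALSE, na.rm = TRUE))
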