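#' Detect calcium transient peaks in a df/F trace
#'
#' Local maxima whose topographic prominence is at least `prominence_sd`
#' times a robust noise estimate are reported. The noise scale is
#' `1.4826 x MAD(diff(trace)) / sqrt(2)`, which tracks the additive noise
#' level while staying insensitive to the transients themselves; referencing
#' the raw trace sd instead would raise the bar for exactly the busiest
#' (interneuron-like) cells and undercount their transients. Peak width is
#' measured at half prominence (linear interpolation between samples) and
#' converted to seconds; peak rate is the count divided by the full trace
#' duration; amplitudes are the raw trace values at the maxima.
#'
#' @param trace numeric df/F vector (length >= 3).
#' @param sample_rate_hz sample rate (Hz).
#' @param prominence_sd prominence threshold in robust noise-sd units.
#' @return object of class `peak_stats`: list with `peak_times` (s),
#'   `peak_amplitudes`, `peak_widths` (s), `peak_indices`, `peak_rate`
#'   (peaks/s), `mean_peak_amplitude` (NA with `undefined = TRUE` when no
#'   peaks), `duration_s`.
#' @export
detect_peaks <- function(trace, sample_rate_hz, prominence_sd = 5) {
  n <- length(trace)
  if (n < 3L) stop("trace must have at least 3 samples")
  duration <- n / sample_rate_hz
  d1 <- diff(trace)
  s <- stats::mad(d1) / sqrt(2)
  # noiseless traces (mostly-constant samples) have MAD 0; fall back to the
  # dispersion of the differences so clean synthetic transients still count
  if (s == 0) s <- stats::sd(d1) / sqrt(2)
  empty <- function() {
    structure(list(peak_times = numeric(0), peak_amplitudes = numeric(0),
                   peak_widths = numeric(0), peak_indices = integer(0),
                   peak_rate = 0, mean_peak_amplitude = NA_real_,
                   undefined = TRUE, duration_s = duration),
              class = "peak_stats")
  }
  if (!is.finite(s) || s == 0) return(empty())
  cand <- which(trace[2:(n - 1)] > trace[1:(n - 2)] &
                  trace[2:(n - 1)] >= trace[3:n]) + 1L
  if (!length(cand)) return(empty())
  thr <- prominence_sd * s
  prom <- numeric(length(cand))
  lips <- numeric(length(cand))
  rips <- numeric(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    h <- trace[i]
    # walk out to the first higher sample (or boundary), tracking the valley
    j <- i; lmin <- h
    while (j > 1L && trace[j - 1L] <= h) {
      j <- j - 1L
      if (trace[j] < lmin) lmin <- trace[j]
    }
    j <- i; rmin <- h
    while (j < n && trace[j + 1L] <= h) {
      j <- j + 1L
      if (trace[j] < rmin) rmin <- trace[j]
    }
    prom[k] <- h - max(lmin, rmin)
    if (prom[k] < thr) next
    # half-prominence crossings by linear interpolation
    half <- h - prom[k] / 2
    j <- i
    while (j > 1L && trace[j - 1L] > half && trace[j - 1L] <= h) j <- j - 1L
    lips[k] <- if (j > 1L && trace[j - 1L] <= half) {
      (j - 1L) + (half - trace[j - 1L]) / (trace[j] - trace[j - 1L])
    } else j
    j <- i
    while (j < n && trace[j + 1L] > half && trace[j + 1L] <= h) j <- j + 1L
    rips[k] <- if (j < n && trace[j + 1L] <= half) {
      j + (trace[j] - half) / (trace[j] - trace[j + 1L])
    } else j
  }
  keep <- prom >= thr
  if (!any(keep)) return(empty())
  idx <- cand[keep]
  widths <- pmax((rips[keep] - lips[keep]) / sample_rate_hz,
                 0.5 / sample_rate_hz)
  structure(list(peak_times = (idx - 1L) / sample_rate_hz,
                 peak_amplitudes = trace[idx],
                 peak_widths = widths,
                 peak_indices = idx,
                 peak_rate = length(idx) / duration,
                 mean_peak_amplitude = mean(trace[idx]),
                 undefined = FALSE, duration_s = duration),
            class = "peak_stats")
}

#' Peak-to-noise ratio of a df/F trace
#'
#' Mean peak amplitude divided by a robust noise estimate: 1.4826 x the
#' median absolute deviation of the trace after removing peak windows (each
#' half-prominence interval extended by three widths to cover the transient
#' decay tail).
#'
#' @param trace numeric df/F vector.
#' @param sample_rate_hz sample rate (Hz).
#' @param prominence_sd peak-detection prominence threshold (robust noise-sd
#'   units).
#' @return list with `pnr` (NA and `undefined = TRUE` when the trace has no
#'   peaks; `Inf` with `infinite = TRUE` when the noise estimate is zero),
#'   `noise_sd`, and the underlying `peaks`.
#' @export
peak_to_noise_ratio <- function(trace, sample_rate_hz, prominence_sd = 5) {
  pk <- detect_peaks(trace, sample_rate_hz, prominence_sd)
  if (pk$undefined) {
    return(list(pnr = NA_real_, undefined = TRUE, infinite = FALSE,
                noise_sd = NA_real_, peaks = pk))
  }
  n <- length(trace)
  drop <- rep(FALSE, n)
  for (k in seq_along(pk$peak_indices)) {
    w <- max(1L, ceiling(pk$peak_widths[k] * sample_rate_hz))
    lo <- max(1L, pk$peak_indices[k] - w)
    hi <- min(n, pk$peak_indices[k] + 3L * w)
    drop[lo:hi] <- TRUE
  }
  resid <- trace[!drop]
  noise <- if (length(resid) >= 10L) stats::mad(resid) else stats::mad(trace)
  if (!is.finite(noise) || noise == 0) {
    return(list(pnr = Inf, undefined = FALSE, infinite = TRUE,
                noise_sd = noise, peaks = pk))
  }
  list(pnr = pk$mean_peak_amplitude / noise, undefined = FALSE,
       infinite = FALSE, noise_sd = noise, peaks = pk)
}

#' Per-cell peak statistics table for a session
#'
#' @param session a [session()].
#' @param config an [analysis_config()].
#' @return data.frame with one row per cell: `cell`, `peak_rate`,
#'   `mean_peak_width`, `mean_peak_amplitude`, `pnr`, `n_peaks`.
#' @export
session_peak_stats <- function(session, config = analysis_config()) {
  rate <- session$sample_rate_hz
  rows <- lapply(seq_len(nrow(session$traces)), function(i) {
    pr <- peak_to_noise_ratio(session$traces[i, ], rate,
                              config$peak_prominence_sd)
    pk <- pr$peaks
    data.frame(cell = i, peak_rate = pk$peak_rate,
               mean_peak_width = if (pk$undefined) NA_real_ else mean(pk$peak_widths),
               mean_peak_amplitude = pk$mean_peak_amplitude,
               pnr = pr$pnr, n_peaks = length(pk$peak_indices))
  })
  do.call(rbind, rows)
}
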