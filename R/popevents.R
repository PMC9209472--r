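# Population coactivity events: event extraction stand-in, coactivity
# thresholding, and the speed profile of detected events.

#' Extract binary calcium events from a trace
#'
#' A deliberately simple deconvolution stand-in with the same downstream
#' contract as spike inference (a binary event series): an event is marked at
#' samples where the positive first difference of the trace exceeds
#' `k x 1.4826 x MAD` of the differenced trace; runs of adjacent
#' supra-threshold samples are merged onto their first sample (refractory
#' merge).
#'
#' @param trace df/F vector.
#' @param threshold_sd threshold in robust sd units of the differenced trace.
#' @return logical vector of events, same length as `trace`.
#' @export
deconvolve_events <- function(trace, threshold_sd = 3) {
  if (any(!is.finite(trace))) stop("trace must be finite")
  n <- length(trace)
  ev <- rep(FALSE, n)
  if (n < 2L) return(ev)
  d <- diff(trace)
  s <- stats::mad(d)
  if (!is.finite(s) || s == 0) return(ev)
  hit <- c(FALSE, d > threshold_sd * s)
  first <- hit & !c(FALSE, hit[-n])
  first
}

#' Build the event raster of a session
#'
#' @param session a [session()].
#' @param config an [analysis_config()].
#' @return logical matrix, cells x samples.
#' @export
event_raster <- function(session, config = analysis_config()) {
  t(apply(session$traces, 1L, deconvolve_events,
          threshold_sd = config$event_threshold_sd))
}

#' Detect population coactivity events
#'
#' A population event occupies any sample at which the number of coactive
#' cells exceeds the mean of the coactivity series by `threshold_sd` or more
#' standard deviations. Contiguous supra-threshold samples are merged into a
#' single event (the merged count is primary; the raw supra-threshold sample
#' count is also reported). Only samples outside the excised interval are
#' considered.
#'
#' @param raster logical event matrix (cells x samples) from [event_raster()].
#' @param threshold_sd threshold above the mean coactivity (sd units).
#' @param valid optional logical vector of analyzable samples.
#' @return object of class `population_events`: list with `event_samples`
#'   (first sample of each merged event), `event_runs` (list of sample
#'   ranges), `n_events` (merged), `n_event_samples` (unmerged),
#'   `threshold`, `coactivity`, `participation` (per-cell logical: has an
#'   event within some population-event sample), `flagged_zero_variance`.
#' @export
detect_population_events <- function(raster, threshold_sd = 4, valid = NULL) {
  if (nrow(raster) < 2L) stop("need at least two cells")
  co <- colSums(raster)
  n <- length(co)
  use <- if (is.null(valid)) rep(TRUE, n) else valid
  mu <- mean(co[use])
  sdv <- stats::sd(co[use])
  if (!is.finite(sdv) || sdv == 0) {
    return(structure(list(event_samples = integer(0), event_runs = list(),
                          n_events = 0L, n_event_samples = 0L,
                          threshold = NA_real_, coactivity = co,
                          participation = rep(FALSE, nrow(raster)),
                          flagged_zero_variance = TRUE),
                     class = "population_events"))
  }
  thr <- mu + threshold_sd * sdv
  supra <- co >= thr & use
  idx <- which(supra)
  runs <- list()
  if (length(idx)) {
    brk <- c(0L, which(diff(idx) > 1L), length(idx))
    runs <- lapply(seq_len(length(brk) - 1L), function(k) {
      idx[(brk[k] + 1L):brk[k + 1L]]
    })
  }
  ev_samples <- vapply(runs, `[`, integer(1), 1L)
  all_ev <- unlist(runs)
  participation <- if (length(all_ev)) {
    rowSums(raster[, all_ev, drop = FALSE]) > 0
  } else rep(FALSE, nrow(raster))
  structure(list(event_samples = as.integer(ev_samples), event_runs = runs,
                 n_events = length(runs), n_event_samples = length(idx),
                 threshold = thr, coactivity = co,
                 participation = participation,
                 flagged_zero_variance = FALSE),
            class = "population_events")
}

#' Speed profile of population events
#'
#' Mean running speed during events and the cumulative percentage of events
#' occurring below each speed on a 1 cm/s grid.
#'
#' @param events a [detect_population_events()] result.
#' @param behavior a [behavior_series()].
#' @param grid_cm_s speed grid spacing (cm/s).
#' @return list with `mean_speed` (cm/s), `event_speeds` (one per merged
#'   event, averaged over the event's samples), `grid` and `cumulative_pct`.
#' @export
event_speed_profile <- function(events, behavior, grid_cm_s = 1) {
  if (events$n_events < 1L) stop("no population events to profile")
  sp <- vapply(events$event_runs, function(run) mean(behavior$speed[run]),
               numeric(1))
  grid <- seq(0, ceiling(max(sp)) + grid_cm_s, by = grid_cm_s)
  cum <- vapply(grid, function(g) 100 * mean(sp <= g), numeric(1))
  list(mean_speed = mean(sp), event_speeds = sp, grid = grid,
       cumulative_pct = cum)
}
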