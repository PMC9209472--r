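#' Run the full analysis pipeline
#'
#' Applies the variance cell filter, then runs every stage appropriate to
#' each session's manipulation label: behavioral series, per-cell peak
#' statistics, place-cell classification with field geometry, speed-cell
#' classification, and population-event detection for every session;
#' half-pair remapping analyses (map correlations with chance, rotation
#' thirds, width change) for manipulation sessions; and, when at least two
#' sessions carry footprints on different days, cross-day matching,
#' coregistration validation, turnover, and stability. All randomness derives
#' from `config$rng_seed`, so identical inputs and seed give identical
#' outputs; when `out_dir` is given, per-cell tables (CSV), a
#' machine-readable `summary.json`, and a log with the config echo are
#' written without timestamps, making repeat runs byte-identical.
#'
#' @param sessions a [session()] or list of sessions.
#' @param config an [analysis_config()].
#' @param out_dir optional output directory.
#' @param decode logical; run speed decoding per session (needs at least
#'   `decode_n_subsample` cells after filtering).
#' @param decode_n_subsample cells per decoding subset.
#' @return report list (per-session results and cross-day tables), invisibly
#'   when writing, visibly otherwise.
#' @export
run_pipeline <- function(sessions, config = analysis_config(), out_dir = NULL,
                         decode = FALSE, decode_n_subsample = 32L) {
  if (inherits(sessions, "session")) sessions <- list(sessions)
  report <- list(config = unclass(config), sessions = list())
  for (s in sessions) {
    id <- s$meta$session_id
    filt <- filter_cells(s$traces)
    sf <- subset_cells(s, filt$kept)
    beh <- behavior_series(sf, config)
    peaks <- session_peak_stats(sf, config)
    raster <- event_raster(sf, config)
    pop <- detect_population_events(raster, config$popevent_threshold_sd,
                                    valid_samples(sf))
    res <- list(session_id = id, manipulation = sf$meta$manipulation,
                n_cells_recorded = nrow(s$traces),
                n_cells_kept = length(filt$kept),
                kept_indices = filt$kept,
                path_length_cm = beh$path_length_cm,
                peaks = peaks,
                popevents = list(n_events = pop$n_events,
                                 n_event_samples = pop$n_event_samples,
                                 threshold = pop$threshold,
                                 participation_fraction = mean(pop$participation)))
    if (sf$meta$manipulation == "none") {
      pa <- session_place_analysis(sf, beh, config)
      sc <- classify_speed_cells(sf, beh, config)
      res$place <- pa$cells
      res$speed <- as.data.frame(sc)
      res$place_fraction <- mean(isTRUE_vec(pa$cells$is_place))
      if (pop$n_events >= 1L) {
        res$popevents$mean_event_speed <- event_speed_profile(pop, beh)$mean_speed
      }
      res$.analysis <- pa
    } else {
      hp <- analyze_half_pair(sf, config)
      res$half_pair <- hp$cells
      res$chance_threshold <- hp$chance_threshold
      res$rotate_fraction <- hp$rotate_fraction
      res$non_rotate_fraction <- hp$non_rotate_fraction
      wc <- field_width_change(hp)
      res$median_width_change_cm <- if (nrow(wc)) {
        stats::median(wc$width_change_cm)
      } else NA_real_
    }
    if (decode && nrow(sf$traces) >= decode_n_subsample &&
        sf$meta$manipulation == "none") {
      dec <- decode_speed(sf, decode_n_subsample, beh, config)
      res$decoding <- list(mean_r = dec$mean_r,
                           chance_threshold = dec$chance_threshold)
    }
    report$sessions[[id]] <- res
  }
  # cross-day analyses over consecutive sessions with footprints
  with_fp <- which(vapply(sessions, function(s) !is.null(s$footprints),
                          logical(1)))
  if (length(with_fp) >= 2L) {
    days <- vapply(sessions[with_fp], function(s) s$meta$day, numeric(1))
    ord <- with_fp[order(days)]
    cross <- list()
    for (k in seq_len(length(ord) - 1L)) {
      si <- sessions[[ord[k]]]; sj <- sessions[[ord[k + 1L]]]
      m <- match_cells(si$footprints, sj$footprints, config)
      tv <- turnover_fraction(m)
      cv <- coregistration_validation(si, sj, m, config)
      ai <- report$sessions[[si$meta$session_id]]$.analysis
      aj <- report$sessions[[sj$meta$session_id]]$.analysis
      st <- across_day_stability(si, sj, m, config,
                                 analysis_i = ai, analysis_j = aj)
      cross[[paste0(si$meta$session_id, "_vs_", sj$meta$session_id)]] <-
        list(n_matched = tv$n_matched, turnover_fraction = tv$fraction,
             amplitude_r = cv$amplitude$r, amplitude_chance = cv$amplitude$chance,
             pnr_r = cv$pnr$r,
             map_r_mean = st$map_r_mean, mi_r = st$mi$r,
             speed_r = st$speed$r, speed_chance = st$speed$chance)
    }
    report$cross_day <- cross
  }
  for (id in names(report$sessions)) report$sessions[[id]]$.analysis <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(report$sessions)) {
      res <- report$sessions[[id]]
      for (tab in c("place", "speed", "half_pair", "peaks")) {
        if (!is.null(res[[tab]])) {
          utils::write.csv(res[[tab]],
                           file.path(out_dir, paste0(id, "_", tab, ".csv")),
                           row.names = FALSE)
        }
      }
    }
    slim <- report
    for (id in names(slim$sessions)) {
      slim$sessions[[id]]$place <- NULL
      slim$sessions[[id]]$speed <- NULL
      slim$sessions[[id]]$half_pair <- NULL
      slim$sessions[[id]]$peaks <- NULL
    }
    jsonlite::write_json(slim, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    writeLines(c("placecode pipeline log",
                 paste0("seed: ", config$rng_seed),
                 "config:",
                 paste0("  ", names(unclass(config)), " = ",
                        vapply(unclass(config), function(v)
                          paste(format(v), collapse = ","), character(1)))),
               file.path(out_dir, "log.txt"))
    return(invisible(report))
  }
  report
}
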