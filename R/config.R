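#' Analysis configuration
#'
#' Collects every fixed constant used by the analysis stages. Defaults follow
#' the acquisition and analysis conventions of miniscope linear-track
#' experiments: 30 Hz behavioral video averaged onto a 7.5 Hz neural timebase,
#' a 3 cm/s translational-movement threshold applied jointly to nose and
#' tailbase speed, 3.5 cm spatial bins, a 5 x 5-bin Gaussian map-smoothing
#' kernel with sd 0.85 bins (2.98 cm), 100-shift circular permutation nulls
#' for place and speed statistics, 1000 shifts for map-correlation chance,
#' a 1.5-sd place-field threshold, a 4-sd population-event threshold, and
#' 60 s decoding blocks separated by 10 s guards.
#'
#' @param speed_threshold_cm_s movement threshold (cm/s), strict `>`.
#' @param pose_smooth_window_s moving-average window for pose and speed (s).
#' @param spatial_bin_cm spatial bin side (cm).
#' @param map_smooth_size Gaussian kernel size (bins, odd).
#' @param map_smooth_sd Gaussian kernel sd (bins).
#' @param n_shuffles_place circular shifts for the place-cell null.
#' @param n_shuffles_speed circular shifts for the speed-cell null.
#' @param n_shuffles_mapcorr iterations for map-correlation chance.
#' @param field_threshold_sd place-field threshold above the map mean (sd units).
#' @param popevent_threshold_sd population-event threshold above the mean
#'   coactivity (sd units).
#' @param event_threshold_sd transient-onset threshold for the event
#'   deconvolution stand-in (robust sd units of the differenced trace).
#' @param peak_prominence_sd peak-detection prominence (robust noise-sd
#'   units; see [detect_peaks()]).
#' @param decode_block_s training/testing block length (s).
#' @param decode_guard_s guard interval between blocks (s).
#' @param decode_n_iter cell-subsample iterations for decoding.
#' @param decode_n_iter_chance subsample iterations per chance permutation.
#' @param percentile percentile for all significance thresholds (0-100).
#' @param match_min_iou minimum footprint intersection-over-union to accept a
#'   cross-day match.
#' @param match_max_dist_px maximum centroid distance (px) to accept a match.
#' @param rng_seed master seed for all stochastic stages.
#' @return object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(speed_threshold_cm_s = 3,
                            pose_smooth_window_s = 0.5,
                            spatial_bin_cm = 3.5,
                            map_smooth_size = 5L,
                            map_smooth_sd = 0.85,
                            n_shuffles_place = 100L,
                            n_shuffles_speed = 100L,
                            n_shuffles_mapcorr = 1000L,
                            field_threshold_sd = 1.5,
                            popevent_threshold_sd = 4,
                            event_threshold_sd = 3,
                            peak_prominence_sd = 5,
                            decode_block_s = 60,
                            decode_guard_s = 10,
                            decode_n_iter = 100L,
                            decode_n_iter_chance = 1L,
                            percentile = 95,
                            match_min_iou = 0.3,
                            match_max_dist_px = 8,
                            rng_seed = 1L) {
  cfg <- list(
    speed_threshold_cm_s = speed_threshold_cm_s,
    pose_smooth_window_s = pose_smooth_window_s,
    spatial_bin_cm = spatial_bin_cm,
    map_smooth_size = as.integer(map_smooth_size),
    map_smooth_sd = map_smooth_sd,
    n_shuffles_place = as.integer(n_shuffles_place),
    n_shuffles_speed = as.integer(n_shuffles_speed),
    n_shuffles_mapcorr = as.integer(n_shuffles_mapcorr),
    field_threshold_sd = field_threshold_sd,
    popevent_threshold_sd = popevent_threshold_sd,
    event_threshold_sd = event_threshold_sd,
    peak_prominence_sd = peak_prominence_sd,
    decode_block_s = decode_block_s,
    decode_guard_s = decode_guard_s,
    decode_n_iter = as.integer(decode_n_iter),
    decode_n_iter_chance = as.integer(decode_n_iter_chance),
    percentile = percentile,
    match_min_iou = match_min_iou,
    match_max_dist_px = match_max_dist_px,
    rng_seed = as.integer(rng_seed)
  )
  counts <- c("map_smooth_size", "n_shuffles_place", "n_shuffles_speed",
              "n_shuffles_mapcorr", "decode_n_iter", "decode_n_iter_chance")
  for (nm in counts) {
    if (cfg[[nm]] < 1L) stop("config field '", nm, "' must be a positive integer")
  }
  if (percentile <= 0 || percentile >= 100) stop("percentile must lie in (0, 100)")
  if (speed_threshold_cm_s < 0) stop("speed threshold must be non-negative")
  structure(cfg, class = "analysis_config")
}

# Per-archetype generator defaults. Baseline transient rates and the two decay
# regimes reproduce the characteristic ordering of pyramidal (CAMK2A-like,
# sparse, fast transients) versus interneuron (VGAT-like, dense, slow
# transients) calcium activity; the tuned fractions follow the proportions
# typically reported for CA1 populations of each type.
.archetypes <- list(
  CAMK2A = list(baseline_rate = 0.11, decay_s = 1.0,
                fraction_place_cells = 0.51,
                fraction_speed_pos = 0.138, fraction_speed_neg = 0.324,
                p_survive = 0.47, p_place_stable_day = 0.9,
                popevent_speed_regime = "low"),
  VGAT   = list(baseline_rate = 0.17, decay_s = 1.9,
                fraction_place_cells = 0.27,
                fraction_speed_pos = 0.338, fraction_speed_neg = 0.146,
                p_survive = 0.17, p_place_stable_day = 0.2,
                popevent_speed_regime = "high")
)

#' Simulation configuration
#'
#' Parameters of the synthetic-session generator. Archetype-dependent defaults
#' (baseline transient rate, transient decay, tuned-cell fractions, across-day
#' survival) are filled in from the `cell_type` argument when not supplied
#' explicitly; pass a value to override.
#'
#' @param n_cells number of cells.
#' @param cell_type archetype, `"CAMK2A"` (sparse pyramidal-like) or `"VGAT"`
#'   (dense interneuron-like).
#' @param track_length_cm enclosure length (cm).
#' @param track_width_cm enclosure width (cm).
#' @param duration_s session duration (s).
#' @param sample_rate_hz neural sample rate (Hz).
#' @param baseline_rate baseline transient rate (peaks/s); archetype default.
#' @param decay_s transient exponential decay constant (s); archetype default.
#' @param fraction_place_cells fraction of cells given a place field.
#' @param field_width_range_cm range of the Gaussian place-tuning sd (cm);
#'   widths are drawn uniformly from this interval.
#' @param place_gain peak multiplicative rate gain at the field center.
#' @param place_floor out-of-field rate gain for place cells (fraction of
#'   baseline); place cells fire predominantly in-field, so the floor is low.
#' @param fraction_speed_pos,fraction_speed_neg fractions of positively /
#'   negatively speed-tuned cells.
#' @param speed_slope magnitude of the linear speed gain per 10 cm/s.
#' @param p_rotate,p_stable probabilities that a place cell mirrors / keeps its
#'   field across a mid-session manipulation (remainder: field redrawn).
#' @param rescale_mode `"scale_with_track"` (centers and widths follow the
#'   length ratio) or `"fixed"`.
#' @param gap_s samples excised around a mid-session manipulation (s).
#' @param p_survive probability a cell remains active on the next day.
#' @param p_place_stable_day probability a surviving place cell keeps its field
#'   across days (otherwise redrawn).
#' @param amp_rho across-day persistence (correlation on the log scale) of a
#'   surviving cell's mean transient amplitude.
#' @param footprint_jitter_px across-day centroid jitter of footprints (px).
#' @param n_popevents synchronous population events injected per session
#'   (0 disables injection).
#' @param popevent_participation fraction of cells participating in population
#'   events.
#' @param popevent_speed_regime `"low"` or `"high"`: speed range targeted by
#'   injected events; archetype default.
#' @param amp_meanlog,amp_sdlog log-normal parameters of per-cell mean
#'   transient amplitude (df/F).
#' @param noise_sd additive Gaussian trace noise (df/F).
#' @param rng_seed master seed.
#' @return object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_cells = 100L,
                       cell_type = c("CAMK2A", "VGAT"),
                       track_length_cm = 70,
                       track_width_cm = 9,
                       duration_s = 1200,
                       sample_rate_hz = 7.5,
                       baseline_rate = NULL,
                       decay_s = NULL,
                       fraction_place_cells = NULL,
                       field_width_range_cm = c(4, 8),
                       place_gain = 6,
                       place_floor = 0.15,
                       fraction_speed_pos = NULL,
                       fraction_speed_neg = NULL,
                       speed_slope = 0.8,
                       p_rotate = 0.5,
                       p_stable = 0.5,
                       rescale_mode = c("scale_with_track", "fixed"),
                       gap_s = 22,
                       p_survive = NULL,
                       p_place_stable_day = NULL,
                       amp_rho = 0.8,
                       footprint_jitter_px = 2,
                       n_popevents = 0L,
                       popevent_participation = 0.6,
                       popevent_speed_regime = NULL,
                       amp_meanlog = 0,
                       amp_sdlog = 0.4,
                       noise_sd = 0.1,
                       rng_seed = 1L) {
  cell_type <- match.arg(cell_type)
  arch <- .archetypes[[cell_type]]
  pick <- function(x, nm) if (is.null(x)) arch[[nm]] else x
  cfg <- list(
    n_cells = as.integer(n_cells),
    cell_type = cell_type,
    track_length_cm = track_length_cm,
    track_width_cm = track_width_cm,
    duration_s = duration_s,
    sample_rate_hz = sample_rate_hz,
    baseline_rate = pick(baseline_rate, "baseline_rate"),
    decay_s = pick(decay_s, "decay_s"),
    fraction_place_cells = pick(fraction_place_cells, "fraction_place_cells"),
    field_width_range_cm = field_width_range_cm,
    place_gain = place_gain,
    place_floor = place_floor,
    fraction_speed_pos = pick(fraction_speed_pos, "fraction_speed_pos"),
    fraction_speed_neg = pick(fraction_speed_neg, "fraction_speed_neg"),
    speed_slope = speed_slope,
    p_rotate = p_rotate,
    p_stable = p_stable,
    rescale_mode = match.arg(rescale_mode),
    gap_s = gap_s,
    p_survive = pick(p_survive, "p_survive"),
    p_place_stable_day = pick(p_place_stable_day, "p_place_stable_day"),
    amp_rho = amp_rho,
    footprint_jitter_px = footprint_jitter_px,
    n_popevents = as.integer(n_popevents),
    popevent_participation = popevent_participation,
    popevent_speed_regime = pick(popevent_speed_regime, "popevent_speed_regime"),
    amp_meanlog = amp_meanlog,
    amp_sdlog = amp_sdlog,
    noise_sd = noise_sd,
    rng_seed = as.integer(rng_seed)
  )
  fr <- c(cfg$fraction_place_cells, cfg$fraction_speed_pos,
          cfg$fraction_speed_neg, cfg$popevent_participation,
          cfg$p_survive, cfg$p_place_stable_day)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$p_rotate + cfg$p_stable > 1 + 1e-12) stop("p_rotate + p_stable must be <= 1")
  if (cfg$baseline_rate <= 0) stop("baseline_rate must be positive")
  if (cfg$duration_s <= 0 || cfg$sample_rate_hz <= 0) {
    stop("duration and sample rate must be positive")
  }
  if (cfg$fraction_speed_pos + cfg$fraction_speed_neg > 1) {
    stop("speed-tuned fractions exceed 1")
  }
  structure(cfg, class = "sim_config")
}
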