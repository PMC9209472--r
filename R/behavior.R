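#' Smooth pose coordinates with a centered moving average
#'
#' Positions are averaged over a window of `window_s` seconds. At 7.5 Hz a
#' 0.5 s window corresponds to 3.75 samples; the nearest integer window (4
#' samples, about 0.53 s) is used. Windows are truncated at the series edges,
#' so output length equals input length.
#'
#' @param pose data.frame of xy columns (any subset of the pose columns).
#' @param window_s window length (s).
#' @param sample_rate_hz sample rate (Hz).
#' @return data.frame of the same shape with smoothed columns.
#' @export
smooth_pose <- function(pose, window_s, sample_rate_hz) {
  if (window_s <= 0) stop("window_s must be positive")
  w <- as.integer(round(window_s * sample_rate_hz))
  if (w < 2L) {
    warning("smoothing window shorter than one sample; returning pose unchanged")
    return(pose)
  }
  as.data.frame(lapply(pose, moving_average, window = w))
}

#' Instantaneous speed from smoothed coordinates
#'
#' Speed at sample t is the Euclidean step distance from sample t-1 times the
#' sample rate; the first sample copies the second. The speed series is then
#' smoothed with the same moving-average window as the pose.
#'
#' @param x,y smoothed coordinates (cm).
#' @param sample_rate_hz sample rate (Hz).
#' @param window_s smoothing window (s); 0 disables speed smoothing.
#' @return speed vector (cm/s), same length as `x`.
#' @export
compute_speed <- function(x, y, sample_rate_hz, window_s = 0.5) {
  if (length(x) < 2L) stop("need at least two samples to compute speed")
  step <- sqrt(diff(x)^2 + diff(y)^2) * sample_rate_hz
  sp <- c(step[1], step)
  if (window_s > 0) {
    w <- as.integer(round(window_s * sample_rate_hz))
    if (w >= 2L) sp <- moving_average(sp, w)
  }
  sp
}

#' Behavioral series for a session
#'
#' Smooths the pose, computes per-body-point speeds, builds the
#' translational-movement mask (nose AND tailbase speed strictly above the
#' threshold, excised samples forced FALSE), and accumulates path length from
#' the tailbase point, which is also the position used for all spatial
#' analyses.
#'
#' @param session a [session()].
#' @param config an [analysis_config()].
#' @return object of class `behavior_series`: list with smoothed `x`, `y`
#'   (tailbase, cm), `speed` (tailbase, cm/s), `nose_speed`, `tail_speed`,
#'   `movement_mask`, `valid` (non-excised samples), `path_length_cm`, and the
#'   session sample rate.
#' @export
behavior_series <- function(session, config = analysis_config()) {
  rate <- session$sample_rate_hz
  sm <- smooth_pose(session$pose, config$pose_smooth_window_s, rate)
  nose_speed <- compute_speed(sm$nose_x, sm$nose_y, rate, config$pose_smooth_window_s)
  tail_speed <- compute_speed(sm$tail_x, sm$tail_y, rate, config$pose_smooth_window_s)
  valid <- valid_samples(session)
  mask <- movement_mask(nose_speed, tail_speed, config$speed_threshold_cm_s, valid)
  path <- sum(sqrt(diff(sm$tail_x)^2 + diff(sm$tail_y)^2)[valid[-1] & valid[-length(valid)]])
  structure(list(x = sm$tail_x, y = sm$tail_y, speed = tail_speed,
                 nose_speed = nose_speed, tail_speed = tail_speed,
                 movement_mask = mask, valid = valid,
                 path_length_cm = path, sample_rate_hz = rate),
            class = "behavior_series")
}

#' Translational-movement mask
#'
#' TRUE where both nose and tailbase speed strictly exceed the threshold;
#' boundary ties are excluded. Samples flagged invalid (the excised
#' manipulation window) are forced FALSE.
#'
#' @param nose_speed,tail_speed speed vectors (cm/s).
#' @param threshold_cm_s movement threshold (cm/s).
#' @param valid optional logical vector of analyzable samples.
#' @return logical vector.
#' @export
movement_mask <- function(nose_speed, tail_speed, threshold_cm_s = 3,
                          valid = NULL) {
  if (is.null(nose_speed)) stop("missing body point: nose")
  if (is.null(tail_speed)) stop("missing body point: tailbase")
  m <- nose_speed > threshold_cm_s & tail_speed > threshold_cm_s
  if (!is.null(valid)) m <- m & valid
  m
}
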