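# Within-session manipulation analyses: flattened-map correlations with
# rescaling, rotation thirds classification, and place-field width change.

#' Flatten a 2-D activity map to a 1-D track profile
#'
#' Takes the maximum over occupied bins in each column (position along the
#' track), so a 3 x 20 map becomes a length-20 vector. Columns with no
#' occupied bin are NA and are excluded pairwise from correlations.
#'
#' @param map an [compute_activity_map()] result.
#' @return numeric vector, one value per position bin along the track.
#' @export
flatten_map <- function(map) {
  apply(map$map, 2L, function(col) {
    v <- col[!is.na(col)]
    if (length(v)) max(v) else NA_real_
  })
}

#' Correlate two flattened map profiles
#'
#' When the profiles have different lengths (rescaled enclosures), the second
#' is resampled onto the first's grid by linear interpolation at matched
#' relative positions. Returns the Spearman correlation over
#' pairwise-complete bins.
#'
#' @param profile1,profile2 numeric profiles from [flatten_map()].
#' @return Spearman r, or NA (flagged via attribute `undefined`) when fewer
#'   than 3 complete bin pairs exist.
#' @export
rate_map_correlation <- function(profile1, profile2) {
  if (!length(profile1) || !length(profile2)) stop("profiles must be nonempty")
  p2 <- resample_profile(profile2, length(profile1))
  ok <- !is.na(profile1) & !is.na(p2)
  if (sum(ok) < 3L) {
    r <- NA_real_
    attr(r, "undefined") <- TRUE
    return(r)
  }
  spearman(profile1[ok], p2[ok])
}

#' Linearly resample a profile to a target length
#'
#' Interpolates at matched relative positions along the track, so a profile
#' from a rescaled enclosure is compared bin-for-bin with its partner.
#'
#' @param profile numeric vector.
#' @param n_out target length.
#' @return resampled numeric vector of length `n_out`.
#' @export
resample_profile <- function(profile, n_out) {
  n_in <- length(profile)
  if (n_in == n_out) return(profile)
  pos_in <- seq(0, 1, length.out = n_in)
  pos_out <- seq(0, 1, length.out = n_out)
  ok <- !is.na(profile)
  if (sum(ok) < 2L) return(rep(NA_real_, n_out))
  out <- stats::approx(pos_in[ok], profile[ok], xout = pos_out, rule = 2)$y
  out
}

#' Chance level for half-pair map correlations
#'
#' Concatenates all cells; per iteration, every (resampled) second-half
#' profile is circularly shifted by a shared seeded offset and all
#' pairwise-matched correlations are recomputed. The threshold is the 95th
#' percentile of the pooled null.
#'
#' @param profiles1 list of first-half profiles.
#' @param profiles2 list of second-half profiles (matched by cell).
#' @param n_iter shuffle iterations.
#' @param config an [analysis_config()].
#' @param seed integer seed.
#' @param shared_offset logical; use one offset for all cells within an
#'   iteration (preserves across-cell structure) or independent offsets.
#' @return list with `threshold` (95th percentile) and `null` (pooled r's).
#' @export
correlation_chance <- function(profiles1, profiles2,
                               n_iter = 1000L, config = analysis_config(),
                               seed = config$rng_seed, shared_offset = TRUE) {
  stopifnot(length(profiles1) == length(profiles2))
  if (!length(profiles1)) stop("need at least one cell")
  n1 <- length(profiles1[[1]])
  p2r <- lapply(profiles2, resample_profile, n_out = n1)
  set.seed(derive_seed(seed, 31L))
  null <- numeric(0)
  for (m in seq_len(n_iter)) {
    if (shared_offset) {
      off <- sample.int(n1 - 1L, 1L)
      offv <- rep(off, length(p2r))
    } else {
      offv <- sample.int(n1 - 1L, length(p2r), replace = TRUE)
    }
    rs <- vapply(seq_along(p2r), function(i) {
      rate_map_correlation(profiles1[[i]], circular_shift(p2r[[i]], offv[i]))
    }, numeric(1))
    null <- c(null, rs[!is.na(rs)])
  }
  list(threshold = pctl(null, config$percentile / 100), null = null)
}

#' Classify a place cell's rotation across session halves
#'
#' The track is divided into thirds. Cells whose first-half primary field
#' center lies in the middle third are excluded (`middle_excluded`); cells
#' that are not place cells in the second half are `lost`. Otherwise the cell
#' `rotate`s if its second-half primary center lies in the opposite outer
#' third, is `non_rotate` if it stays in the same outer third, and is `lost`
#' (from the rotate/non-rotate denominators) when the second-half center
#' falls in the middle third.
#'
#' @param center1_cm first-half primary field center (cm).
#' @param is_place2 logical: place cell in the second half.
#' @param center2_cm second-half primary field center (cm, may be NA).
#' @param track_length_cm track length (cm).
#' @return one of `"rotate"`, `"non_rotate"`, `"middle_excluded"`, `"lost"`.
#' @export
classify_rotation <- function(center1_cm, is_place2, center2_cm,
                              track_length_cm) {
  L <- track_length_cm
  if (L <= 0) stop("track length must be positive")
  third <- function(x) {
    if (x < L / 3) 1L else if (x < 2 * L / 3) 2L else 3L
  }
  t1 <- third(center1_cm)
  if (t1 == 2L) return("middle_excluded")
  if (!isTRUE(is_place2) || is.na(center2_cm)) return("lost")
  t2 <- third(center2_cm)
  if (t2 == 2L) return("lost")
  if (t2 == t1) "non_rotate" else "rotate"
}

#' Analyze a mid-session manipulation pair
#'
#' Splits the session at the excised interval, runs the full place-coding
#' analysis independently on each half, and assembles per-cell remapping
#' statistics: flattened-profile map correlation (with resampling for
#' rescaled halves), rotation category (only for cells that are place cells
#' in the first half), and primary-field width change (only for cells
#' independently classified as place cells in both halves). The pooled
#' shuffle chance threshold for the map correlations is included.
#'
#' @param session a joined manipulation [session()] (from
#'   [simulate_manipulation_pair()] or [load_session()]).
#' @param config an [analysis_config()].
#' @param n_iter_chance iterations for the correlation chance threshold.
#' @return object of class `half_pair_result`: list with `cells` (data.frame:
#'   `cell`, `is_place1`, `is_place2`, `center1_cm`, `center2_cm`,
#'   `width1_cm`, `width2_cm`, `map_r`, `rotation`, `width_change_cm`),
#'   `chance_threshold`, `rotate_fraction`, `non_rotate_fraction` (fractions
#'   over first-half outer-third place cells, cells lost in the second half
#'   included in the denominator), `rotate_fraction_classified` (conditional
#'   on classification, the unbiased estimator of the underlying rotation
#'   probability), and the two half analyses.
#' @export
analyze_half_pair <- function(session, config = analysis_config(),
                              n_iter_chance = config$n_shuffles_mapcorr) {
  halves <- split_halves(session)
  a1 <- session_place_analysis(halves$half1, config = config)
  a2 <- session_place_analysis(halves$half2, config = config)
  n_cells <- nrow(session$traces)
  L1 <- halves$half1$meta$track_length_cm
  prof1 <- lapply(a1$maps, flatten_map)
  prof2 <- lapply(a2$maps, flatten_map)
  map_r <- vapply(seq_len(n_cells), function(i) {
    as.numeric(rate_map_correlation(prof1[[i]], prof2[[i]]))
  }, numeric(1))
  chance <- correlation_chance(prof1, prof2, n_iter = n_iter_chance,
                               config = config, seed = config$rng_seed)
  cells <- data.frame(
    cell = seq_len(n_cells),
    is_place1 = a1$cells$is_place,
    is_place2 = a2$cells$is_place,
    center1_cm = a1$cells$center_cm,
    center2_cm = a2$cells$center_cm,
    width1_cm = a1$cells$width_cm,
    width2_cm = a2$cells$width_cm,
    map_r = map_r,
    rotation = NA_character_,
    width_change_cm = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_cells)) {
    if (isTRUE(cells$is_place1[i]) && !is.na(cells$center1_cm[i])) {
      cells$rotation[i] <- classify_rotation(cells$center1_cm[i],
                                             cells$is_place2[i],
                                             cells$center2_cm[i], L1)
      if (isTRUE(cells$is_place2[i]) &&
          !is.na(cells$width1_cm[i]) && !is.na(cells$width2_cm[i])) {
        cells$width_change_cm[i] <- cells$width2_cm[i] - cells$width1_cm[i]
      }
    }
  }
  n_rot <- sum(cells$rotation == "rotate", na.rm = TRUE)
  n_non <- sum(cells$rotation == "non_rotate", na.rm = TRUE)
  denom <- sum(cells$rotation %in% c("rotate", "non_rotate", "lost"))
  structure(list(cells = cells,
                 chance_threshold = chance$threshold,
                 # fractions over all first-half outer-third place cells
                 # (cells lost in the second half stay in the denominator)
                 rotate_fraction = if (denom) n_rot / denom else NA_real_,
                 non_rotate_fraction = if (denom) n_non / denom else NA_real_,
                 # conditional on a second-half outer-third field: the
                 # unbiased estimator of an underlying rotation probability
                 rotate_fraction_classified =
                   if (n_rot + n_non) n_rot / (n_rot + n_non) else NA_real_,
                 half1 = a1, half2 = a2),
            class = "half_pair_result")
}

#' Place-field width change across session halves
#'
#' Width change (second half minus first half, cm) of the primary field for
#' cells independently classified as place cells in both halves.
#'
#' @param half_pair an [analyze_half_pair()] result.
#' @return data.frame with `cell` and `width_change_cm` for eligible cells.
#' @export
field_width_change <- function(half_pair) {
  cells <- half_pair$cells
  keep <- isTRUE_vec(cells$is_place1) & isTRUE_vec(cells$is_place2) &
    !is.na(cells$width_change_cm)
  cells[keep, c("cell", "width_change_cm")]
}

# Vectorized isTRUE: TRUE where x is TRUE, FALSE for FALSE/NA.
isTRUE_vec <- function(x) !is.na(x) & x
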