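# Cross-day cell matching from spatial footprints, coregistration
# validation, turnover, and across-day stability of place and speed coding.

# Binarize a footprint at half its maximum; an empty footprint has no mask.
.fp_mask <- function(fp) {
  m <- max(fp)
  if (m <= 0) return(matrix(FALSE, nrow(fp), ncol(fp)))
  fp >= 0.5 * m
}

# Weighted centroid (row, col) of a footprint; NA for an empty footprint.
.fp_centroid <- function(fp) {
  s <- sum(fp)
  if (s <= 0) return(c(NA_real_, NA_real_))
  w <- fp / s
  c(sum(row(fp) * w), sum(col(fp) * w))
}

# Rigid integer translation (dr, dc) taking set B onto set A, estimated as
# the mode of the centroid displacement field: the shift that aligns the most
# centroid pairs to within `count_radius` px. Robust to heavy turnover, where
# correlating summed footprint images fails (most blobs have no partner).
.align_footprints <- function(fps_a, fps_b, max_shift = 6L, count_radius = 4) {
  ca <- t(vapply(fps_a, .fp_centroid, numeric(2)))
  cb <- t(vapply(fps_b, .fp_centroid, numeric(2)))
  win <- max_shift
  d <- cbind(rep(cb[, 1], each = nrow(ca)) - rep(ca[, 1], nrow(cb)),
             rep(cb[, 2], each = nrow(ca)) - rep(ca[, 2], nrow(cb)))
  d <- d[stats::complete.cases(d) &
           abs(d[, 1]) <= win + count_radius &
           abs(d[, 2]) <= win + count_radius, , drop = FALSE]
  if (!nrow(d)) return(c(0L, 0L))
  best <- c(0L, 0L); best_n <- -1L
  for (dr in -win:win) {
    for (dc in -win:win) {
      nhit <- sum((d[, 1] - dr)^2 + (d[, 2] - dc)^2 <= count_radius^2)
      if (nhit > best_n) { best_n <- nhit; best <- c(dr, dc) }
    }
  }
  # shift convention: B aligned onto A by subtracting `best`
  -best
}

#' Match cells across days by footprint overlap
#'
#' Footprint sets are first aligned by the rigid translation maximizing the
#' cross-correlation of their summed images. Candidate pairs within
#' `match_max_dist_px` centroid distance are then scored by the
#' intersection-over-union of their binarized (half-maximum) masks and
#' accepted greedily in descending IoU order, one-to-one, requiring
#' IoU >= `match_min_iou`.
#'
#' @param footprints_i,footprints_j lists of footprint matrices on a common
#'   pixel grid (one per cell).
#' @param config an [analysis_config()].
#' @param max_align_shift_px search radius for the rigid alignment (px).
#' @return object of class `cell_matching`: list with `pairs` (data.frame:
#'   `i`, `j`, `dist_px`, `iou`), `unmatched_i`, `unmatched_j`, `shift`
#'   (applied to set j), `n_i`, `n_j`.
#' @export
match_cells <- function(footprints_i, footprints_j,
                        config = analysis_config(), max_align_shift_px = 6L) {
  empty <- function(ni, nj, shift = c(0L, 0L)) {
    structure(list(pairs = data.frame(i = integer(0), j = integer(0),
                                      dist_px = numeric(0), iou = numeric(0)),
                   unmatched_i = seq_len(ni), unmatched_j = seq_len(nj),
                   shift = shift, n_i = ni, n_j = nj),
              class = "cell_matching")
  }
  ni <- length(footprints_i); nj <- length(footprints_j)
  if (ni == 0L || nj == 0L) return(empty(ni, nj))
  shift <- .align_footprints(footprints_i, footprints_j, max_align_shift_px)
  cent_i <- t(vapply(footprints_i, .fp_centroid, numeric(2)))
  cent_j <- t(vapply(footprints_j, .fp_centroid, numeric(2)))
  # refine: rounded median residual displacement over nearest-centroid pairs
  # (robust to turnover; removes the +-1 px bias of the image correlation)
  cj <- sweep(cent_j, 2L, -shift)
  resid <- t(vapply(seq_len(ni), function(a) {
    d <- sqrt((cent_i[a, 1] - cj[, 1])^2 + (cent_i[a, 2] - cj[, 2])^2)
    b <- which.min(d)
    if (length(b) && isTRUE(d[b] <= config$match_max_dist_px)) {
      cj[b, ] - cent_i[a, ]
    } else c(NA_real_, NA_real_)
  }, numeric(2)))
  if (any(stats::complete.cases(resid))) {
    shift <- shift - apply(resid, 2L, stats::median, na.rm = TRUE)
  }
  # the declared search radius bounds the total shift; the flow refinement
  # must not drag unrelated point sets onto each other
  shift <- pmin(pmax(shift, -max_align_shift_px), max_align_shift_px)
  cent_j <- sweep(cent_j, 2L, -shift)   # apply alignment shift to set j
  G <- nrow(footprints_i[[1]])
  pix <- function(fp, dr = 0L, dc = 0L) {
    nz <- which(.fp_mask(fp), arr.ind = TRUE)
    (nz[, 1] + dr) * (2L * G) + (nz[, 2] + dc)
  }
  pix_i <- lapply(footprints_i, pix)
  # the refined shift is fractional; pixel masks are scored at its four
  # adjacent integerizations and the best overlap is kept
  ishifts <- unique(expand.grid(dr = c(floor(shift[1]), ceiling(shift[1])),
                                dc = c(floor(shift[2]), ceiling(shift[2]))))
  pix_j <- lapply(footprints_j, function(fp) {
    lapply(seq_len(nrow(ishifts)), function(k) {
      pix(fp, as.integer(ishifts$dr[k]), as.integer(ishifts$dc[k]))
    })
  })
  cand <- list()
  for (a in seq_len(ni)) {
    d <- sqrt((cent_i[a, 1] - cent_j[, 1])^2 + (cent_i[a, 2] - cent_j[, 2])^2)
    for (b in which(d <= config$match_max_dist_px)) {
      iou <- max(vapply(pix_j[[b]], function(pj) {
        inter <- length(intersect(pix_i[[a]], pj))
        uni <- length(pix_i[[a]]) + length(pj) - inter
        if (uni > 0) inter / uni else 0
      }, numeric(1)))
      if (iou >= config$match_min_iou) {
        cand[[length(cand) + 1L]] <- c(a, b, d[b], iou)
      }
    }
  }
  if (!length(cand)) return(empty(ni, nj, shift))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, 4]), , drop = FALSE]
  used_i <- logical(ni); used_j <- logical(nj)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    a <- cand[k, 1]; b <- cand[k, 2]
    if (!used_i[a] && !used_j[b]) {
      keep[k] <- TRUE
      used_i[a] <- TRUE; used_j[b] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  pairs <- data.frame(i = as.integer(cand[, 1]), j = as.integer(cand[, 2]),
                      dist_px = cand[, 3], iou = cand[, 4])
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, unmatched_i = which(!used_i),
                 unmatched_j = which(!used_j), shift = shift,
                 n_i = ni, n_j = nj),
            class = "cell_matching")
}

#' Correlation of a per-cell metric across matched pairs, with chance
#'
#' Spearman correlation of `x_i[pairs$i]` against `x_j[pairs$j]`, with a
#' chance threshold from the 95th percentile of the correlation under random
#' permutations of the pair assignment.
#'
#' @param x_i,x_j per-cell metric vectors for the two sessions.
#' @param matching a [match_cells()] result.
#' @param n_perm permutations for the chance threshold.
#' @param config an [analysis_config()].
#' @param seed integer seed.
#' @return list with `r`, `chance`, `n_pairs`, `low_power` (TRUE when fewer
#'   than 10 pairs).
#' @export
matched_correlation <- function(x_i, x_j, matching, n_perm = 1000L,
                                config = analysis_config(),
                                seed = config$rng_seed) {
  a <- x_i[matching$pairs$i]
  b <- x_j[matching$pairs$j]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 3L) {
    return(list(r = NA_real_, chance = NA_real_, n_pairs = n, low_power = TRUE))
  }
  r <- spearman(a, b)
  set.seed(derive_seed(seed, 41L))
  null <- vapply(seq_len(n_perm), function(k) spearman(a, b[sample.int(n)]),
                 numeric(1))
  list(r = r, chance = pctl(null, config$percentile / 100), n_pairs = n,
       low_power = n < 10L)
}

#' Validate a coregistration by amplitude and peak-to-noise persistence
#'
#' The same physical cell should show a similar mean transient amplitude and
#' peak-to-noise ratio on consecutive days; a matching whose amplitude
#' correlation does not beat its pair-shuffled chance is suspect.
#'
#' @param session_i,session_j [session()] objects for the two days.
#' @param matching a [match_cells()] result.
#' @param config an [analysis_config()].
#' @param n_perm permutations for chance thresholds.
#' @return list with `amplitude` and `pnr`, each a [matched_correlation()]
#'   result.
#' @export
coregistration_validation <- function(session_i, session_j, matching,
                                      config = analysis_config(),
                                      n_perm = 1000L) {
  ps_i <- session_peak_stats(session_i, config)
  ps_j <- session_peak_stats(session_j, config)
  list(amplitude = matched_correlation(ps_i$mean_peak_amplitude,
                                       ps_j$mean_peak_amplitude, matching,
                                       n_perm, config),
       pnr = matched_correlation(ps_i$pnr, ps_j$pnr, matching, n_perm, config))
}

#' Fraction of cells coregistered between two sessions
#'
#' Matched pairs divided by the mean of the two sessions' cell counts;
#' per-session denominators are also reported.
#'
#' @param matching a [match_cells()] result.
#' @param n_cells_i,n_cells_j cell counts (default from the matching).
#' @return list with `fraction` (mean denominator), `fraction_i`,
#'   `fraction_j`, `n_matched`.
#' @export
turnover_fraction <- function(matching, n_cells_i = matching$n_i,
                              n_cells_j = matching$n_j) {
  if (n_cells_i <= 0 || n_cells_j <= 0) stop("cell counts must be positive")
  m <- nrow(matching$pairs)
  list(fraction = m / mean(c(n_cells_i, n_cells_j)),
       fraction_i = m / n_cells_i, fraction_j = m / n_cells_j,
       n_matched = m)
}

#' Across-day stability of place and speed coding
#'
#' For coregistered cells: per-cell flattened-map Spearman correlation across
#' days (restricted to cells that are place cells on day i), the
#' population-level Spearman correlation of spatial mutual information across
#' days, and of the residual df/F-speed Spearman r across days, each with a
#' pair-shuffled chance threshold.
#'
#' @param session_i,session_j [session()] objects for the two days.
#' @param matching a [match_cells()] result.
#' @param config an [analysis_config()].
#' @param n_perm permutations for chance thresholds.
#' @param analysis_i,analysis_j optional precomputed
#'   [session_place_analysis()] results.
#' @return object of class `stability_report`: list with `map_r` (per matched
#'   day-i place cell), `map_r_mean`, `mi` and `speed` (each a
#'   [matched_correlation()] result), `n_matched_place`.
#' @export
across_day_stability <- function(session_i, session_j, matching,
                                 config = analysis_config(), n_perm = 1000L,
                                 analysis_i = NULL, analysis_j = NULL) {
  if (is.null(analysis_i)) analysis_i <- session_place_analysis(session_i, config = config)
  if (is.null(analysis_j)) analysis_j <- session_place_analysis(session_j, config = config)
  pairs <- matching$pairs
  prof_i <- lapply(analysis_i$maps, flatten_map)
  prof_j <- lapply(analysis_j$maps, flatten_map)
  place_i <- isTRUE_vec(analysis_i$cells$is_place[pairs$i])
  map_r <- rep(NA_real_, nrow(pairs))
  for (k in which(place_i)) {
    map_r[k] <- as.numeric(rate_map_correlation(prof_i[[pairs$i[k]]],
                                                prof_j[[pairs$j[k]]]))
  }
  n_place <- sum(!is.na(map_r))
  mi_cor <- matched_correlation(analysis_i$cells$mi, analysis_j$cells$mi,
                                matching, n_perm, config)
  sc_i <- classify_speed_cells(session_i, analysis_i$behavior, config)
  sc_j <- classify_speed_cells(session_j, analysis_j$behavior, config)
  sp_cor <- matched_correlation(sc_i$spearman_r, sc_j$spearman_r, matching,
                                n_perm, config)
  structure(list(map_r = map_r, map_r_mean = mean(map_r, na.rm = TRUE),
                 mi = mi_cor, speed = sp_cor, n_matched_place = n_place),
            class = "stability_report")
}
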