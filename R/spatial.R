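# Spatial coding: occupancy-normalized activity maps, spatial mutual
# information with circular-shift permutation nulls, and place-field geometry.

#' Sturges' rule bin count
#'
#' `ceiling(1 + log2(n))`; the ceiling makes the rule integer for general n.
#'
#' @param n number of samples (>= 1).
#' @return integer bin count.
#' @export
sturges_bins <- function(n) {
  if (n < 1) stop("n must be >= 1")
  as.integer(ceiling(1 + log2(n)))
}

# Bin edges along one spatial axis: 3.5 cm increments from 0, with a partial
# final bin when the extent is not a multiple of the bin size.
.space_edges <- function(extent_cm, bin_cm) {
  e <- seq(0, extent_cm, by = bin_cm)
  if (e[length(e)] < extent_cm) e <- c(e, extent_cm)
  e
}

# Bin index with the top edge assigned to the last bin.
.bin_index <- function(x, edges) {
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Occupancy-normalized activity map
#'
#' Bins the enclosure into `spatial_bin_cm` square pixels (partial edge bins
#' where the extent is not a multiple), accumulates df/F over
#' movement-masked samples, and divides by the per-bin occupancy, giving the
#' mean calcium activity at each visited location. Unvisited bins are NA.
#' Optional smoothing convolves with a Gaussian kernel
#' (`map_smooth_size` x `map_smooth_size` bins, sd `map_smooth_sd` bins),
#' renormalized over in-bounds occupied bins so edges and occupancy holes do
#' not leak mass.
#'
#' @param trace df/F vector for one cell.
#' @param behavior a [behavior_series()].
#' @param track_length_cm,track_width_cm enclosure extent (cm).
#' @param config an [analysis_config()].
#' @param smooth logical; apply Gaussian smoothing.
#' @return object of class `activity_map`: list with `map` (y bins x x bins),
#'   `occupancy` (masked sample counts), `smoothed`, `x_edges`, `y_edges`,
#'   `x_centers`.
#' @export
compute_activity_map <- function(trace, behavior, track_length_cm,
                                 track_width_cm, config = analysis_config(),
                                 smooth = TRUE) {
  mask <- behavior$movement_mask
  if (!any(mask)) stop("no movement-masked samples: cannot build an activity map")
  xe <- .space_edges(track_length_cm, config$spatial_bin_cm)
  ye <- .space_edges(track_width_cm, config$spatial_bin_cm)
  nx <- length(xe) - 1L
  ny <- length(ye) - 1L
  xi <- .bin_index(behavior$x[mask], xe)
  yi <- .bin_index(behavior$y[mask], ye)
  lin <- (xi - 1L) * ny + yi
  occ <- matrix(tabulate(lin, nx * ny), ny, nx)
  tot <- matrix(0, ny, nx)
  sums <- tapply(trace[mask], lin, sum)
  tot[as.integer(names(sums))] <- as.numeric(sums)
  m <- tot / occ
  m[occ == 0L] <- NA_real_
  if (smooth) m <- .smooth_map(m, config$map_smooth_size, config$map_smooth_sd)
  structure(list(map = m, occupancy = occ, smoothed = smooth,
                 x_edges = xe, y_edges = ye,
                 x_centers = (xe[-1] + xe[-length(xe)]) / 2),
            class = "activity_map")
}

# Gaussian smoothing with kernel weights renormalized over occupied bins.
.smooth_map <- function(m, size, sd_bins) {
  half <- size %/% 2L
  off <- -half:half
  k <- exp(-outer(off^2, off^2, "+") / (2 * sd_bins^2))
  occ <- !is.na(m)
  v0 <- ifelse(occ, m, 0)
  w0 <- ifelse(occ, 1, 0)
  nr <- nrow(m); nc <- ncol(m)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (a in seq_along(off)) {
    for (b in seq_along(off)) {
      dr <- off[a]; dc <- off[b]; kk <- k[a, b]
      rs <- max(1, 1 + dr):min(nr, nr + dr)  # destination rows
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      num[rs, cs] <- num[rs, cs] + kk * v0[rs - dr, cs - dc, drop = FALSE]
      den[rs, cs] <- den[rs, cs] + kk * w0[rs - dr, cs - dc, drop = FALSE]
    }
  }
  out <- num / den
  out[!occ] <- NA_real_
  out
}

# Mutual information (bits) between binned position and binned df/F, given
# precomputed position bin indices for the masked samples.
.mi_binned <- function(yvals, xb, nx) {
  n <- length(yvals)
  rng <- range(yvals)
  if (rng[1] == rng[2]) return(0)
  ny <- sturges_bins(n)
  yedges <- seq(rng[1], rng[2], length.out = ny + 1L)
  yb <- .bin_index(yvals, yedges)
  counts <- tabulate((xb - 1L) * ny + yb, nx * ny)
  p <- counts / n
  px <- tabulate(xb, nx) / n
  py <- tabulate(yb, ny) / n
  denom <- as.vector(outer(py, px))   # column-major: y fast, x slow
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / denom[nz]))
}

#' Spatial mutual information of a trace
#'
#' Computes I(X;Y) in bits between 1-D position (binned at
#' `spatial_bin_cm` along the track length) and df/F (binned by Sturges'
#' rule over the movement-masked samples; the top edge is assigned to the
#' last bin), summing `p(x,y) log2( p(x,y) / (p(x) p(y)) )` over non-empty
#' cells.
#'
#' @param trace df/F vector.
#' @param x position along the track (cm).
#' @param mask logical vector of samples to use (movement mask).
#' @param track_length_cm track length (cm).
#' @param config an [analysis_config()].
#' @return mutual information in bits.
#' @export
mutual_information <- function(trace, x, mask, track_length_cm,
                               config = analysis_config()) {
  if (sum(mask) < 2L) stop("need at least two masked samples")
  xe <- .space_edges(track_length_cm, config$spatial_bin_cm)
  xb <- .bin_index(x[mask], xe)
  if (length(unique(xb)) < 2L) {
    warning("single occupied position bin; MI is 0")
    return(0)
  }
  .mi_binned(trace[mask], xb, length(xe) - 1L)
}

#' Classify place cells by mutual information against a circular-shift null
#'
#' For each cell, the observed spatial mutual information is compared with a
#' null distribution built by circularly permuting the full trace by constant
#' increments `round(k T / n_shuffles)`, `k = 1..n_shuffles` (the final shift
#' is the identity, making the observed statistic a member of its own null
#' and the test exact at the nominal level). A cell is a place cell when its
#' MI strictly exceeds the 95th percentile of its null. Cells on sessions
#' with fewer than 100 movement-masked samples are flagged unclassifiable.
#'
#' @param session a [session()].
#' @param behavior a [behavior_series()] for the session (computed if NULL).
#' @param config an [analysis_config()].
#' @return object of class `place_cell_result`: data.frame with `cell`, `mi`,
#'   `threshold`, `is_place`; the per-cell null matrix is in the `null`
#'   attribute.
#' @export
classify_place_cells <- function(session, behavior = NULL,
                                 config = analysis_config()) {
  if (is.null(behavior)) behavior <- behavior_series(session, config)
  L <- session$meta$track_length_cm[1]
  mask <- behavior$movement_mask
  n_cells <- nrow(session$traces)
  T <- n_samples(session)
  if (sum(mask) < 100L) {
    res <- data.frame(cell = seq_len(n_cells), mi = NA_real_,
                      threshold = NA_real_, is_place = NA)
    class(res) <- c("place_cell_result", "data.frame")
    return(res)
  }
  xe <- .space_edges(L, config$spatial_bin_cm)
  nx <- length(xe) - 1L
  xb <- .bin_index(behavior$x[mask], xe)
  offs <- shift_offsets(T, config$n_shuffles_place)
  mi <- numeric(n_cells)
  thr <- numeric(n_cells)
  null <- matrix(0, n_cells, length(offs))
  q <- config$percentile / 100
  for (i in seq_len(n_cells)) {
    tr <- session$traces[i, ]
    mi[i] <- .mi_binned(tr[mask], xb, nx)
    for (k in seq_along(offs)) {
      null[i, k] <- .mi_binned(circular_shift(tr, offs[k])[mask], xb, nx)
    }
    thr[i] <- pctl(null[i, ], q)
  }
  res <- data.frame(cell = seq_len(n_cells), mi = mi, threshold = thr,
                    is_place = mi > thr)
  attr(res, "null") <- null
  class(res) <- c("place_cell_result", "data.frame")
  res
}

#' Segment place fields from a smoothed activity map
#'
#' Fields are 4-connected components of bins whose value exceeds
#' `mean + field_threshold_sd x sd` (mean and sd over occupied bins of the
#' smoothed map). Per field: size = bin area x bin count, width = extent
#' along the track from the first to the last column spanned, center = x
#' center of the maximum bin. Fields are sorted by peak value, so the first
#' row is the primary field.
#'
#' @param map an [compute_activity_map()] result (smoothed).
#' @param config an [analysis_config()].
#' @return data.frame with one row per field: `field`, `n_bins`, `size_cm2`,
#'   `width_cm`, `center_cm`, `peak`.
#' @export
detect_place_fields <- function(map, config = analysis_config()) {
  m <- map$map
  vals <- m[!is.na(m)]
  empty <- data.frame(field = integer(0), n_bins = integer(0),
                      size_cm2 = numeric(0), width_cm = numeric(0),
                      center_cm = numeric(0), peak = numeric(0))
  if (length(vals) < 2L) return(empty)
  thr <- mean(vals) + config$field_threshold_sd * stats::sd(vals)
  above <- !is.na(m) & m > thr
  if (!any(above)) return(empty)
  nr <- nrow(m); nc <- ncol(m)
  comp <- matrix(0L, nr, nc)
  n_comp <- 0L
  for (start in which(above)) {
    if (comp[start] > 0L) next
    n_comp <- n_comp + 1L
    queue <- start
    comp[start] <- n_comp
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1L && d[1] <= nr && d[2] >= 1L && d[2] <= nc) {
          j <- (d[2] - 1L) * nr + d[1]
          if (above[j] && comp[j] == 0L) {
            comp[j] <- n_comp
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  bin_area <- config$spatial_bin_cm^2
  xe <- map$x_edges
  rows <- lapply(seq_len(n_comp), function(f) {
    idx <- which(comp == f)
    cols <- (idx - 1L) %/% nr + 1L
    peak_idx <- idx[which.max(m[idx])]
    peak_col <- (peak_idx - 1L) %/% nr + 1L
    data.frame(field = f, n_bins = length(idx),
               size_cm2 = bin_area * length(idx),
               width_cm = xe[max(cols) + 1L] - xe[min(cols)],
               center_cm = map$x_centers[peak_col],
               peak = m[peak_idx])
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$peak), , drop = FALSE]
  out$field <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full place-coding analysis of one session
#'
#' Runs place-cell classification and, for every cell classified as a place
#' cell, segments its fields from the smoothed activity map.
#'
#' @param session a [session()].
#' @param behavior optional precomputed [behavior_series()].
#' @param config an [analysis_config()].
#' @return list with `cells` (data.frame: `cell`, `mi`, `threshold`,
#'   `is_place`, `field_count`, `center_cm`, `width_cm`, `size_cm2` of the
#'   primary field), `fields` (per-cell field tables), `maps` (per-cell
#'   smoothed [compute_activity_map()] objects), `behavior`.
#' @export
session_place_analysis <- function(session, behavior = NULL,
                                   config = analysis_config()) {
  if (is.null(behavior)) behavior <- behavior_series(session, config)
  pc <- classify_place_cells(session, behavior, config)
  L <- session$meta$track_length_cm[1]
  W <- session$meta$track_width_cm
  n_cells <- nrow(session$traces)
  maps <- vector("list", n_cells)
  fields <- vector("list", n_cells)
  pc$field_count <- 0L
  pc$center_cm <- NA_real_
  pc$width_cm <- NA_real_
  pc$size_cm2 <- NA_real_
  for (i in seq_len(n_cells)) {
    maps[[i]] <- compute_activity_map(session$traces[i, ], behavior, L, W,
                                      config, smooth = TRUE)
    if (isTRUE(pc$is_place[i])) {
      f <- detect_place_fields(maps[[i]], config)
      fields[[i]] <- f
      pc$field_count[i] <- nrow(f)
      if (nrow(f)) {
        pc$center_cm[i] <- f$center_cm[1]
        pc$width_cm[i] <- f$width_cm[1]
        pc$size_cm2[i] <- f$size_cm2[1]
      }
    }
  }
  list(cells = as.data.frame(pc), fields = fields, maps = maps,
       behavior = behavior)
}
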