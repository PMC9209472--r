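#' Construct a recording session
#'
#' A session holds the aligned df/F trace matrix, the behavioral pose series
#' on the same timebase, optional per-cell spatial footprints, and metadata.
#' Samples inside `removed_interval` (the excision window around a mid-session
#' manipulation) are excluded from every downstream statistic.
#'
#' @param traces numeric matrix, cells x samples (df/F).
#' @param pose data.frame with columns `nose_x`, `nose_y`, `ear_x`, `ear_y`,
#'   `tail_x`, `tail_y` (cm), one row per neural sample.
#' @param sample_rate_hz neural sample rate (Hz).
#' @param meta named list: `track_length_cm` (length 1 or 2: per session half),
#'   `track_width_cm`, `manipulation` (one of `none`, `rotate0`, `rotate180`,
#'   `med_med`, `med_short`, `med_long`), `cell_type`, `session_id`, `day`.
#' @param footprints optional list of 2-D footprint matrices, one per cell, on
#'   a common pixel grid.
#' @param removed_interval optional integer vector `c(first, last)` of samples
#'   excised around the manipulation (1-based, inclusive).
#' @return object of class `session`.
#' @export
session <- function(traces, pose, sample_rate_hz, meta = list(),
                    footprints = NULL, removed_interval = NULL) {
  traces <- as.matrix(traces)
  if (nrow(pose) != ncol(traces)) {
    stop("alignment error: traces have ", ncol(traces), " samples but pose has ",
         nrow(pose), " rows")
  }
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  need <- c("nose_x", "nose_y", "ear_x", "ear_y", "tail_x", "tail_y")
  miss <- setdiff(need, names(pose))
  if (length(miss)) stop("pose is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(footprints) && length(footprints) != nrow(traces)) {
    stop("footprints must have one entry per cell")
  }
  if (!is.null(removed_interval)) {
    removed_interval <- as.integer(removed_interval)
    if (length(removed_interval) != 2L ||
        removed_interval[1] < 1L || removed_interval[2] > ncol(traces) ||
        removed_interval[1] > removed_interval[2]) {
      stop("removed_interval must be c(first, last) within the sample range")
    }
  }
  defaults <- list(track_length_cm = 70, track_width_cm = 9,
                   manipulation = "none", cell_type = "CAMK2A",
                   session_id = "s1", day = 1L)
  meta <- utils::modifyList(defaults, meta)
  ok <- c("none", "rotate0", "rotate180", "med_med", "med_short", "med_long")
  if (!meta$manipulation %in% ok) {
    stop("unknown manipulation label: ", meta$manipulation)
  }
  structure(list(traces = traces, pose = as.data.frame(pose),
                 sample_rate_hz = sample_rate_hz, meta = meta,
                 footprints = footprints,
                 removed_interval = removed_interval),
            class = "session")
}

#' @export
print.session <- function(x, ...) {
  cat("<session> ", x$meta$session_id, ": ", nrow(x$traces), " cells x ",
      ncol(x$traces), " samples @ ", x$sample_rate_hz, " Hz, manipulation=",
      x$meta$manipulation, ", cell_type=", x$meta$cell_type, "\n", sep = "")
  invisible(x)
}

#' Logical index of analyzable samples
#'
#' TRUE for every sample outside the excised manipulation window.
#'
#' @param session a [session()].
#' @return logical vector, one element per sample.
#' @export
valid_samples <- function(session) {
  keep <- rep(TRUE, ncol(session$traces))
  ri <- session$removed_interval
  if (!is.null(ri)) keep[ri[1]:ri[2]] <- FALSE
  keep
}

#' Number of samples in a session
#' @param session a [session()].
#' @return integer sample count.
#' @export
n_samples <- function(session) ncol(session$traces)

#' Variance-based cell inclusion filter
#'
#' Keeps cells whose trace variance is at least 10% of the maximum variance
#' among non-outliers. Outliers are defined by the upper Tukey fence: variance
#' greater than Q3 + 1.5 IQR across cells (nearest-rank quartiles). Outlying
#' cells themselves are kept
#' whenever they pass the 10% threshold; the fence only stops them from
#' inflating the reference maximum.
#'
#' @param traces numeric matrix, cells x samples.
#' @param min_fraction inclusion threshold as a fraction of the reference
#'   maximum variance (default 0.1).
#' @return object of class `cell_filter`: list with `kept` (integer indices),
#'   `variance` (per cell), `outlier` (logical per cell), `threshold`.
#' @export
filter_cells <- function(traces, min_fraction = 0.1) {
  traces <- as.matrix(traces)
  if (nrow(traces) < 1L) stop("need at least one cell")
  v <- apply(traces, 1L, stats::var)
  v[is.na(v)] <- 0
  if (all(v == 0)) {
    warning("all traces are constant; no cells kept")
    return(structure(list(kept = integer(0), variance = v,
                          outlier = rep(FALSE, length(v)), threshold = NA_real_),
                     class = "cell_filter"))
  }
  # nearest-rank (inverse-ECDF) quartiles keep the fence meaningful at small n
  q <- stats::quantile(v, c(0.25, 0.75), type = 1, names = FALSE)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  outlier <- v > fence
  ref_max <- max(v[!outlier])
  thr <- min_fraction * ref_max
  structure(list(kept = which(v >= thr), variance = v, outlier = outlier,
                 threshold = thr),
            class = "cell_filter")
}

#' Restrict a session to a subset of cells
#'
#' @param session a [session()].
#' @param idx integer cell indices to keep.
#' @return a new [session()] with the selected cells.
#' @export
subset_cells <- function(session, idx) {
  session$traces <- session$traces[idx, , drop = FALSE]
  if (!is.null(session$footprints)) session$footprints <- session$footprints[idx]
  lat <- attr(session, "latent_events")
  if (!is.null(lat)) attr(session, "latent_events") <- lat[idx]
  session
}

#' Split a manipulation session into its two halves
#'
#' The boundary is the excised interval when present, otherwise the midpoint.
#' Each half becomes a standalone session with its own enclosure length taken
#' from `meta$track_length_cm` (recycled when scalar).
#'
#' @param session a [session()].
#' @return list of two [session()] objects, `half1` and `half2`.
#' @export
split_halves <- function(session) {
  n <- n_samples(session)
  ri <- session$removed_interval
  if (is.null(ri)) {
    i1 <- seq_len(n %/% 2)
    i2 <- (n %/% 2 + 1L):n
  } else {
    i1 <- seq_len(ri[1] - 1L)
    i2 <- if (ri[2] < n) (ri[2] + 1L):n else integer(0)
  }
  if (length(i1) < 2L || length(i2) < 2L) stop("a session half is empty")
  len <- rep(session$meta$track_length_cm, length.out = 2L)
  mk <- function(idx, L, half_id) {
    m <- session$meta
    m$track_length_cm <- L
    m$session_id <- paste0(m$session_id, "_h", half_id)
    s <- session(session$traces[, idx, drop = FALSE],
                 session$pose[idx, , drop = FALSE],
                 session$sample_rate_hz, m, session$footprints)
    lat <- attr(session, "latent_events")
    if (!is.null(lat)) {
      attr(s, "latent_events") <- lapply(lat, function(ev) {
        ev <- ev[ev >= idx[1] & ev <= idx[length(idx)]]
        ev - idx[1] + 1L
      })
    }
    s
  }
  list(half1 = mk(i1, len[1], 1L), half2 = mk(i2, len[2], 2L))
}

#' Save a session as a plain-text bundle
#'
#' Writes a directory containing `traces.csv` (cells x samples), `pose.csv`,
#' `meta.json`, and optionally `footprints.csv` (long format: cell, row, col,
#' value for non-zero pixels, plus grid dimensions in the metadata).
#'
#' @param session a [session()].
#' @param path directory to create or overwrite.
#' @return `path`, invisibly.
#' @export
save_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(session$traces),
                   file.path(path, "traces.csv"), row.names = FALSE)
  utils::write.csv(session$pose, file.path(path, "pose.csv"), row.names = FALSE)
  meta <- session$meta
  meta$sample_rate_hz <- session$sample_rate_hz
  meta$removed_interval <- session$removed_interval
  if (!is.null(session$footprints)) {
    dims <- dim(session$footprints[[1]])
    meta$footprint_dims <- dims
    fp <- do.call(rbind, lapply(seq_along(session$footprints), function(i) {
      nz <- which(session$footprints[[i]] != 0, arr.ind = TRUE)
      if (nrow(nz) == 0L) return(NULL)
      data.frame(cell = i, row = nz[, 1], col = nz[, 2],
                 value = session$footprints[[i]][nz])
    }))
    utils::write.csv(fp, file.path(path, "footprints.csv"), row.names = FALSE)
  }
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(path, "meta.json"))
  invisible(path)
}

#' Load a session from a plain-text bundle
#'
#' Reads the bundle written by [save_session()], or an externally prepared one
#' with the same layout. When the pose table carries more rows than the trace
#' matrix by an integer factor (e.g. 30 Hz behavior against 7.5 Hz neural
#' data), pose samples are block-averaged onto the neural timebase.
#'
#' @param path bundle directory.
#' @return a [session()].
#' @export
load_session <- function(path) {
  need <- c("traces.csv", "pose.csv", "meta.json")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop("load error: required file '", f, "' is missing from ", path)
    }
  }
  traces <- as.matrix(utils::read.csv(file.path(path, "traces.csv")))
  dimnames(traces) <- NULL
  pose <- utils::read.csv(file.path(path, "pose.csv"))
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  rate <- meta$sample_rate_hz
  n <- ncol(traces)
  if (nrow(pose) != n) {
    fac <- nrow(pose) / n
    if (fac != round(fac) || fac < 1) {
      stop("alignment error: pose has ", nrow(pose),
           " rows which is not an integer multiple of the ", n, " neural samples")
    }
    fac <- as.integer(fac)
    grp <- rep(seq_len(n), each = fac)
    pose <- as.data.frame(lapply(pose, function(col) {
      as.numeric(tapply(col, grp, mean))
    }))
  }
  footprints <- NULL
  fp_path <- file.path(path, "footprints.csv")
  if (file.exists(fp_path) && !is.null(meta$footprint_dims)) {
    fp <- utils::read.csv(fp_path)
    dims <- as.integer(meta$footprint_dims)
    footprints <- lapply(seq_len(nrow(traces)), function(i) {
      m <- matrix(0, dims[1], dims[2])
      rows <- fp[fp$cell == i, , drop = FALSE]
      m[cbind(rows$row, rows$col)] <- rows$value
      m
    })
  }
  ri <- meta$removed_interval
  if (!is.null(ri) && length(ri) == 0L) ri <- NULL
  keep <- c("track_length_cm", "track_width_cm", "manipulation", "cell_type",
            "session_id", "day")
  session(traces, pose, rate, meta[intersect(keep, names(meta))],
          footprints = footprints, removed_interval = ri)
}
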