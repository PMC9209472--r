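# Speed coding: position-regressed speed-cell classification, encoding
# consistency splits, and block-cross-validated linear speed decoding.

#' Regress position out of a trace
#'
#' Fits a Gaussian-family, identity-link linear model of df/F on one-hot
#' position-bin indicators (3.5 cm bins along the track), which for this
#' design is exactly the per-bin mean, and returns the residual. One-hot
#' encoding removes arbitrary (e.g. unimodal place-field) position tuning,
#' which a single linear-in-x term could not absorb.
#'
#' @param trace df/F vector.
#' @param x position along the track (cm).
#' @param track_length_cm track length (cm).
#' @param config an [analysis_config()].
#' @return residual trace (trace minus fitted position effect).
#' @export
regress_out_position <- function(trace, x, track_length_cm,
                                 config = analysis_config()) {
  xe <- .space_edges(track_length_cm, config$spatial_bin_cm)
  xb <- .bin_index(x, xe)
  if (length(unique(xb)) < 2L) {
    warning("constant position; returning mean-centered trace")
    return(trace - mean(trace))
  }
  fitted <- stats::ave(trace, xb)
  trace - fitted
}

#' Classify speed cells against a circular-shift null
#'
#' Per cell, position is regressed out of the trace and the Spearman
#' correlation of the residual with speed is computed over all analyzable
#' samples. The null circularly permutes the speed vector by constant
#' increments `round(k T / n_shuffles)`, `k = 1..n_shuffles` (identity shift
#' included, making each 5% tail exact). A cell is `positive` when its r
#' strictly exceeds the 95th percentile of its null, `negative` when below
#' the 5th percentile, otherwise `none`.
#'
#' @param session a [session()].
#' @param behavior optional precomputed [behavior_series()].
#' @param config an [analysis_config()].
#' @return object of class `speed_cell_result`: data.frame with `cell`,
#'   `spearman_r`, `upper`, `lower`, `class`; null matrix in the `null`
#'   attribute.
#' @export
classify_speed_cells <- function(session, behavior = NULL,
                                 config = analysis_config()) {
  if (is.null(behavior)) behavior <- behavior_series(session, config)
  valid <- behavior$valid
  speed <- behavior$speed[valid]
  L <- session$meta$track_length_cm[1]
  n_cells <- nrow(session$traces)
  offs <- shift_offsets(length(speed), config$n_shuffles_speed)
  q_hi <- config$percentile / 100
  q_lo <- 1 - q_hi
  speed_ranks <- rank(speed)
  shifted_ranks <- vapply(offs, function(o) rank(circular_shift(speed, o)),
                          numeric(length(speed)))
  r <- numeric(n_cells)
  hi <- numeric(n_cells)
  lo <- numeric(n_cells)
  cls <- character(n_cells)
  null <- matrix(0, n_cells, length(offs))
  for (i in seq_len(n_cells)) {
    resid <- regress_out_position(session$traces[i, valid],
                                  behavior$x[valid], L, config)
    if (stats::sd(resid) == 0) {
      r[i] <- NA_real_; hi[i] <- NA_real_; lo[i] <- NA_real_; cls[i] <- "none"
      next
    }
    rr <- rank(resid)
    r[i] <- stats::cor(rr, speed_ranks)
    null[i, ] <- as.numeric(stats::cor(rr, shifted_ranks))
    hi[i] <- pctl(null[i, ], q_hi)
    lo[i] <- pctl(null[i, ], q_lo)
    cls[i] <- if (r[i] > hi[i]) "positive" else if (r[i] < lo[i]) "negative" else "none"
  }
  res <- data.frame(cell = seq_len(n_cells), spearman_r = r, upper = hi,
                    lower = lo, class = cls, stringsAsFactors = FALSE)
  attr(res, "null") <- null
  class(res) <- c("speed_cell_result", "data.frame")
  res
}

#' Consistency of speed encoding across a session split
#'
#' Computes each cell's Spearman correlation of df/F with speed separately
#' within two partitions (left/right halves of the track, or first/second
#' halves of the session) and returns the across-cell Spearman correlation of
#' the two per-cell r-vectors. A consistency near 1 indicates stationary
#' speed tuning.
#'
#' @param session a [session()].
#' @param split `"left_right"` or `"half_half"`.
#' @param behavior optional precomputed [behavior_series()].
#' @param config an [analysis_config()].
#' @return list with `consistency_r`, and the per-cell `r1`, `r2` vectors.
#' @export
split_consistency <- function(session, split = c("left_right", "half_half"),
                              behavior = NULL, config = analysis_config()) {
  split <- match.arg(split)
  if (is.null(behavior)) behavior <- behavior_series(session, config)
  valid <- behavior$valid
  idx <- which(valid)
  if (split == "left_right") {
    L <- session$meta$track_length_cm[1]
    p1 <- idx[behavior$x[idx] < L / 2]
    p2 <- idx[behavior$x[idx] >= L / 2]
  } else {
    mid <- length(valid) %/% 2
    p1 <- idx[idx <= mid]
    p2 <- idx[idx > mid]
  }
  if (length(p1) < 100L) stop("partition 1 of split '", split, "' has too few samples")
  if (length(p2) < 100L) stop("partition 2 of split '", split, "' has too few samples")
  r_in <- function(part) {
    sp <- behavior$speed[part]
    apply(session$traces[, part, drop = FALSE], 1L, spearman, y = sp)
  }
  r1 <- r_in(p1)
  r2 <- r_in(p2)
  list(consistency_r = spearman(r1, r2), r1 = r1, r2 = r2)
}

# Alternating train/test block labels over the session timeline:
# `block_s` seconds of data then `guard_s` seconds of guard, odd data blocks
# train, even test; guard samples belong to neither.
.decode_blocks <- function(n, rate, block_s, guard_s) {
  t <- (seq_len(n) - 1L) / rate
  period <- block_s + guard_s
  b <- floor(t / period)
  inblock <- (t - b * period) < block_s
  role <- rep("guard", n)
  role[inblock & b %% 2 == 0] <- "train"
  role[inblock & b %% 2 == 1] <- "test"
  role
}

#' Decode running speed from population activity
#'
#' Position-regressed traces are the predictors of a Gaussian-family linear
#' model of instantaneous speed. The session is separated into alternating
#' 60 s training and testing blocks with 10 s guards; odd blocks train the
#' model, withheld even blocks are scored by the Spearman correlation of
#' actual and predicted speed over the concatenated test samples. The
#' statistic is averaged over `decode_n_iter` random cell subsets of size
#' `n_subsample`. The chance threshold is the 95th percentile of the same
#' pipeline run on circularly permuted speed (`n_shuffles_speed` constant
#' increments, `decode_n_iter_chance` subsets each).
#'
#' @param session a [session()].
#' @param n_subsample cells per decoding subset.
#' @param behavior optional precomputed [behavior_series()].
#' @param config an [analysis_config()].
#' @param seed integer seed for cell subsampling.
#' @return object of class `decoding_result`: list with `mean_r`, `iter_r`,
#'   `chance_threshold`, `chance_r`, `n_cells_used`, `n_train`, `n_test`.
#' @export
decode_speed <- function(session, n_subsample = 32L, behavior = NULL,
                         config = analysis_config(), seed = config$rng_seed) {
  if (is.null(behavior)) behavior <- behavior_series(session, config)
  valid <- behavior$valid
  n_cells <- nrow(session$traces)
  if (n_cells < n_subsample) {
    stop("session has ", n_cells, " cells, fewer than n_subsample = ", n_subsample)
  }
  L <- session$meta$track_length_cm[1]
  idx <- which(valid)
  speed <- behavior$speed[idx]
  rate <- session$sample_rate_hz
  role <- .decode_blocks(length(idx), rate, config$decode_block_s,
                         config$decode_guard_s)
  tr_i <- role == "train"
  te_i <- role == "test"
  if (sum(tr_i) < 10L || sum(te_i) < 10L) {
    stop("session too short for the configured block structure")
  }
  resid <- t(apply(session$traces[, idx, drop = FALSE], 1L, function(tr) {
    regress_out_position(tr, behavior$x[idx], L, config)
  }))
  fit_score <- function(cells, y) {
    X <- cbind(1, t(resid[cells, , drop = FALSE]))
    fit <- stats::lm.fit(X[tr_i, , drop = FALSE], y[tr_i])
    beta <- fit$coefficients
    if (anyNA(beta)) beta[is.na(beta)] <- 0   # rank-deficient fit: drop aliased
    pred <- X[te_i, , drop = FALSE] %*% beta
    spearman(y[te_i], as.numeric(pred))
  }
  set.seed(derive_seed(seed, 21L))
  subsets <- lapply(seq_len(config$decode_n_iter),
                    function(k) sample.int(n_cells, n_subsample))
  iter_r <- vapply(subsets, fit_score, numeric(1), y = speed)
  offs <- shift_offsets(length(speed), config$n_shuffles_speed)
  set.seed(derive_seed(seed, 22L))
  chance_r <- unlist(lapply(seq_along(offs), function(k) {
    ys <- circular_shift(speed, offs[k])
    vapply(seq_len(config$decode_n_iter_chance), function(j) {
      fit_score(sample.int(n_cells, n_subsample), ys)
    }, numeric(1))
  }))
  structure(list(mean_r = mean(iter_r), iter_r = iter_r,
                 chance_threshold = pctl(chance_r, config$percentile / 100),
                 chance_r = chance_r, n_cells_used = n_subsample,
                 n_train = sum(tr_i), n_test = sum(te_i)),
            class = "decoding_result")
}

#' Flag sessions with poor spatial sampling
#'
#' Sessions whose path length falls more than one standard deviation below
#' the cohort mean are flagged for exclusion from decoding.
#'
#' @param path_lengths_cm numeric vector of per-session path lengths.
#' @return logical vector, TRUE = excluded.
#' @export
flag_low_path_sessions <- function(path_lengths_cm) {
  path_lengths_cm < mean(path_lengths_cm) - stats::sd(path_lengths_cm)
}
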