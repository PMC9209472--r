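# Synthetic-session generator: trajectories, tuned populations, rendered df/F.
# Every stochastic draw flows from one master seed through derive_seed(), so
# per-cell randomness is stable under reordering.

#' Simulate a free-exploration trajectory on a linear enclosure
#'
#' A bout-structured random walk: running bouts (exponentially distributed
#' durations, mean 4 s) with target speeds drawn uniformly from
#' `run_speed_range`, alternating with pauses (mean 2 s) near zero speed, so
#' that both sub- and supra-threshold (3 cm/s) epochs exist. Speed relaxes
#' toward its target with Gaussian innovations; walls are reflective. The
#' transverse coordinate is an Ornstein-Uhlenbeck wander about the enclosure
#' midline, wide enough that occupancy covers the transverse bins.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default `config$rng_seed`).
#' @param run_speed_range target running-speed range (cm/s).
#' @param speed_noise sd of per-sample speed innovations (cm/s).
#' @return object of class `trajectory`: list with `x`, `y` (cm), `speed`
#'   (true speed, cm/s), `sample_rate_hz`, `track_length_cm`, `track_width_cm`.
#' @export
simulate_trajectory <- function(config, seed = config$rng_seed,
                                run_speed_range = c(8, 25),
                                speed_noise = 1.2) {
  L <- config$track_length_cm
  W <- config$track_width_cm
  rate <- config$sample_rate_hz
  if (L <= 2 * 3.5) stop("track length must exceed two spatial bins")
  n <- as.integer(round(config$duration_s * rate))
  dt <- 1 / rate
  set.seed(seed)
  x <- numeric(n); y <- numeric(n); v <- numeric(n)
  x[1] <- L / 2; y[1] <- W / 2
  dir <- 1
  running <- TRUE
  bout_left <- stats::rexp(1, 1 / 4)
  target <- stats::runif(1, run_speed_range[1], run_speed_range[2])
  for (t in 2:n) {
    bout_left <- bout_left - dt
    if (bout_left <= 0) {
      running <- !running
      if (running) {
        bout_left <- max(1, stats::rexp(1, 1 / 4))
        target <- stats::runif(1, run_speed_range[1], run_speed_range[2])
        if (stats::runif(1) < 0.3) dir <- -dir
      } else {
        bout_left <- max(0.4, stats::rexp(1, 1 / 2))
        target <- 0
      }
    }
    v[t] <- max(0, v[t - 1] + 0.25 * (target - v[t - 1]) +
                  stats::rnorm(1, 0, speed_noise))
    xn <- x[t - 1] + dir * v[t] * dt
    if (xn < 0) { xn <- -xn; dir <- 1 }
    if (xn > L) { xn <- 2 * L - xn; dir <- -1 }
    x[t] <- xn
    y[t] <- min(W, max(0, y[t - 1] + 0.2 * (W / 2 - y[t - 1]) +
                         stats::rnorm(1, 0, 1.0)))
  }
  v[1] <- v[2]
  structure(list(x = x, y = y, speed = v, sample_rate_hz = rate,
                 track_length_cm = L, track_width_cm = W),
            class = "trajectory")
}

#' Draw a tuned cell population with known ground truth
#'
#' Exactly `round(fraction_place_cells * n_cells)` cells (sampled without
#' replacement) receive a 1-D Gaussian place field with center uniform on the
#' track and tuning sd uniform on `field_width_range_cm`. Speed tuning is
#' linear in speed on the event-rate scale, with the configured fractions of
#' positively and negatively tuned cells. Each place cell carries a remap
#' label (`rotate` / `stable` / `random`, probabilities `p_rotate`,
#' `p_stable`, remainder) consumed by [simulate_manipulation_pair()].
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return object of class `ground_truth`: a data.frame with one row per cell
#'   (columns `cell`, `id`, `cell_type`, `baseline_rate`, `decay_s`, `amp`,
#'   `is_place`, `center_cm`, `width_cm`, `remap_label`, `speed_class`,
#'   `speed_slope`, `popevent_participant`).
#' @export
simulate_population <- function(config, seed = config$rng_seed) {
  n <- config$n_cells
  set.seed(seed)
  gt <- data.frame(
    cell = seq_len(n),
    id = paste0("c", seq_len(n)),
    cell_type = config$cell_type,
    baseline_rate = config$baseline_rate * stats::rlnorm(n, 0, 0.25),
    decay_s = config$decay_s * stats::runif(n, 0.9, 1.1),
    amp = stats::rlnorm(n, config$amp_meanlog, config$amp_sdlog),
    is_place = FALSE,
    center_cm = NA_real_,
    width_cm = NA_real_,
    remap_label = NA_character_,
    speed_class = "none",
    speed_slope = 0,
    popevent_participant = stats::runif(n) < config$popevent_participation,
    stringsAsFactors = FALSE
  )
  n_place <- round(config$fraction_place_cells * n)
  if (n_place > 0) {
    pc <- sample.int(n, n_place)
    gt$is_place[pc] <- TRUE
    gt$center_cm[pc] <- stats::runif(n_place, 0, config$track_length_cm)
    gt$width_cm[pc] <- stats::runif(n_place, config$field_width_range_cm[1],
                                    config$field_width_range_cm[2])
    p_rand <- max(0, 1 - config$p_rotate - config$p_stable)
    gt$remap_label[pc] <- sample(c("rotate", "stable", "random"), n_place,
                                 replace = TRUE,
                                 prob = c(config$p_rotate, config$p_stable, p_rand))
  }
  n_pos <- round(config$fraction_speed_pos * n)
  n_neg <- round(config$fraction_speed_neg * n)
  if (n_pos + n_neg > 0) {
    sp <- sample.int(n, n_pos + n_neg)
    if (n_pos > 0) {
      gt$speed_class[sp[seq_len(n_pos)]] <- "positive"
      gt$speed_slope[sp[seq_len(n_pos)]] <-
        config$speed_slope * stats::runif(n_pos, 0.75, 1.25)
    }
    if (n_neg > 0) {
      neg <- sp[n_pos + seq_len(n_neg)]
      gt$speed_class[neg] <- "negative"
      gt$speed_slope[neg] <- -config$speed_slope * stats::runif(n_neg, 0.75, 1.25)
    }
  }
  class(gt) <- c("ground_truth", "data.frame")
  gt
}

# Per-sample event rate (peaks/s) for one cell on a trajectory.
.cell_rate <- function(row, traj, config) {
  r <- rep(row$baseline_rate, length(traj$x))
  if (isTRUE(row$is_place)) {
    bump <- exp(-(traj$x - row$center_cm)^2 / (2 * row$width_cm^2))
    r <- r * (config$place_floor + (config$place_gain - config$place_floor) * bump)
  }
  if (row$speed_class != "none") {
    gain <- 1 + row$speed_slope * (traj$speed - 10) / 10
    r <- r * gain
  }
  r
}

#' Render a df/F session from ground truth and a trajectory
#'
#' Per cell, transient onsets are drawn as a Bernoulli process at
#' `rate x dt`, where rate = baseline x place gain(x) x speed gain(v); the
#' place gain is a Gaussian bump, the speed gain linear in speed and clipped
#' at zero (clips counted in the `rate_clips` attribute). Onsets are convolved
#' with a single-exponential transient (per-cell decay, per-event amplitude
#' jitter) and Gaussian noise is added. When `config$n_popevents > 0`,
#' synchronous events are injected at samples in the configured speed regime
#' for all participating cells; the injected samples are stored in the
#' `popevent_samples` attribute. Latent onsets per cell are kept in the
#' `latent_events` attribute for generator bookkeeping.
#'
#' @param ground_truth a [simulate_population()] result.
#' @param trajectory a [simulate_trajectory()] result.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param manipulation manipulation label recorded in the session metadata.
#' @param session_id session identifier.
#' @param day day index.
#' @param footprints optional footprint list to attach.
#' @return a [session()] with pose synthesized around the trajectory.
#' @export
render_session <- function(ground_truth, trajectory, config,
                           seed = config$rng_seed, manipulation = "none",
                           session_id = "sim", day = 1L, footprints = NULL) {
  n <- length(trajectory$x)
  n_cells <- nrow(ground_truth)
  dt <- 1 / trajectory$sample_rate_hz
  # Injected population-event samples, drawn from the target speed regime.
  pop_samples <- integer(0)
  if (config$n_popevents > 0L) {
    set.seed(derive_seed(seed, 900001L))
    cand <- if (config$popevent_speed_regime == "low") {
      which(trajectory$speed < 3)
    } else {
      which(trajectory$speed > 8)
    }
    if (length(cand) < config$n_popevents) {
      stop("not enough samples in the target speed regime for injected events")
    }
    # greedy draw keeping >= 3 samples separation so injected events stay
    # distinct after refractory merging
    perm <- sample(cand)
    chosen <- integer(0)
    for (s0 in perm) {
      if (!length(chosen) || all(abs(chosen - s0) >= 3L)) {
        chosen <- c(chosen, s0)
        if (length(chosen) == config$n_popevents) break
      }
    }
    pop_samples <- sort(chosen)
  }
  traces <- matrix(0, n_cells, n)
  latent <- vector("list", n_cells)
  clips <- 0L
  for (i in seq_len(n_cells)) {
    row <- ground_truth[i, ]
    rate <- .cell_rate(row, trajectory, config)
    nclip <- sum(rate < 0)
    clips <- clips + nclip
    rate[rate < 0] <- 0
    set.seed(derive_seed(seed, i))
    ev <- stats::runif(n) < pmin(rate * dt, 1)
    if (length(pop_samples) && isTRUE(row$popevent_participant)) {
      ev[pop_samples] <- TRUE
    }
    idx <- which(ev)
    impulse <- numeric(n)
    if (length(idx)) {
      impulse[idx] <- row$amp * stats::rlnorm(length(idx), 0, 0.2)
    }
    tr <- stats::filter(impulse, exp(-dt / row$decay_s), method = "recursive")
    traces[i, ] <- as.numeric(tr) + stats::rnorm(n, 0, config$noise_sd)
    latent[[i]] <- idx
  }
  if (clips > 0L) {
    warning(clips, " negative rate samples clipped to zero")
  }
  pose <- .synth_pose(trajectory, seed)
  meta <- list(track_length_cm = trajectory$track_length_cm,
               track_width_cm = trajectory$track_width_cm,
               manipulation = manipulation, cell_type = config$cell_type,
               session_id = session_id, day = as.integer(day))
  s <- session(traces, pose, trajectory$sample_rate_hz, meta,
               footprints = footprints)
  attr(s, "latent_events") <- latent
  attr(s, "popevent_samples") <- pop_samples
  attr(s, "rate_clips") <- clips
  s
}

# Nose/ear/tailbase pose synthesized as the trajectory plus smooth
# per-body-point offsets (OU wander, sd ~0.5 cm), clipped to the enclosure.
.synth_pose <- function(traj, seed) {
  n <- length(traj$x)
  set.seed(derive_seed(seed, 777001L))
  ou <- function(sd) {
    e <- stats::rnorm(n, 0, sd)
    as.numeric(stats::filter(e, 0.8, method = "recursive"))
  }
  clipx <- function(v) pmin(traj$track_length_cm, pmax(0, v))
  clipy <- function(v) pmin(traj$track_width_cm, pmax(0, v))
  data.frame(
    nose_x = clipx(traj$x + ou(0.3)), nose_y = clipy(traj$y + ou(0.3)),
    ear_x = clipx(traj$x + ou(0.2)), ear_y = clipy(traj$y + ou(0.2)),
    tail_x = clipx(traj$x + ou(0.2)), tail_y = clipy(traj$y + ou(0.2))
  )
}

#' Simulate a complete single-enclosure session
#'
#' Convenience wrapper: population, trajectory, rendered session.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `session`, `ground_truth`, `trajectory`.
#' @export
simulate_session <- function(config = sim_config(), seed = config$rng_seed) {
  gt <- simulate_population(config, seed = derive_seed(seed, 1L))
  traj <- simulate_trajectory(config, seed = derive_seed(seed, 2L))
  s <- render_session(gt, traj, config, seed = derive_seed(seed, 3L))
  list(session = s, ground_truth = gt, trajectory = traj)
}

#' Simulate a mid-session manipulation session pair
#'
#' Renders two session halves (each `duration_s / 2` long) around an excised
#' gap of `gap_s` seconds. The second half's ground truth is transformed per
#' cell: for rotation sessions, `rotate`-labeled place cells mirror their
#' center (`L - center`), `stable` cells keep it, `random` cells redraw;
#' for rescaling sessions with `rescale_mode = "scale_with_track"`, centers
#' and tuning widths of non-`random` cells are multiplied by the length
#' ratio (35/70 or 105/70), while `"fixed"` keeps them (clipped into the new
#' track). The gap samples contain noise-only traces with frozen pose and are
#' recorded as the session's `removed_interval`.
#'
#' @param config a [sim_config()].
#' @param kind one of `rotate0`, `rotate180`, `med_med`, `med_short`,
#'   `med_long`.
#' @param ground_truth optional pre-drawn [simulate_population()] result.
#' @param seed integer seed.
#' @return list with `session` (joined halves, excised gap flagged), `half1`,
#'   `half2` (standalone rendered halves), and `ground_truth` (per-cell
#'   columns for both halves: `center1_cm`, `width1_cm`, `center2_cm`,
#'   `width2_cm`, `remap_label`).
#' @export
simulate_manipulation_pair <- function(config, kind, ground_truth = NULL,
                                       seed = config$rng_seed) {
  kinds <- c(rotate0 = 1, rotate180 = 1, med_med = 1, med_short = 0.5,
             med_long = 1.5)
  if (!kind %in% names(kinds)) stop("unknown manipulation kind: ", kind)
  ratio <- kinds[[kind]]
  L1 <- config$track_length_cm
  L2 <- L1 * ratio
  if (is.null(ground_truth)) {
    ground_truth <- simulate_population(config, seed = derive_seed(seed, 1L))
  }
  gt2 <- ground_truth
  set.seed(derive_seed(seed, 4L))
  for (i in which(ground_truth$is_place)) {
    lab <- ground_truth$remap_label[i]
    if (identical(lab, "random")) {
      gt2$center_cm[i] <- stats::runif(1, 0, L2)
      gt2$width_cm[i] <- stats::runif(1, config$field_width_range_cm[1],
                                      config$field_width_range_cm[2])
    } else if (startsWith(kind, "rotate")) {
      if (identical(lab, "rotate")) gt2$center_cm[i] <- L1 - ground_truth$center_cm[i]
    } else if (config$rescale_mode == "scale_with_track") {
      gt2$center_cm[i] <- ground_truth$center_cm[i] * ratio
      gt2$width_cm[i] <- ground_truth$width_cm[i] * ratio
    } else {
      gt2$center_cm[i] <- min(ground_truth$center_cm[i], L2)
    }
  }
  half_cfg <- function(L) {
    cfg <- config
    cfg$track_length_cm <- L
    cfg$duration_s <- config$duration_s / 2
    cfg
  }
  cfg1 <- half_cfg(L1); cfg2 <- half_cfg(L2)
  traj1 <- simulate_trajectory(cfg1, seed = derive_seed(seed, 2L))
  traj2 <- simulate_trajectory(cfg2, seed = derive_seed(seed, 3L))
  h1 <- render_session(ground_truth, traj1, cfg1, seed = derive_seed(seed, 5L),
                       manipulation = kind, session_id = paste0(kind, "_h1"))
  h2 <- render_session(gt2, traj2, cfg2, seed = derive_seed(seed, 6L),
                       manipulation = kind, session_id = paste0(kind, "_h2"))
  # join with an excised gap: noise-only traces, frozen pose
  rate <- config$sample_rate_hz
  gap_n <- as.integer(round(config$gap_s * rate))
  n1 <- n_samples(h1)
  set.seed(derive_seed(seed, 7L))
  gap_tr <- matrix(stats::rnorm(nrow(h1$traces) * gap_n, 0, config$noise_sd),
                   nrow(h1$traces), gap_n)
  gap_pose <- h1$pose[rep(n1, gap_n), , drop = FALSE]
  traces <- cbind(h1$traces, gap_tr, h2$traces)
  pose <- rbind(h1$pose, gap_pose, h2$pose)
  meta <- h1$meta
  meta$track_length_cm <- c(L1, L2)
  meta$session_id <- kind
  joined <- session(traces, pose, rate, meta,
                    removed_interval = c(n1 + 1L, n1 + gap_n))
  lat1 <- attr(h1, "latent_events"); lat2 <- attr(h2, "latent_events")
  attr(joined, "latent_events") <- lapply(seq_along(lat1), function(i) {
    c(lat1[[i]], lat2[[i]] + n1 + gap_n)
  })
  out_gt <- ground_truth
  out_gt$center1_cm <- ground_truth$center_cm
  out_gt$width1_cm <- ground_truth$width_cm
  out_gt$center2_cm <- gt2$center_cm
  out_gt$width2_cm <- gt2$width_cm
  list(session = joined, half1 = h1, half2 = h2, ground_truth = out_gt)
}

# A round Gaussian footprint blob (sd ~2.2 px) on a G x G grid.
.make_footprint <- function(G, center, sd_px = 5.5, radius = 13L) {
  m <- matrix(0, G, G)
  r0 <- max(1L, center[1] - radius); r1 <- min(G, center[1] + radius)
  c0 <- max(1L, center[2] - radius); c1 <- min(G, center[2] + radius)
  rr <- r0:r1; cc <- c0:c1
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  m[rr, cc] <- exp(-d2 / (2 * sd_px^2))
  m[m < 0.05] <- 0
  m
}

# Irregular footprint sites by dart throwing with a minimum separation.
# Random placement (rather than a lattice) ensures no global translation can
# spuriously align many cells at once. Caller must have seeded the RNG.
.footprint_sites <- function(n_needed, min_sep = 12, margin = 8L) {
  G <- ceiling(sqrt(n_needed * min_sep^2 / 0.3)) + 2L * margin
  repeat {
    centers <- matrix(NA_real_, n_needed, 2L)
    placed <- 0L
    for (try in seq_len(60L * n_needed)) {
      p <- stats::runif(2L, margin, G - margin)
      if (placed == 0L ||
          min((centers[seq_len(placed), 1] - p[1])^2 +
                (centers[seq_len(placed), 2] - p[2])^2) >= min_sep^2) {
        placed <- placed + 1L
        centers[placed, ] <- p
        if (placed == n_needed) break
      }
    }
    if (placed == n_needed) break
    G <- ceiling(G * 1.2)
  }
  list(centers = round(centers), G = G)
}

#' Simulate a multi-day recording series with cell turnover
#'
#' Each cell survives to the next day with probability `p_survive`; survivors
#' keep their identity, speed tuning, and footprint (centroid jittered by at
#' most `footprint_jitter_px` pixels per axis), and their log mean transient
#' amplitude regresses toward the population mean with correlation `amp_rho`.
#' Surviving place cells keep their field with probability
#' `p_place_stable_day`, otherwise the field is redrawn. Non-survivors are
#' replaced by new cells at unused footprint sites, keeping the population
#' size constant.
#'
#' @param config a [sim_config()].
#' @param n_days number of consecutive days (>= 2).
#' @param seed integer seed.
#' @return list with `sessions` (one [session()] per day, footprints
#'   attached) and `ground_truth` (data.frame: `day`, `cell` index within the
#'   day's session, global `id`, tuning and amplitude columns).
#' @export
simulate_multiday <- function(config, n_days = 2L, seed = config$rng_seed) {
  if (n_days < 2L) stop("n_days must be >= 2")
  set.seed(derive_seed(seed, 11L))
  # pool sized for the expected number of replacement cells, with headroom
  n_sites <- ceiling(config$n_cells *
                       (1 + 1.3 * (1 - config$p_survive) * (n_days - 1))) + 10L
  sites <- .footprint_sites(n_sites)
  G <- sites$G
  next_site <- 0L
  take_site <- function() {
    next_site <<- next_site + 1L
    if (next_site > nrow(sites$centers)) stop("footprint site pool exhausted")
    sites$centers[next_site, ]
  }
  gt <- simulate_population(config, seed = derive_seed(seed, 1L))
  gt$site_r <- NA_integer_; gt$site_c <- NA_integer_
  for (i in seq_len(nrow(gt))) {
    s <- take_site(); gt$site_r[i] <- s[1]; gt$site_c[i] <- s[2]
  }
  next_id <- config$n_cells
  sessions <- vector("list", n_days)
  gt_days <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    set.seed(derive_seed(seed, 100L + d))
    jit <- function(ctr) {
      j <- config$footprint_jitter_px
      if (j <= 0) return(ctr)
      ctr + sample(seq(-j, j), 2L, replace = TRUE)
    }
    fps <- lapply(seq_len(nrow(gt)), function(i) {
      .make_footprint(G, jit(c(gt$site_r[i], gt$site_c[i])))
    })
    traj <- simulate_trajectory(config, seed = derive_seed(seed, 200L + d))
    sess <- render_session(gt, traj, config, seed = derive_seed(seed, 300L + d),
                           session_id = paste0("day", d), day = d,
                           footprints = fps)
    sessions[[d]] <- sess
    gt_days[[d]] <- cbind(day = d, gt[, setdiff(names(gt), c("site_r", "site_c"))])
    if (d == n_days) break
    # transition to the next day
    set.seed(derive_seed(seed, 400L + d))
    survive <- stats::runif(nrow(gt)) < config$p_survive
    nxt <- gt[survive, , drop = FALSE]
    if (nrow(nxt)) {
      mu <- config$amp_meanlog; sg <- config$amp_sdlog; rho <- config$amp_rho
      nxt$amp <- exp(mu + rho * (log(nxt$amp) - mu) +
                       sqrt(max(0, 1 - rho^2)) * sg * stats::rnorm(nrow(nxt)))
      redraw <- nxt$is_place & (stats::runif(nrow(nxt)) > config$p_place_stable_day)
      nredraw <- sum(redraw)
      if (nredraw) {
        nxt$center_cm[redraw] <- stats::runif(nredraw, 0, config$track_length_cm)
        nxt$width_cm[redraw] <- stats::runif(nredraw,
                                             config$field_width_range_cm[1],
                                             config$field_width_range_cm[2])
      }
    }
    n_new <- config$n_cells - nrow(nxt)
    if (n_new > 0) {
      cfg_new <- config
      cfg_new$n_cells <- n_new
      new_gt <- simulate_population(cfg_new, seed = derive_seed(seed, 500L + d))
      new_gt$cell <- NULL
      new_gt$id <- paste0("c", next_id + seq_len(n_new))
      next_id <- next_id + n_new
      new_gt$site_r <- NA_integer_; new_gt$site_c <- NA_integer_
      for (i in seq_len(n_new)) {
        s <- take_site(); new_gt$site_r[i] <- s[1]; new_gt$site_c[i] <- s[2]
      }
      nxt$cell <- NULL
      gt <- rbind(nxt, new_gt)
    } else {
      gt <- nxt
      gt$cell <- NULL
    }
    gt <- cbind(cell = seq_len(nrow(gt)), gt)
    rownames(gt) <- NULL
  }
  ground_truth <- do.call(rbind, gt_days)
  rownames(ground_truth) <- NULL
  list(sessions = sessions, ground_truth = ground_truth)
}
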