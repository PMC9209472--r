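test_that("trajectories are bounded, bout-structured, and cover the enclosure", {
  fr <- vapply(1:10, function(s) {
    cfg <- sim_config(rng_seed = s)
    tr <- simulate_trajectory(cfg, seed = s)
    expect_true(all(tr$x >= 0 & tr$x <= 70))
    expect_true(all(tr$speed >= 0))
    expect_length(tr$x, 9000L)
    mean(tr$speed > 3)
  }, numeric(1))
  # both sub- and supra-threshold epochs exist in reasonable proportion
  expect_true(all(fr >= 0.3 & fr <= 0.9))
})

test_that("zero-drive, zero-noise trajectory stays put", {
  cfg <- sim_config(duration_s = 60, rng_seed = 1)
  tr <- simulate_trajectory(cfg, run_speed_range = c(0, 0), speed_noise = 0)
  expect_equal(stats::var(tr$x), 0)
  expect_equal(tr$speed, rep(0, length(tr$speed)))
  expect_error(simulate_trajectory(sim_config(track_length_cm = 6)),
               "track length")
})

test_that("occupancy covers at least 90% of spatial bins on default sessions", {
  cfg0 <- analysis_config()
  for (s in 1:5) {
    sim <- suppressWarnings(simulate_session(sim_config(n_cells = 2, rng_seed = s)))
    beh <- behavior_series(sim$session, cfg0)
    am <- compute_activity_map(sim$session$traces[1, ], beh, 70, 9, cfg0,
                               smooth = FALSE)
    expect_gte(mean(am$occupancy > 0), 0.9)
  }
})

test_that("population draws honor configured fractions and remap labels", {
  cfg <- sim_config(n_cells = 100, fraction_place_cells = 0.5, rng_seed = 5)
  gt <- simulate_population(cfg)
  expect_equal(sum(gt$is_place), 50L)
  expect_true(all(is.na(gt$center_cm[!gt$is_place])))

  cfg2 <- sim_config(n_cells = 80, fraction_speed_pos = 0, rng_seed = 6)
  gt2 <- simulate_population(cfg2)
  expect_false(any(gt2$speed_class == "positive"))

  cfg3 <- sim_config(n_cells = 60, fraction_place_cells = 1, p_rotate = 1,
                     p_stable = 0, rng_seed = 7)
  pair <- suppressWarnings(simulate_manipulation_pair(cfg3, "rotate180"))
  g <- pair$ground_truth
  expect_equal(g$center2_cm, 70 - g$center1_cm, tolerance = 1e-12)
})

test_that("rendering is exactly bookkept and respects degenerate configs", {
  cfg <- sim_config(n_cells = 3, duration_s = 100, noise_sd = 0,
                    fraction_place_cells = 0, fraction_speed_pos = 0,
                    fraction_speed_neg = 0, rng_seed = 8)
  traj <- simulate_trajectory(cfg)
  gt <- simulate_population(cfg)
  gt$baseline_rate <- rep(1e-9, 3)   # effectively zero drive
  ses <- render_session(gt, traj, cfg)
  expect_equal(max(abs(ses$traces)), 0)

  # latent bookkeeping: each trace is the transient-filtered latent onsets
  cfg2 <- sim_config(n_cells = 5, duration_s = 200, rng_seed = 9)
  sim <- suppressWarnings(simulate_session(cfg2))
  lat <- attr(sim$session, "latent_events")
  expect_length(lat, 5L)
  for (i in 1:5) {
    expect_true(all(lat[[i]] >= 1 & lat[[i]] <= ncol(sim$session$traces)))
  }
})

test_that("place-field rate gain raises in-field activity", {
  cfg <- sim_config(n_cells = 1, duration_s = 400, fraction_place_cells = 1,
                    fraction_speed_pos = 0, fraction_speed_neg = 0,
                    noise_sd = 0, rng_seed = 10)
  traj <- simulate_trajectory(cfg)
  gt <- simulate_population(cfg)
  ses <- render_session(gt, traj, cfg)
  infield <- abs(traj$x - gt$center_cm[1]) < gt$width_cm[1]
  outfield <- abs(traj$x - gt$center_cm[1]) > 3 * gt$width_cm[1]
  expect_gt(mean(ses$traces[1, infield]), mean(ses$traces[1, outfield]))
})

test_that("manipulation pairs transform second-half tuning by kind", {
  cfg <- sim_config(n_cells = 30, duration_s = 300, fraction_place_cells = 1,
                    p_rotate = 0, p_stable = 1, rng_seed = 11)
  short <- suppressWarnings(simulate_manipulation_pair(cfg, "med_short"))
  g <- short$ground_truth
  expect_equal(g$width2_cm, 0.5 * g$width1_cm, tolerance = 1e-12)
  expect_equal(g$center2_cm, 0.5 * g$center1_cm, tolerance = 1e-12)
  long <- suppressWarnings(simulate_manipulation_pair(cfg, "med_long"))
  expect_equal(long$ground_truth$center2_cm,
               1.5 * long$ground_truth$center1_cm, tolerance = 1e-12)
  rot <- suppressWarnings(simulate_manipulation_pair(cfg, "rotate180"))
  expect_equal(rot$ground_truth$center2_cm, rot$ground_truth$center1_cm)
  expect_error(simulate_manipulation_pair(cfg, "spin"), "kind")
  # halves carry their own track lengths; the gap is flagged for removal
  expect_equal(short$session$meta$track_length_cm, c(70, 35))
  ri <- short$session$removed_interval
  expect_equal(ri[2] - ri[1] + 1L, round(22 * 7.5))
})

test_that("multiday survival, identity, and amplitude persistence behave", {
  # p_survive = 1, jitter 0: identical footprints, identity matching
  cfg <- sim_config(n_cells = 20, duration_s = 200, p_survive = 1,
                    footprint_jitter_px = 0, amp_rho = 1, rng_seed = 12)
  md <- suppressWarnings(simulate_multiday(cfg, n_days = 2))
  expect_identical(md$sessions[[1]]$footprints, md$sessions[[2]]$footprints)
  g1 <- md$ground_truth[md$ground_truth$day == 1, ]
  g2 <- md$ground_truth[md$ground_truth$day == 2, ]
  expect_identical(g1$id, g2$id)
  # amp_rho = 1: amplitudes perfectly correlated (identical) across days
  expect_equal(stats::cor(g1$amp, g2$amp, method = "spearman"), 1)

  # mean survival tracks p_survive across seeds
  surv <- vapply(1:8, function(s) {
    cfg2 <- sim_config(n_cells = 120, duration_s = 100, p_survive = 0.5,
                       rng_seed = 100 + s)
    m <- suppressWarnings(simulate_multiday(cfg2, n_days = 2))
    gt <- m$ground_truth
    length(intersect(gt$id[gt$day == 1], gt$id[gt$day == 2])) / 120
  }, numeric(1))
  expect_lt(abs(mean(surv) - 0.5), 0.05)
  expect_error(simulate_multiday(sim_config(), n_days = 1), "n_days")
})
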