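test_that("peaks are detected with amplitudes, widths, and rates", {
  rate <- 10
  # single triangular bump of height 1 on a tiny-noise baseline
  tri <- c(rep(0, 20), seq(0, 1, length.out = 6), seq(1, 0, length.out = 6)[-1],
           rep(0, 20))
  pk <- detect_peaks(tri, rate)
  expect_equal(length(pk$peak_indices), 1L)
  expect_equal(pk$peak_amplitudes, 1)
  # two identical bumps over 20 s -> 0.1 peaks/s
  bump <- c(rep(0, 40), seq(0, 1, length.out = 6), seq(1, 0, length.out = 6)[-1])
  two <- c(bump, bump, rep(0, 200 - 2 * length(bump)))
  pk2 <- detect_peaks(two, rate)
  expect_equal(pk2$peak_rate, 2 / 20)
  # flat trace: zero peaks, flagged undefined amplitude
  flat <- detect_peaks(rep(1, 50), rate)
  expect_equal(flat$peak_rate, 0)
  expect_true(flat$undefined)
})

test_that("peak detection is amplitude-scale covariant", {
  set.seed(13)
  cfg <- sim_config(n_cells = 1, duration_s = 300, rng_seed = 13)
  sim <- suppressWarnings(simulate_session(cfg))
  tr <- sim$session$traces[1, ]
  a <- detect_peaks(tr, 7.5)
  b <- detect_peaks(3 * tr, 7.5)
  expect_equal(b$peak_indices, a$peak_indices)
  expect_equal(b$peak_amplitudes, 3 * a$peak_amplitudes)
  expect_equal(b$peak_widths, a$peak_widths)
})

test_that("detected peak counts track the generator's latent events", {
  hits <- vapply(1:8, function(s) {
    cfg <- sim_config(n_cells = 1, duration_s = 600, noise_sd = 0.05,
                      fraction_place_cells = 0, fraction_speed_pos = 0,
                      fraction_speed_neg = 0, rng_seed = 200 + s)
    sim <- suppressWarnings(simulate_session(cfg))
    truth <- length(attr(sim$session, "latent_events")[[1]])
    det <- length(detect_peaks(sim$session$traces[1, ], 7.5)$peak_indices)
    abs(det - truth) / truth
  }, numeric(1))
  expect_lt(mean(hits), 0.1)
})

test_that("peak-to-noise ratio recovers a constructed signal-to-noise level", {
  set.seed(14)
  n <- 9000
  noise <- stats::rnorm(n, 0, 1)
  tr <- noise
  at <- seq(200, n - 200, by = 450)
  for (i in at) tr[i + 0:5] <- tr[i + 0:5] + 10 * exp(-(0:5) / 2)
  res <- peak_to_noise_ratio(tr, 7.5)
  expect_equal(res$pnr, 10, tolerance = 0.2 * 10)
  # homogeneity of the peak term: at low noise, doubling the transient
  # amplitude doubles the ratio
  lo <- stats::rnorm(n, 0, 0.1)
  mk <- function(a) {
    t2 <- lo
    for (i in at) t2[i + 0:5] <- t2[i + 0:5] + a * exp(-(0:5) / 2)
    peak_to_noise_ratio(t2, 7.5)$pnr
  }
  expect_equal(mk(20) / mk(10), 2, tolerance = 0.05)
  # no peaks -> flagged undefined
  resf <- peak_to_noise_ratio(rep(0, 100), 7.5)
  expect_true(resf$undefined)
})

test_that("interneuron-like archetype shows higher peak rate and width", {
  wins_rate <- 0L; wins_width <- 0L
  n_pairs <- 20L
  for (s in seq_len(n_pairs)) {
    cc <- sim_config(n_cells = 4, duration_s = 300, cell_type = "CAMK2A",
                     fraction_place_cells = 0, fraction_speed_pos = 0,
                     fraction_speed_neg = 0, rng_seed = 300 + s)
    cv <- sim_config(n_cells = 4, duration_s = 300, cell_type = "VGAT",
                     fraction_place_cells = 0, fraction_speed_pos = 0,
                     fraction_speed_neg = 0, rng_seed = 300 + s)
    pc <- session_peak_stats(suppressWarnings(simulate_session(cc))$session)
    pv <- session_peak_stats(suppressWarnings(simulate_session(cv))$session)
    wins_rate <- wins_rate + (mean(pv$peak_rate) > mean(pc$peak_rate))
    wins_width <- wins_width + (mean(pv$mean_peak_width, na.rm = TRUE) >
                                  mean(pc$mean_peak_width, na.rm = TRUE))
  }
  expect_gte(wins_rate / n_pairs, 0.95)
  expect_gte(wins_width / n_pairs, 0.95)
})
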