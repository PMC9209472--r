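# Shared fixtures: small seeded simulations built in code.

# A quick default session (40 cells, 20 min) cached per test file run.
quick_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_cells = 40, rng_seed = 101)
      cache <<- suppressWarnings(simulate_session(cfg))
    }
    cache
  }
})

# Untuned population: no place or speed tuning.
untuned_config <- function(n_cells, seed, duration_s = 600) {
  sim_config(n_cells = n_cells, duration_s = duration_s,
             fraction_place_cells = 0, fraction_speed_pos = 0,
             fraction_speed_neg = 0, rng_seed = seed)
}

# White-noise traces on a simulated behavioral session: the null construction
# for classifier calibration (position-independent, speed-independent).
white_noise_session <- function(n_cells, seed, duration_s = 600) {
  cfg <- untuned_config(1L, seed, duration_s)
  sim <- suppressWarnings(simulate_session(cfg))
  ses <- sim$session
  set.seed(seed + 7L)
  ses$traces <- matrix(stats::rnorm(n_cells * ncol(ses$traces)), n_cells)
  ses
}

# True matching pairs (row indices per day) from multiday ground truth.
true_pairs <- function(ground_truth, day_i, day_j) {
  gi <- ground_truth[ground_truth$day == day_i, ]
  gj <- ground_truth[ground_truth$day == day_j, ]
  merge(data.frame(i = seq_len(nrow(gi)), id = gi$id),
        data.frame(j = seq_len(nrow(gj)), id = gj$id))
}
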