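mk_map <- function(m) {
  structure(list(map = m, occupancy = matrix(1L, nrow(m), ncol(m)),
                 smoothed = TRUE,
                 x_edges = seq(0, ncol(m) * 3.5, 3.5),
                 y_edges = seq(0, nrow(m) * 3.5, 3.5),
                 x_centers = seq(1.75, by = 3.5, length.out = ncol(m))),
            class = "activity_map")
}

test_that("flattening takes column maxima and keeps track length", {
  m <- matrix(stats::runif(60), 3, 20)
  p <- flatten_map(mk_map(m))
  expect_length(p, 20L)
  expect_equal(p, apply(m, 2, max))
  expect_equal(flatten_map(mk_map(matrix(2, 3, 20))), rep(2, 20))
  m2 <- matrix(0, 3, 20); m2[2, 7] <- 5
  expect_equal(which.max(flatten_map(mk_map(m2))), 7L)
  # unoccupied column -> NA, excluded pairwise
  m3 <- matrix(1:60 / 10, 3, 20); m3[, 4] <- NA
  am <- mk_map(m3); am$occupancy[, 4] <- 0L
  expect_true(is.na(flatten_map(am)[4]))
})

test_that("profile correlation handles resampling and matches a rank oracle", {
  expect_equal(rate_map_correlation(1:20 / 2, 1:20 / 2), 1)
  p <- stats::runif(20)
  expect_equal(rate_map_correlation(sort(p), rev(sort(p))), -1)
  # exact 2x spatial compression: resampling recovers the shape
  long <- exp(-((1:20) - 8)^2 / 8)
  short <- exp(-((1:10) - 4)^2 / 2)   # same relative center/width on 10 bins
  expect_gte(rate_map_correlation(long, short), 0.95)
  # brute-force rank-correlation oracle on random pairs
  set.seed(23)
  for (rep in 1:50) {
    a <- stats::rnorm(20); b <- stats::rnorm(20)
    oracle <- stats::cor(rank(a), rank(b))
    expect_equal(rate_map_correlation(a, b), oracle, tolerance = 1e-12)
  }
  r <- rate_map_correlation(c(1, 2, NA, NA), c(NA, 1, 2, NA))
  expect_true(is.na(r))
})

test_that("rotation category follows the thirds geometry", {
  expect_equal(classify_rotation(5, TRUE, 65, 70), "rotate")
  expect_equal(classify_rotation(5, TRUE, 6, 70), "non_rotate")
  expect_equal(classify_rotation(35, TRUE, 5, 70), "middle_excluded")
  expect_equal(classify_rotation(5, FALSE, NA, 70), "lost")
  expect_equal(classify_rotation(5, TRUE, 35, 70), "lost")
  expect_error(classify_rotation(5, TRUE, 65, 0), "positive")
})

test_that("shuffle chance is seeded, reproducible, and self-consistent", {
  set.seed(24)
  prof1 <- lapply(1:15, function(i) stats::runif(20))
  prof2 <- lapply(1:15, function(i) stats::runif(20))
  cfg <- analysis_config(rng_seed = 5L)
  ch1 <- correlation_chance(prof1, prof2, n_iter = 200, config = cfg)
  ch2 <- correlation_chance(prof1, prof2, n_iter = 200, config = cfg)
  expect_identical(ch1$threshold, ch2$threshold)
  # independent random profiles: observed mean r below the 95th percentile
  obs <- mean(vapply(1:15, function(i) {
    as.numeric(rate_map_correlation(prof1[[i]], prof2[[i]]))
  }, numeric(1)))
  expect_lt(obs, ch1$threshold)
  # identical profiles: observed r = 1 above chance
  chi <- correlation_chance(prof1, prof1, n_iter = 200, config = cfg)
  expect_lt(chi$threshold, 1)
})

test_that("width change is restricted to dual-half place cells", {
  cfg <- sim_config(n_cells = 25, duration_s = 500, fraction_place_cells = 1,
                    p_rotate = 0, p_stable = 1, rng_seed = 25)
  pair <- suppressWarnings(simulate_manipulation_pair(cfg, "med_med"))
  hp <- analyze_half_pair(pair$session, n_iter_chance = 20)
  wc <- field_width_change(hp)
  both <- hp$cells$is_place1 & hp$cells$is_place2
  expect_true(all(wc$cell %in% hp$cells$cell[both]))
  # identical tuning across halves: median change centered near zero
  expect_lte(abs(stats::median(wc$width_change_cm)), 3.5)
})
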