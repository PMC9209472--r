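test_that("matching handles identity, disjoint, and empty footprint sets", {
  set.seed(30)
  cfg <- sim_config(n_cells = 15, duration_s = 100, p_survive = 1,
                    footprint_jitter_px = 0, rng_seed = 30)
  md <- suppressWarnings(simulate_multiday(cfg, n_days = 2))
  fps <- md$sessions[[1]]$footprints
  m <- match_cells(fps, fps)
  expect_equal(m$pairs$i, m$pairs$j)
  expect_equal(nrow(m$pairs), 15L)
  expect_equal(m$pairs$iou, rep(1, 15))
  # genuinely disjoint locations: the two sets occupy separate grid regions
  G <- 140L
  left <- lapply(seq(15, 125, by = 15), function(r) {
    placecode:::.make_footprint(G, c(r, 30L))
  })
  right <- lapply(seq(15, 125, by = 15), function(r) {
    placecode:::.make_footprint(G, c(r, 110L))
  })
  m2 <- match_cells(left, right, max_align_shift_px = 2L)
  expect_equal(nrow(m2$pairs), 0L)
  m3 <- match_cells(list(), fps)
  expect_equal(nrow(m3$pairs), 0L)
})

test_that("matching is symmetric under swapped roles", {
  cfg <- sim_config(n_cells = 40, duration_s = 100, p_survive = 0.5,
                    rng_seed = 31)
  md <- suppressWarnings(simulate_multiday(cfg, n_days = 2))
  f1 <- md$sessions[[1]]$footprints; f2 <- md$sessions[[2]]$footprints
  ab <- match_cells(f1, f2)
  ba <- match_cells(f2, f1)
  expect_setequal(paste(ab$pairs$i, ab$pairs$j), paste(ba$pairs$j, ba$pairs$i))
})

test_that("turnover fractions use the documented denominators", {
  cfg <- sim_config(n_cells = 12, duration_s = 100, p_survive = 1,
                    footprint_jitter_px = 0, rng_seed = 32)
  md <- suppressWarnings(simulate_multiday(cfg, n_days = 2))
  m <- match_cells(md$sessions[[1]]$footprints, md$sessions[[2]]$footprints)
  tv <- turnover_fraction(m)
  expect_equal(tv$fraction, 1)
  empty <- match_cells(list(), list())
  expect_error(turnover_fraction(empty), "positive")
  expect_equal(turnover_fraction(empty, 10, 10)$fraction, 0)
})

test_that("matched correlations recover persistence and collapse when scrambled", {
  cfg <- sim_config(n_cells = 80, duration_s = 400, p_survive = 1,
                    amp_rho = 0.8, rng_seed = 33)
  md <- suppressWarnings(simulate_multiday(cfg, n_days = 2))
  m <- match_cells(md$sessions[[1]]$footprints, md$sessions[[2]]$footprints)
  cv <- coregistration_validation(md$sessions[[1]], md$sessions[[2]], m,
                                  n_perm = 200)
  expect_gt(cv$amplitude$r, cv$amplitude$chance)
  expect_false(cv$amplitude$low_power)
  # deliberately scrambled matching: correlation at or below chance
  ms <- m
  set.seed(34)
  ms$pairs$j <- sample(ms$pairs$j)
  cvs <- coregistration_validation(md$sessions[[1]], md$sessions[[2]], ms,
                                   n_perm = 200)
  expect_lt(cvs$amplitude$r, cv$amplitude$r)
  expect_lt(cvs$amplitude$r, cvs$amplitude$chance + 0.2)
})

test_that("a session duplicated as both days gives perfect stability", {
  sim <- quick_sim()
  ses <- sim$session
  set.seed(35)
  G <- 120L
  sites <- placecode:::.footprint_sites(nrow(ses$traces))
  ses$footprints <- lapply(seq_len(nrow(ses$traces)), function(i) {
    placecode:::.make_footprint(sites$G, sites$centers[i, ])
  })
  m <- match_cells(ses$footprints, ses$footprints)
  st <- across_day_stability(ses, ses, m, n_perm = 100)
  expect_equal(st$mi$r, 1)
  expect_equal(st$speed$r, 1)
  expect_true(all(st$map_r[!is.na(st$map_r)] == 1))
  expect_gte(st$n_matched_place, 1L)
})
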