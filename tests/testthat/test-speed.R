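test_that("position regression removes exactly the binned position effect", {
  sim <- quick_sim()
  cfg <- analysis_config()
  beh <- behavior_series(sim$session, cfg)
  xb <- findInterval(beh$x, seq(0, 70, 3.5), rightmost.closed = TRUE,
                     all.inside = TRUE)
  lut <- stats::runif(20)
  # trace exactly a function of position bin -> residual ~ 0
  resid <- regress_out_position(lut[xb], beh$x, 70, cfg)
  expect_lt(max(abs(resid)), 1e-8)
  # position-independent trace -> residual ~ trace - bin means ~ centered
  set.seed(18)
  tr <- stats::rnorm(length(beh$x))
  r2 <- regress_out_position(tr, beh$x, 70, cfg)
  expect_equal(mean(r2), 0, tolerance = 1e-10)
  expect_gt(stats::cor(r2, tr), 0.99)
  expect_warning(r3 <- regress_out_position(tr, rep(1, length(tr)), 70, cfg),
                 "constant position")
  expect_equal(r3, tr - mean(tr))
})

test_that("additive position + speed construction leaves the speed effect intact", {
  devs <- vapply(1:5, function(s) {
    cfg <- untuned_config(1L, 600 + s, duration_s = 600)
    sim <- suppressWarnings(simulate_session(cfg))
    beh <- behavior_series(sim$session)
    set.seed(s)
    pure_speed <- 0.3 * beh$speed + stats::rnorm(length(beh$speed))
    xb <- findInterval(beh$x, seq(0, 70, 3.5), rightmost.closed = TRUE,
                       all.inside = TRUE)
    lut <- stats::runif(20, 0, 5)
    mixed <- pure_speed + lut[xb]
    r_pure <- stats::cor(pure_speed, beh$speed, method = "spearman")
    r_mixed <- stats::cor(regress_out_position(mixed, beh$x, 70), beh$speed,
                          method = "spearman")
    abs(r_mixed - r_pure)
  }, numeric(1))
  expect_lt(mean(devs), 0.05)
})

test_that("speed-cell classification hits the exact positive/negative contract", {
  sim <- quick_sim()
  beh <- behavior_series(sim$session)
  ses <- sim$session
  # residuals equal to +speed and -speed after position regression is
  # approximate; instead drive traces hard with speed
  ses$traces <- rbind(beh$speed, -beh$speed, ses$traces[1, ])
  sc <- classify_speed_cells(ses, beh)
  expect_equal(sc$class[1:2], c("positive", "negative"))
  expect_gt(sc$spearman_r[1], 0.8)
  expect_lt(sc$spearman_r[2], -0.8)
  # invariance to monotone transforms of the driving signal (Spearman)
  ses$traces[1, ] <- log1p(beh$speed)^2
  sc2 <- classify_speed_cells(ses, beh)
  expect_equal(sc2$class[1], "positive")
})

test_that("split consistency detects stationary speed tuning", {
  cfg <- sim_config(n_cells = 40, fraction_place_cells = 0,
                    fraction_speed_pos = 0.4, fraction_speed_neg = 0.4,
                    rng_seed = 21)
  sim <- suppressWarnings(simulate_session(cfg))
  for (split in c("left_right", "half_half")) {
    res <- split_consistency(sim$session, split)
    expect_gt(res$consistency_r, 0.5)
    expect_length(res$r1, 40L)
  }
})

test_that("decoding blocks alternate train/test with a 10 s guard", {
  role <- placecode:::.decode_blocks(9000L, 7.5, 60, 10)
  t <- (0:8999) / 7.5
  expect_true(all(role[t < 60] == "train"))
  expect_true(all(role[t >= 60 & t < 70] == "guard"))
  expect_true(all(role[t >= 70 & t < 130] == "test"))
  # train/test sets disjoint and separated by at least 10 s
  tr <- t[role == "train"]; te <- t[role == "test"]
  gap <- min(vapply(te, function(x) min(abs(x - tr)), numeric(1)))
  expect_gte(gap, 10 - 1 / 7.5 + 1e-9)
})

test_that("an oracle predictor decodes speed nearly perfectly", {
  sim <- quick_sim()
  beh <- behavior_series(sim$session)
  # position made uninformative so the position regression cannot absorb any
  # of the injected speed signal
  set.seed(22)
  beh$x <- stats::runif(length(beh$x), 0, 70)
  ses <- sim$session
  ses$traces <- rbind(beh$speed,
                      matrix(stats::rnorm(3 * length(beh$speed), sd = 1e-3), 3))
  cfg <- analysis_config(decode_n_iter = 5L)
  dec <- decode_speed(ses, n_subsample = 4L, behavior = beh, config = cfg)
  expect_gte(dec$mean_r, 0.99)
  expect_gt(dec$mean_r, dec$chance_threshold)
  expect_error(decode_speed(ses, n_subsample = 10L, behavior = beh,
                            config = cfg), "fewer")
})

test_that("session exclusion flags path lengths 1 SD below the cohort mean", {
  pl <- c(100, 110, 105, 95, 40)
  fl <- flag_low_path_sessions(pl)
  expect_equal(which(fl), 5L)
})
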