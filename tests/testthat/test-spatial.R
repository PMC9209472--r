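test_that("Sturges' rule bin counts", {
  expect_equal(sturges_bins(256), 9L)
  expect_equal(sturges_bins(1), 1L)
  expect_equal(sturges_bins(1000), 11L)
  expect_error(sturges_bins(0), "n must be")
})

test_that("mutual information matches the brute-force double-sum oracle", {
  set.seed(15)
  for (rep in 1:20) {
    n <- sample(200:600, 1)
    x <- stats::runif(n, 0, 70)
    y <- stats::rnorm(n) + 0.05 * x * stats::rbinom(1, 1, 0.5)
    mask <- rep(TRUE, n)
    mi <- mutual_information(y, x, mask, 70)
    xe <- seq(0, 70, by = 3.5)
    xb <- findInterval(x, xe, rightmost.closed = TRUE, all.inside = TRUE)
    expect_equal(mi, mi_oracle(y, xb), tolerance = 1e-12)
  }
})

test_that("mutual information obeys its defining identities", {
  # independent X, Y constructed as an exact outer product
  x <- rep(c(1.75, 5.25), each = 50)
  y <- rep(c(0, 1), times = 50)
  expect_equal(mutual_information(y, x, rep(TRUE, 100), 7), 0, tolerance = 1e-12)
  # perfectly dependent binary variables -> 1 bit
  y2 <- ifelse(x < 3.5, 0, 1)
  expect_equal(mutual_information(y2, x, rep(TRUE, 100), 7), 1, tolerance = 1e-12)
  # non-negativity and entropy bound on random cases; relabeling invariance
  set.seed(16)
  for (rep in 1:10) {
    n <- 400
    x <- stats::runif(n, 0, 70)
    y <- stats::rnorm(n, sd = 0.5) + sin(x / 10)
    mi <- mutual_information(y, x, rep(TRUE, n), 70)
    expect_gte(mi, 0)
    xb <- findInterval(x, seq(0, 70, 3.5), rightmost.closed = TRUE,
                       all.inside = TRUE)
    hx <- -sum(prop.table(table(xb)) * log2(prop.table(table(xb))))
    expect_lte(mi, hx + 1e-12)
    # mirroring position relabels the bins without changing MI
    expect_equal(mutual_information(y, 70 - x, rep(TRUE, n), 70), mi,
                 tolerance = 1e-9)
  }
  expect_warning(mi0 <- mutual_information(rnorm(50), rep(1, 50),
                                           rep(TRUE, 50), 70), "single")
  expect_equal(mi0, 0)
})

test_that("activity maps occupancy-normalize and conserve mass", {
  sim <- quick_sim()
  cfg <- analysis_config()
  beh <- behavior_series(sim$session, cfg)
  # constant trace: every occupied bin equals the constant, smoothed or not
  const <- rep(2.5, ncol(sim$session$traces))
  for (sm in c(FALSE, TRUE)) {
    am <- compute_activity_map(const, beh, 70, 9, cfg, smooth = sm)
    expect_equal(range(am$map[!is.na(am$map)]), c(2.5, 2.5), tolerance = 1e-12)
  }
  # conservation: unsmoothed map x occupancy sums to total masked df/F
  tr <- sim$session$traces[3, ]
  am <- compute_activity_map(tr, beh, 70, 9, cfg, smooth = FALSE)
  lhs <- sum(am$map * am$occupancy, na.rm = TRUE)
  rhs <- sum(tr[beh$movement_mask])
  expect_equal(lhs, rhs, tolerance = 1e-9 * abs(rhs))
})

test_that("circular shifting preserves the trace's marginal histogram", {
  sim <- quick_sim()
  tr <- sim$session$traces[1, ]
  off <- placecode:::shift_offsets(length(tr), 100L)
  expect_length(off, 100L)
  expect_equal(off[100], length(tr))   # identity shift is part of the null
  sh <- placecode:::circular_shift(tr, off[37])
  expect_equal(sort(sh), sort(tr))
})

test_that("a deterministic position code is classified as a place cell", {
  sim <- quick_sim()
  cfg <- analysis_config()
  beh <- behavior_series(sim$session, cfg)
  ses <- sim$session
  # trace that is a pure function of the position bin
  xb <- findInterval(beh$x, seq(0, 70, 3.5), rightmost.closed = TRUE,
                     all.inside = TRUE)
  set.seed(17)
  lut <- stats::runif(20)
  ses$traces <- rbind(lut[xb], ses$traces[1, ])
  pc <- classify_place_cells(ses, beh, cfg)
  expect_true(pc$is_place[1])
  expect_equal(pc$mi[1], max(pc$mi[1], attr(pc, "null")[1, ]))
})

test_that("place fields are segmented with 4-connectivity and sized in cm", {
  mk_map <- function(m, occ = NULL) {
    if (is.null(occ)) occ <- matrix(1L, nrow(m), ncol(m))
    structure(list(map = m, occupancy = occ, smoothed = TRUE,
                   x_edges = seq(0, ncol(m) * 3.5, 3.5),
                   y_edges = seq(0, nrow(m) * 3.5, 3.5),
                   x_centers = seq(1.75, by = 3.5, length.out = ncol(m))),
              class = "activity_map")
  }
  # 4 contiguous bins above threshold -> one field of 49 cm^2
  m <- matrix(0, 3, 20)
  m[2, 5:8] <- 10
  f <- detect_place_fields(mk_map(m))
  expect_equal(nrow(f), 1L)
  expect_equal(f$size_cm2, 4 * 12.25)
  expect_equal(f$width_cm, 4 * 3.5)
  # two bins touching only at a corner -> two fields
  m2 <- matrix(0, 3, 20)
  m2[1, 5] <- 10; m2[2, 6] <- 9
  f2 <- detect_place_fields(mk_map(m2))
  expect_equal(nrow(f2), 2L)
  expect_equal(f2$center_cm[1], 4 * 3.5 + 1.75)  # primary = higher peak
  # constant map: nothing exceeds mean + 1.5 sd -> empty table
  f3 <- detect_place_fields(mk_map(matrix(5, 3, 20)))
  expect_equal(nrow(f3), 0L)
})

test_that("detected field width grows with the generator's tuning width", {
  # tuning sd values inside the method's informative range: because the
  # 1.5-sd field threshold adapts to the map, detected widths saturate once
  # fields span more than ~1/5 of the track (sigma above ~5 cm)
  widths <- vapply(c(2, 3.5, 5), function(w) {
    per_seed <- vapply(1:6, function(s) {
      cfg <- sim_config(n_cells = 12, duration_s = 500, fraction_place_cells = 1,
                        field_width_range_cm = c(w, w), rng_seed = 520 + s)
      sim <- suppressWarnings(simulate_session(cfg))
      pa <- session_place_analysis(sim$session)
      mean(pa$cells$width_cm, na.rm = TRUE)
    }, numeric(1))
    mean(per_seed)
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})
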