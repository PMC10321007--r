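test_that("hand-enumerated steep decline starts after k_consec steps", {
  g <- time_grid()
  # flat at 20 um, then steady 2 um/min approach for 10 min from onset
  f <- 0:119
  d <- ifelse(f <= 29, 20, pmax(20 - 2 * (f - 29), 0))
  tr <- cell_track("c", "o", d, g)
  est <- detect_start_heuristic(tr, g)
  # hand enumeration: criterion 1 first met at t = 32 (three decreasing
  # steps 30,31,32); criteria 2 and 3 already hold there; 32 - 29 = 3 min
  expect_equal(est$start_min, 3)
})

test_that("non-approaching series yield infinite starts", {
  g <- time_grid()
  inc <- cell_track("c", "o", seq(5, by = 0.05, length.out = 120), g)
  expect_true(is.infinite(detect_start_heuristic(inc, g)$start_min))

  alt <- cell_track("c", "o", 20 + 0.05 * (-1)^(0:119), g)
  expect_true(is.infinite(detect_start_heuristic(alt, g)$start_min))
})

test_that("detector is translation- and scale-invariant", {
  set.seed(61)
  sim <- simulate_accumulation(sim_params(organelles_per_cell = 4, seed = 17))
  g <- sim$tracks$grid
  for (tr in sim$tracks$tracks) {
    base <- detect_start_heuristic(tr, g)$start_min
    shifted <- cell_track("c", "o", tr$distances + 7.3, g)
    scaled <- cell_track("c", "o", tr$distances * 2.6, g)
    expect_equal(detect_start_heuristic(shifted, g)$start_min, base)
    expect_equal(detect_start_heuristic(scaled, g)$start_min, base)
  }
})

test_that("noiseless lagged pulses are detected within k_consec of the lag", {
  k <- heuristic_params()$k_consec
  for (lag_d0 in c(5, 12, 20)) {
    # organelles reach the beam and stop: the zero-floor diagnostic is expected
    sim <- suppressWarnings(simulate_accumulation(sim_params(
      organelles_per_cell = 1, initial_distances = lag_d0, signal_speed = 1,
      sigma_w = 0, sigma_y = 0, beta_profile = pulse_profile(depth = 1),
      seed = 3)))
    g <- sim$tracks$grid
    est <- detect_start_heuristic(sim$tracks$tracks[[1]], g)
    expect_gte(est$start_min, lag_d0)
    expect_lte(est$start_min, lag_d0 + k)
  }
})

test_that("horizon overrun leaves criterion 3 undefined, not an error", {
  g <- time_grid(n_frames = 40, onset = 20)
  # decline begins so late that the look-ahead never fits
  f <- 0:39
  d <- ifelse(f <= 35, 10, 10 - 0.5 * (f - 35))
  tr <- cell_track("c", "o", d, g)
  p <- heuristic_params(k_consec = 2, ma_window = 5, horizon = 13)
  expect_true(is.infinite(detect_start_heuristic(tr, g, p)$start_min))
})

test_that("grid search returns the self-consistent optimum", {
  sim <- simulate_accumulation(sim_params(organelles_per_cell = 6, seed = 23))
  g <- sim$tracks$grid
  defaults <- heuristic_params()
  det <- vapply(sim$tracks$tracks, function(tr)
    detect_start_heuristic(tr, g, defaults)$start_min, numeric(1))
  # annotate each track with the detector's own output at the defaults
  tracks <- track_set(g, lapply(seq_along(sim$tracks$tracks), function(i) {
    tr <- sim$tracks$tracks[[i]]
    cell_track(tr$cell_id, tr$organelle_id, tr$distances, g,
               visual_start = det[i])
  }))

  single <- grid_search_params(tracks, grids = list(k_consec = 3))
  expect_equal(single$params$k_consec, 3L)
  expect_equal(single$rmse, 0)

  multi <- grid_search_params(tracks, grids = list(
    k_consec = c(2, 3, 4), ma_window = c(5, 9), fold = c(1.0, 1.5, 2.5)))
  expect_equal(multi$rmse, 0)
  # the winner reproduces every annotation exactly
  redet <- vapply(tracks$tracks, function(tr)
    detect_start_heuristic(tr, g, multi$params)$start_min, numeric(1))
  expect_equal(redet, det)
  # deterministic tie-break: rerunning gives the identical tuple
  again <- grid_search_params(tracks, grids = list(
    k_consec = c(2, 3, 4), ma_window = c(5, 9), fold = c(1.0, 1.5, 2.5)))
  expect_identical(unclass(multi$params), unclass(again$params))
})

test_that("grid search rejects an unusable annotation set", {
  g <- time_grid()
  tr <- make_track(rep(0, 119), 10, g)
  expect_error(grid_search_params(track_set(g, list(tr))), "visual")
})
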