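test_that("identical configs give bit-identical videos and truth", {
  cfg <- simulation_config(frame_shape = c(64, 64), n_frames = 5,
                           n_cells = 4, motion_model = "random_walk",
                           eye_motion_sigma_px = 2, rng_seed = 99)
  a <- simulate_cell_video(cfg)
  b <- simulate_cell_video(cfg)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)
  expect_identical(a$shifts, b$shifts)
})

test_that("empty field is background plus noise with empty truth", {
  cfg <- simulation_config(frame_shape = c(48, 48), n_frames = 3,
                           n_cells = 0, noise_sigma = 0, rng_seed = 1)
  sim <- simulate_cell_video(cfg)
  expect_equal(nrow(sim$truth), 0)
  # without noise or motion, all frames are the identical background
  expect_identical(sim$stack$frames[[1]], sim$stack$frames[[3]])
})

test_that("motion models give exact truth kinematics", {
  stat <- simulate_cell_video(simulation_config(
    frame_shape = c(64, 64), n_frames = 10, n_cells = 3,
    motion_model = "stationary", rng_seed = 2))
  for (tr in split(stat$truth, stat$truth$cell_id)) {
    expect_equal(diff(range(tr$row_um)), 0)
    expect_equal(diff(range(tr$col_um)), 0)
  }
  # drift at 0.1 um/s for 100 s -> exactly 10 um, every cell
  drift <- simulate_cell_video(simulation_config(
    frame_shape = c(96, 96), n_frames = 101, frame_rate = 1,
    n_cells = 4, motion_model = "drift",
    drift_velocity_um_s = c(0.1, 0), rng_seed = 3))
  for (tr in split(drift$truth, drift$truth$cell_id)) {
    d <- sqrt((tr$row_um[101] - tr$row_um[1])^2 +
                (tr$col_um[101] - tr$col_um[1])^2)
    expect_equal(d, 10.0, tolerance = 1e-12)
  }
})

test_that("truth micrometre coordinates are pixel times scale exactly", {
  cfg <- simulation_config(field_size_deg = 4, frame_shape = c(60, 80),
                           n_frames = 2, n_cells = 3, rng_seed = 7)
  sim <- simulate_cell_video(cfg)
  upp <- config_um_per_px(cfg)
  expect_equal(upp, 4 * 34 / 80)
  # positions lie inside the field in um
  expect_true(all(sim$truth$row_um >= 0 & sim$truth$row_um <= 59 * upp))
  expect_true(all(sim$truth$col_um >= 0 & sim$truth$col_um <= 79 * upp))
})

test_that("random-walk mean squared displacement matches 2 N sigma^2", {
  # truth-level Monte-Carlo check over 600 cells; rendering size kept tiny
  sigma <- 0.3
  nf <- 20
  sim <- simulate_cell_video(simulation_config(
    field_size_deg = 5, frame_shape = c(512, 512), n_frames = nf,
    n_cells = 600, cell_diameter_um = 2, motion_model = "random_walk",
    step_sigma_um = sigma, noise_sigma = 0, background_texture_sd = 0,
    rng_seed = 11))
  d2 <- vapply(split(sim$truth, sim$truth$cell_id), function(tr) {
    (tr$row_um[nf] - tr$row_um[1])^2 + (tr$col_um[nf] - tr$col_um[1])^2
  }, numeric(1))
  expected <- 2 * (nf - 1) * sigma^2
  se <- 2 * ((nf - 1) * sigma^2) / sqrt(length(d2))
  expect_lt(abs(mean(d2) - expected), 3 * se)
})

test_that("eye motion is reproducible and zero sigma is a no-op", {
  cfg <- simulation_config(frame_shape = c(48, 48), n_frames = 6,
                           n_cells = 2, rng_seed = 4)
  sim <- simulate_cell_video(cfg)
  a <- apply_eye_motion(sim$stack, sigma_px = 3, rng_seed = 8)
  b <- apply_eye_motion(sim$stack, sigma_px = 3, rng_seed = 8)
  expect_identical(a$shifts, b$shifts)
  expect_identical(a$stack$frames, b$stack$frames)
  z <- apply_eye_motion(sim$stack, sigma_px = 0)
  expect_identical(z$stack$frames, sim$stack$frames)
  expect_true(all(z$shifts == 0))
})

test_that("scan distortion is identity at amplitude 0 and centre-fixed", {
  m <- matrix(runif(50 * 61), 50, 61)
  expect_identical(apply_scan_distortion(m, 0), m)
  # odd symmetry: the centre column of an odd-width frame maps to itself
  ramp <- matrix(rep(seq_len(61), each = 50), 50, 61)
  d <- apply_scan_distortion(ramp, 0.8)
  expect_equal(d[1, 31], 31, tolerance = 1e-9)
  expect_error(apply_scan_distortion(m, 1.2), "amplitude")
})

test_that("parameter validation rejects bad configs", {
  expect_error(simulation_config(frame_shape = c(0, 10)), "frame_shape")
  expect_error(simulation_config(noise_sigma = -1), "noise_sigma")
  expect_error(simulation_config(n_cells = -2), "n_cells")
  expect_error(simulation_config(scan_distortion_amplitude = 2),
               "scan_distortion")
})

test_that("kymograph streak slopes encode the set velocity", {
  # per-streak regression on true paths: the independent velocity oracle
  sim <- simulate_vessel_kymograph(vessel_sim_config(
    true_velocity_mm_s = 12, lumen_diameter_um = 30, duration_s = 0.3,
    noise_sigma = 0, rng_seed = 21))
  st <- sim$truth$streaks
  slopes <- vapply(split(st, st$streak_id), function(s) {
    if (nrow(s) < 10) return(NA_real_)
    unname(stats::coef(stats::lm(x_um ~ t_s, s))[2]) / 1000
  }, numeric(1))
  expect_equal(stats::median(slopes, na.rm = TRUE), 12, tolerance = 1e-9)

  # V0 = 0 with no pulsatility: streaks are horizontal (constant row)
  sim0 <- simulate_vessel_kymograph(vessel_sim_config(
    true_velocity_mm_s = 0, lumen_diameter_um = 20, duration_s = 0.1,
    rng_seed = 3))
  for (s in split(sim0$truth$streaks, sim0$truth$streaks$streak_id)) {
    expect_equal(diff(range(s$x_um)), 0)
  }

  # sign flip mirrors the slope
  simn <- simulate_vessel_kymograph(vessel_sim_config(
    true_velocity_mm_s = -12, lumen_diameter_um = 30, duration_s = 0.3,
    noise_sigma = 0, rng_seed = 21))
  stn <- simn$truth$streaks
  sn <- vapply(split(stn, stn$streak_id), function(s) {
    if (nrow(s) < 10) return(NA_real_)
    unname(stats::coef(stats::lm(x_um ~ t_s, s))[2]) / 1000
  }, numeric(1))
  expect_equal(stats::median(sn, na.rm = TRUE), -12, tolerance = 1e-9)
})

test_that("pulsatile velocity integrates to V0 over whole cycles", {
  # time-average of v(t) = V0 (1 + m sin(2 pi f t)) over k cycles is V0
  v_mean <- aosloflow:::flow_displacement_um(0.5, 10, 0.3, 6) / 0.5 / 1000
  expect_equal(v_mean, 10, tolerance = 1e-12)
})

test_that("unresolvable streak configurations are rejected", {
  expect_error(vessel_sim_config(true_velocity_mm_s = 100,
                                 lumen_diameter_um = 30,
                                 streak_sigma_um = 2),
               "line rate")
  expect_error(vessel_sim_config(10, 30, pulsatility_fraction = 1),
               "pulsatility")
})
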