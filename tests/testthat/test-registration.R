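test_that("desinusoid round trip restores smooth patterns", {
  ramp <- matrix(rep(seq(0, 100, length.out = 120), each = 80), 80, 120)
  smooth <- ramp + 20 * sin(outer(seq_len(80) / 10, seq_len(120) / 15, "+"))
  for (a in c(0.3, 0.6, 0.9)) {
    rt <- desinusoid_frame(apply_scan_distortion(smooth, a), a)
    expect_lt(max(abs(rt - smooth)), 0.5)
  }
  expect_identical(desinusoid_frame(smooth, 0), smooth)
  # the correction is not an involution: correcting twice is not a no-op
  once <- desinusoid_frame(apply_scan_distortion(smooth, 0.6), 0.6)
  twice <- desinusoid_frame(once, 0.6)
  expect_gt(max(abs(twice - once)), 0.5)
})

test_that("estimate_shift recovers constructed translations", {
  sim <- sim_cell_frame(31, n_cells = 0, shape = c(96, 96))
  ref <- sim$stack$frames[[1]]
  expect_equal(estimate_shift(ref, ref), c(0, 0), tolerance = 0.05)
  shifted <- aosloflow:::translate_frame(ref, 5, -3, fill = mean(ref))
  expect_equal(round(estimate_shift(shifted, ref)), c(-5, 3))
  expect_error(estimate_shift(matrix(1, 10, 10), matrix(1, 10, 10)),
               "constant")
  expect_error(estimate_shift(ref, ref[1:50, ]), "dimensions")
})

test_that("register_video undoes simulated eye motion", {
  cfg <- simulation_config(frame_shape = c(96, 96), n_frames = 60,
                           n_cells = 3, eye_motion_sigma_px = 3,
                           noise_sigma = 2, rng_seed = 17)
  sim <- simulate_cell_video(cfg)
  reg <- register_video(sim$stack, reference_index = 1)
  # estimated shift should equal shift(ref) - shift(frame), exactly for
  # nearly all frames
  expected <- sweep(-sim$shifts, 2, -sim$shifts[1, ])
  exact <- rowSums(reg$shifts == expected) == 2
  expect_gte(mean(exact), 0.99)
  expect_true(all(abs(reg$shifts - expected) <= 1))
  expect_equal(reg$stack$stage, "registered")
})

test_that("registration edge cases behave", {
  sim <- sim_cell_frame(5, n_cells = 2, shape = c(64, 64))
  one <- sim$stack
  reg1 <- register_video(one)
  expect_identical(reg1$stack$frames, one$frames)
  expect_true(all(reg1$shifts == 0))

  # already-aligned stack: all shifts zero, frames unchanged
  cfg <- simulation_config(frame_shape = c(64, 64), n_frames = 5,
                           n_cells = 3, eye_motion_sigma_px = 0,
                           rng_seed = 6)
  aligned <- simulate_cell_video(cfg)$stack
  reg <- register_video(aligned, reference_index = 1)
  expect_true(all(reg$shifts == 0))
  expect_identical(reg$stack$frames, aligned$frames)

  # registering a registered stack changes nothing (idempotence)
  reg2 <- register_video(reg$stack, reference_index = 1)
  expect_true(all(reg2$shifts == 0))
})

test_that("temporal averaging follows the sqrt(N) noise law", {
  set.seed(42)
  frames <- lapply(1:25, function(i) matrix(rnorm(100 * 100, 50, 10),
                                            100, 100))
  stk <- video_stack(frames, um_per_px = 1, stage = "registered")
  avg <- temporal_average(stk, window = 25, stride = 1)
  expect_equal(n_frames(avg), 1)
  expect_equal(sd(as.vector(avg$frames[[1]])), 10 / sqrt(25),
               tolerance = 0.05)
})

test_that("temporal averaging frame count, identity and stage rules hold", {
  frames <- lapply(1:13, function(i) matrix(i + 0, 8, 8))
  stk <- video_stack(frames, um_per_px = 1, stage = "registered")
  for (w in c(1, 3, 5)) {
    for (s in c(1, 2, 5)) {
      avg <- temporal_average(stk, w, s)
      expect_equal(n_frames(avg), floor((13 - w) / s) + 1)
    }
  }
  # window 1 is the identity
  expect_identical(temporal_average(stk, 1, 1)$frames, stk$frames)
  # constant stack is unchanged by averaging
  const <- video_stack(lapply(1:6, function(i) matrix(7, 8, 8)),
                       um_per_px = 1, stage = "registered")
  avg <- temporal_average(const, 3)
  expect_true(all(vapply(avg$frames, function(m) all(m == 7), logical(1))))
  expect_equal(avg$average_window, 3L)
  # output timestamps are window centres
  expect_equal(temporal_average(stk, 5, 5)$timestamps[1],
               mean(stk$timestamps[1:5]))
  expect_error(temporal_average(stk, 20), "window")
  raw <- video_stack(frames, um_per_px = 1, stage = "raw")
  expect_error(temporal_average(raw, 5), "registered")
})

test_that("NA sentinel pixels are excluded from averages, not zeroed", {
  f1 <- matrix(10, 4, 4)
  f2 <- matrix(20, 4, 4); f2[1, 1] <- NA
  stk <- video_stack(list(f1, f2), um_per_px = 1, stage = "registered")
  avg <- temporal_average(stk, 2)
  expect_equal(avg$frames[[1]][1, 1], 10)   # mean over the valid frame only
  expect_equal(avg$frames[[1]][2, 2], 15)
})

test_that("registration and averaging commute with intensity scaling", {
  cfg <- simulation_config(frame_shape = c(64, 64), n_frames = 10,
                           n_cells = 3, eye_motion_sigma_px = 2,
                           rng_seed = 23)
  sim <- simulate_cell_video(cfg)
  scaled <- sim$stack
  scaled$frames <- lapply(scaled$frames, function(m) 3 * m)
  a <- temporal_average(register_video(sim$stack, 1)$stack, 5)
  b <- temporal_average(register_video(scaled, 1)$stack, 5)
  expect_equal(lapply(a$frames, function(m) 3 * m), b$frames,
               tolerance = 1e-12)
})

test_that("stage transitions only move forward", {
  sim <- sim_cell_frame(3, n_cells = 1, shape = c(48, 48))
  reg <- register_video(sim$stack)$stack
  avg <- temporal_average(reg, 1)
  expect_error(desinusoid_video(reg, 0.5), "raw")
  expect_error(register_video(temporal_average(
    video_stack(lapply(1:6, function(i) matrix(rnorm(64), 8, 8)),
                um_per_px = 1, stage = "registered"), 3)), "averaged")
})

test_that("two-pass masked registration matches plain registration when
          cells barely move", {
  cfg <- simulation_config(frame_shape = c(96, 96), n_frames = 30,
                           n_cells = 2, eye_motion_sigma_px = 2,
                           noise_sigma = 2, rng_seed = 41)
  sim <- simulate_cell_video(cfg)
  model <- train_detector(list(), NULL, detector_config(
    kind = "classical", um_per_px = sim$stack$um_per_px))
  plain <- register_video(sim$stack, reference_index = 1)
  robust <- register_video_robust(sim$stack, model, reference_index = 1)
  # static cells cannot drag the correlation peak: both agree with truth
  expected <- sweep(-sim$shifts, 2, -sim$shifts[1, ])
  expect_gte(mean(rowSums(robust$shifts == expected) == 2), 0.95)
  expect_equal(robust$shifts, plain$shifts)
})
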