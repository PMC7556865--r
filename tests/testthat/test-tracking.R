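make_track <- function(t, r, c, id = 1L) {
  data.frame(cell_id = id, frame = seq_along(t), time_s = t,
             row_um = r, col_um = c)
}

test_that("one persistent detection gives exactly one track", {
  det <- data.frame(frame = 1:20, row_um = 50 + 0.1 * (1:20),
                    col_um = rep(30, 20))
  tr <- link_detections(det, frame_interval_s = 0.2)
  expect_equal(length(unique(tr$cell_id)), 1)
  expect_equal(nrow(tr), 20)
  expect_equal(tr$time_s, (0:19) * 0.2)
})

test_that("well-separated cells never swap identities", {
  det <- rbind(
    data.frame(frame = 1:30, row_um = 10 + 0.05 * (1:30), col_um = 10),
    data.frame(frame = 1:30, row_um = 150, col_um = 150 - 0.05 * (1:30)))
  tr <- link_detections(det, max_link_dist_um = 13)
  expect_equal(length(unique(tr$cell_id)), 2)
  for (g in split(tr, tr$cell_id)) {
    expect_true(all(diff(g$frame) == 1))
    # each track stays on one side of the field
    expect_lt(diff(range(g$row_um)), 5)
  }
})

test_that("links agree with simulator identities for sparse random walks", {
  sim <- simulate_cell_video(simulation_config(
    field_size_deg = 5, frame_shape = c(480, 608), n_frames = 40,
    n_cells = 20, motion_model = "random_walk", step_sigma_um = 0.3,
    cell_diameter_um = 13, rng_seed = 77))
  det <- truth_as_detections(sim$truth)
  tr <- link_detections(det, max_link_dist_um = 13, frame_interval_s = 0.2)
  # compare linked ids against true ids: a link is correct when two
  # consecutive samples of one linked track belong to one true cell
  truth <- sim$truth
  truth$true_id <- truth$cell_id
  truth$cell_id <- NULL
  merged <- merge(as.data.frame(tr), truth,
                  by = c("frame", "row_um", "col_um"))
  links_ok <- vapply(split(merged, merged$cell_id), function(g) {
    g <- g[order(g$frame), ]
    c(sum(diff(g$true_id) == 0), nrow(g) - 1)
  }, numeric(2))
  expect_gte(sum(links_ok[1, ]) / sum(links_ok[2, ]), 0.95)
})

test_that("QC flags jump artefacts and keeps clean tracks", {
  clean <- make_track((0:20) * 1, 10 + (0:20) * 0.5, rep(5, 21))
  expect_true(all(qc_tracks(clean)$qc_status == "accepted"))
  jump <- clean
  jump$row_um[10] <- jump$row_um[10] + 20 * 0.5 * 20   # one huge step
  expect_true(all(qc_tracks(jump)$qc_status == "flagged"))
  expect_error(qc_tracks(clean, jump_factor = 1), "jump_factor")
})

test_that("QC rarely flags truth-correct tracks", {
  sim <- simulate_cell_video(simulation_config(
    field_size_deg = 5, frame_shape = c(480, 608), n_frames = 40,
    n_cells = 20, motion_model = "random_walk", step_sigma_um = 0.3,
    rng_seed = 78))
  tr <- link_detections(truth_as_detections(sim$truth),
                        max_link_dist_um = 13, frame_interval_s = 0.2)
  tr <- qc_tracks(tr)
  flagged <- tapply(tr$qc_status, tr$cell_id, function(s) s[1] == "flagged")
  expect_lte(mean(flagged), 0.05)
})

test_that("displacement matches drift kinematics and windowing rules", {
  drift <- make_track(seq(0, 120, by = 1), 10 + 0.1 * seq(0, 120), 5)
  expect_equal(displacement(drift, window_s = 100), 10, tolerance = 1e-9)
  short <- make_track(0:50, 1:51, rep(0, 51))
  expect_error(displacement(short, window_s = 100), "window")
  expect_warning(d <- displacement(short, window_s = 100,
                                   allow_shorter = TRUE), "full-span")
  expect_equal(d, 50)
  stationary <- make_track(0:120, rep(4, 121), rep(4, 121))
  expect_equal(displacement(stationary, 100), 0)
})

test_that("confinement ratio hits the closed-form geometry cases", {
  straight <- make_track(0:100, 0.2 * (0:100), rep(0, 101))
  expect_equal(confinement_ratio(straight, 100), 1, tolerance = 1e-9)
  # closed square loop back to the start
  r_loop <- c(seq(0, 10, length.out = 26), rep(10, 25),
              seq(10, 0, length.out = 26)[-1], rep(0, 25))
  c_loop <- c(rep(0, 26), seq(0, 10, length.out = 26)[-1],
              rep(10, 25), seq(10, 0, length.out = 26)[-1])
  loop <- make_track(0:100, r_loop, c_loop)
  expect_equal(confinement_ratio(loop, 100), 0, tolerance = 1e-9)
  # two equal perpendicular legs: sqrt(2)/2
  lpath <- make_track(0:100, c(seq(0, 10, length.out = 51),
                               rep(10, 50)),
                      c(rep(0, 51), seq(0.2, 10, length.out = 50)))
  expect_equal(confinement_ratio(lpath, 100), sqrt(2) / 2,
               tolerance = 1e-9)
  # zero path length: undefined, not zero
  still <- make_track(0:100, rep(1, 101), rep(1, 101))
  expect_true(is.na(confinement_ratio(still, 100)))
})

test_that("random-walk displacement matches the Monte-Carlo oracle", {
  sigma <- 0.3; n_samples <- 500
  sim <- simulate_cell_video(simulation_config(
    field_size_deg = 5, frame_shape = c(512, 512), n_frames = n_samples,
    n_cells = 120, cell_diameter_um = 2, motion_model = "random_walk",
    step_sigma_um = sigma, noise_sigma = 0, background_texture_sd = 0,
    frame_rate = 5, rng_seed = 13))
  tr <- link_detections(truth_as_detections(sim$truth),
                        max_link_dist_um = 13, frame_interval_s = 0.2)
  disp <- vapply(split(as.data.frame(tr), tr$cell_id), displacement,
                 numeric(1), window_s = 99.8)
  # Monte-Carlo oracle on raw Gaussian walks (independent of the simulator)
  set.seed(991)
  n_steps <- 499
  mc <- replicate(20000, {
    sqrt(sum(rnorm(2, 0, sigma * sqrt(n_steps))^2))
  })
  se <- sd(disp) / sqrt(length(disp))
  expect_lt(abs(mean(disp) - mean(mc)), 3 * se)
})

test_that("normalized traces start at the origin and keep geometry", {
  tr <- make_track(0:10, 5 + (0:10), 9 - (0:10))
  tr$qc_status <- "accepted"
  nt <- normalize_traces(tr)
  expect_equal(nt$drow_um[1], 0)
  expect_equal(nt$dcol_um[1], 0)
  shifted <- tr
  shifted$row_um <- shifted$row_um + 100
  shifted$col_um <- shifted$col_um - 40
  expect_equal(normalize_traces(shifted), nt)
  # max radius equals max displacement-from-start, recomputed directly
  r <- sqrt(nt$drow_um^2 + nt$dcol_um^2)
  d <- sqrt((tr$row_um - tr$row_um[1])^2 + (tr$col_um - tr$col_um[1])^2)
  expect_equal(max(r), max(d))
})

test_that("motility metrics are invariant to translation and rotation", {
  sim <- simulate_cell_video(simulation_config(
    frame_shape = c(256, 256), n_frames = 30, n_cells = 10,
    motion_model = "random_walk", step_sigma_um = 0.4, rng_seed = 19))
  det <- truth_as_detections(sim$truth)
  base <- motility_metrics(qc_tracks(link_detections(det)),
                           window_s = 1, allow_shorter = TRUE)
  shifted <- det
  shifted$row_um <- det$row_um + 50
  shifted$col_um <- det$col_um - 20
  rotated <- det
  rotated$row_um <- det$col_um          # 90 degree rotation
  rotated$col_um <- -det$row_um
  for (variant in list(shifted, rotated)) {
    m <- motility_metrics(qc_tracks(link_detections(variant)),
                          window_s = 1, allow_shorter = TRUE)
    expect_equal(m$displacement_um, base$displacement_um,
                 tolerance = 1e-9)
    expect_equal(m$confinement_ratio, base$confinement_ratio,
                 tolerance = 1e-9)
  }
})
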