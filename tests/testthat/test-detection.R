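test_that("label maps stamp unit-peak Gaussians at centroids", {
  expect_equal(make_label_map(NULL, c(20, 20), 4), matrix(0, 20, 20))
  m <- make_label_map(rbind(c(7, 11)), c(20, 20), 4)
  expect_equal(which(m == max(m)), (11) * 20 + 7 + 1)   # 0-based (7, 11)
  expect_equal(max(m), 1)
  # two kernels 3 sigma apart: clipped max 1, both maxima survive
  sig <- 2
  m2 <- make_label_map(rbind(c(10, 10), c(10, 10 + 3 * sig)), c(24, 24),
                       2 * sig)
  expect_lte(max(m2), 1)
  expect_gt(m2[11, 11], 0.99)
  expect_gt(m2[11, 11 + 3 * sig], 0.99)
  # oracle: direct evaluation of the summed kernels off-peak
  mid <- m2[11, 11 + 3]
  expect_equal(mid, exp(-9 / (2 * sig^2)) + exp(-9 / (2 * sig^2)),
               tolerance = 1e-9)
  expect_error(make_label_map(rbind(c(-1, 5)), c(10, 10), 2), "bounds")
})

test_that("detect_centroids extracts weighted component centroids", {
  expect_equal(nrow(detect_centroids(matrix(0, 30, 30))), 0)
  # suprathreshold disk centred at 0-based (50, 60)
  v <- matrix(0, 80, 80)
  d2 <- outer((0:79 - 50)^2, (0:79 - 60)^2, "+")
  v[d2 <= 9] <- 0.95
  det <- detect_centroids(v)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$row_px - 50), 0.5)
  expect_lt(abs(det$col_px - 60), 0.5)
  expect_equal(det$peak_prob, 0.95)
})

test_that("components split by a subthreshold line stay separate", {
  v <- matrix(0, 20, 20)
  v[5:9, 5:9] <- 0.95
  v[5:9, 11:15] <- 0.95     # column 10 stays below threshold
  det <- detect_centroids(v)
  expect_equal(nrow(det), 2)
  # exhaustive-labelling oracle: flood fill by hand on the binary mask
  mask <- v >= 0.9
  expect_equal(max(aosloflow:::label_components8(mask)), 2)
})

test_that("component labelling is 8-connected", {
  v <- matrix(0, 10, 10)
  v[3, 3] <- v[4, 4] <- v[5, 5] <- 1
  expect_equal(max(aosloflow:::label_components8(v > 0)), 1)
})

test_that("raising the threshold never increases detections", {
  sim <- sim_cell_frame(61)
  model <- classical_detector()
  pm <- predict_probability_map(model, sim$stack$frames[[1]],
                                um_per_px = fixture_um_per_px())
  n <- vapply(c(0.5, 0.7, 0.9, 0.95),
              function(th) nrow(detect_centroids(pm, threshold = th)),
              numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("both detector kinds reach F1 >= 0.90 on held-out frames", {
  f1_learned <- pooled_f1(trained_detector(), 201:215)
  f1_classical <- pooled_f1(classical_detector(), 201:215)
  expect_gte(f1_learned, 0.90)
  expect_gte(f1_classical, 0.90)
})

test_that("learned training is deterministic and hits its MAE ceiling", {
  sims <- lapply(41:44, sim_cell_frame)
  upp <- fixture_um_per_px()
  frames <- lapply(sims, function(s) s$stack$frames[[1]])
  targets <- lapply(sims, function(s) make_label_map(
    as.matrix(s$truth[, c("row_um", "col_um")]) / upp, c(128, 128),
    (13 / 2) / upp))
  cfg <- detector_config(kind = "learned", um_per_px = upp)
  m1 <- train_detector(frames, targets, cfg)
  m2 <- train_detector(frames, targets, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_lt(m1$training$mae, 0.05)
  p1 <- predict_probability_map(m1, frames[[1]])
  p2 <- predict_probability_map(m2, frames[[1]])
  expect_identical(p1$values, p2$values)
  expect_error(train_detector(list(), NULL, cfg), "training frame")
  expect_error(train_detector(frames, targets[1:2], cfg), "one to one")
})

test_that("probability maps live in [0,1] and ignore intensity offsets", {
  sim <- sim_cell_frame(71)
  fr <- sim$stack$frames[[1]]
  for (model in list(trained_detector(), classical_detector())) {
    pm <- predict_probability_map(model, fr)
    expect_true(all(pm$values >= 0 & pm$values <= 1))
    pm_off <- predict_probability_map(model, fr + 500)
    expect_equal(pm$values, pm_off$values, tolerance = 1e-8)
  }
})

test_that("background-only frames stay well below the detection threshold", {
  bg <- sim_cell_frame(81, n_cells = 0)
  pm <- predict_probability_map(trained_detector(), bg$stack$frames[[1]])
  expect_lt(max(pm$values), 0.5)
})

test_that("a single high-contrast cell peaks within 3 px of truth", {
  sim <- sim_cell_frame(91, n_cells = 1)
  upp <- fixture_um_per_px()
  pm <- predict_probability_map(trained_detector(), sim$stack$frames[[1]])
  pk <- which(pm$values == max(pm$values), arr.ind = TRUE)[1, ]
  expect_lt(sqrt((pk[1] - 1 - sim$truth$row_um[1] / upp)^2 +
                   (pk[2] - 1 - sim$truth$col_um[1] / upp)^2), 3)
})

test_that("counting rule averages the first 25 frames", {
  det <- data.frame(frame = rep(1:30, each = 5))
  expect_equal(count_cells(det, n_frames_available = 30), 5.0)
  # alternating 4 and 6 starting with 4: (13*4 + 12*6) / 25
  alt <- data.frame(frame = rep(1:25, times = rep(c(4, 6), length.out = 25)))
  expect_equal(count_cells(alt, n_frames_available = 25), 4.96)
  expect_error(count_cells(data.frame(frame = rep(1:10, 3)),
                           n_frames_available = 10), "allow_fewer")
  expect_warning(
    got <- count_cells(data.frame(frame = rep(1:10, 3)),
                       n_frames_available = 10, allow_fewer = TRUE),
    "10 frames")
  expect_equal(got, 3)
})

test_that("cell density uses cells per square millimetre", {
  expect_equal(cell_density(5, c(170, 170)), 5 / (170 * 170 * 1e-6),
               tolerance = 1e-12)
  expect_equal(round(cell_density(5, c(170, 170))), 173)
  expect_equal(cell_density(0, c(100, 100)), 0)
  expect_equal(cell_density(8, c(200, 200)),
               cell_density(8, c(100, 100)) / 4)
  expect_error(cell_density(1, c(0, 10)), "positive")
})

test_that("counts add over disjoint fields", {
  a <- sim_cell_frame(55, n_cells = 3)
  b <- sim_cell_frame(56, n_cells = 4)
  model <- classical_detector()
  upp <- fixture_um_per_px()
  n_of <- function(fr) nrow(detect_centroids(
    predict_probability_map(model, fr, um_per_px = upp)))
  joined <- rbind(a$stack$frames[[1]], b$stack$frames[[1]])
  expect_equal(n_of(joined),
               n_of(a$stack$frames[[1]]) + n_of(b$stack$frames[[1]]))
})
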