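# Shared synthetic fixtures, built in code at test time.

# One-frame cell field at the default 5-degree / 128 px scale (1.33 um/px).
sim_cell_frame <- function(seed, n_cells = 5, shape = c(128, 128),
                           noise_sigma = 2) {
  simulate_cell_video(simulation_config(
    frame_shape = shape, n_frames = 1, n_cells = n_cells,
    rng_seed = seed, noise_sigma = noise_sigma))
}

fixture_um_per_px <- function(shape = c(128, 128)) {
  config_um_per_px(simulation_config(frame_shape = shape))
}

# Trained learned detector shared across detection tests (cheap: closed-form
# ridge fit on 20 frames).
trained_detector <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      sims <- lapply(1:20, sim_cell_frame)
      upp <- fixture_um_per_px()
      cfg <- detector_config(kind = "learned", um_per_px = upp)
      model <<- train_detector(
        lapply(sims, function(s) s$stack$frames[[1]]),
        lapply(sims, function(s) make_label_map(
          as.matrix(s$truth[, c("row_um", "col_um")]) / upp,
          c(128, 128), (13 / 2) / upp)),
        cfg)
    }
    model
  }
})

classical_detector <- function() {
  train_detector(list(), NULL,
                 detector_config(kind = "classical",
                                 um_per_px = fixture_um_per_px()))
}

# Pooled F1 of a detector over a block of held-out single-frame simulations.
pooled_f1 <- function(model, seeds, n_cells = 5) {
  upp <- fixture_um_per_px()
  tp <- fp <- fn <- 0L
  for (sd in seeds) {
    s <- sim_cell_frame(sd, n_cells = n_cells)
    pm <- predict_probability_map(model, s$stack$frames[[1]],
                                  um_per_px = upp)
    det <- detect_centroids(pm)
    r <- match_detections(det,
                          as.matrix(s$truth[, c("row_um", "col_um")]) / upp)
    tp <- tp + r$tp; fp <- fp + r$fp; fn <- fn + r$fn
  }
  2 * tp / (2 * tp + fp + fn)
}

# Turn simulator truth into a detections table (perfect detector), for
# tracking tests that should not depend on the imaging stages.
truth_as_detections <- function(truth) {
  data.frame(frame = truth$frame, row_px = NA_real_, col_px = NA_real_,
             row_um = truth$row_um, col_um = truth$col_um,
             area_px = 1L, peak_prob = 1)
}
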