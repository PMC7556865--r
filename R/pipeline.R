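#' Assemble a full pipeline configuration
#'
#' Builds the configuration consumed by [run_pipeline()], filling every
#' stage with defaults. Conventions used throughout the outputs: pixel
#' coordinates are 0-based `(row, col)`; physical coordinates micrometres;
#' times seconds from the first frame; velocities mm/s; flows nL/s;
#' densities cells/mm^2; changes percent.
#'
#' The default `vessels` block describes one arteriole/venule pair followed
#' over five timepoints with conserved flow: the venule dilates with
#' a modest velocity change while the arteriole speeds up at nearly fixed
#' calibre — the two ways a vessel can carry more flow.
#'
#' @param seed global integer seed; every stochastic stage derives its own
#'   stream from it.
#' @param outdir output directory for tables, report and figures.
#' @param cell_video named list overriding [simulation_config()] arguments.
#' @param registration list: `desinusoid_amplitude`, `average_window`,
#'   `average_stride`.
#' @param detector list: `kind`, `threshold`, `min_area_px`, plus
#'   [detector_config()] overrides.
#' @param tracking list: `max_link_dist_um`, `max_gap_frames`,
#'   `jump_factor`, `window_s`.
#' @param vessels list: `timepoints`, and per vessel type the true
#'   velocity/diameter series used to simulate each timepoint.
#' @param velocimetry list: `window_ms`, `cardiac_freq_hz`,
#'   `pulsatility_fraction`, `kymo_duration_s`.
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("aosloflow_"),
                            cell_video = list(), registration = list(),
                            detector = list(), tracking = list(),
                            vessels = list(), velocimetry = list(),
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  cfg <- list(
    seed = as.integer(seed), outdir = outdir, log_level = log_level,
    cell_video = utils::modifyList(list(
      frame_shape = c(160, 160), n_frames = 250, n_cells = 8,
      motion_model = "random_walk", step_sigma_um = 0.25,
      eye_motion_sigma_px = 2, scan_distortion_amplitude = 0.3,
      noise_sigma = 2), cell_video),
    registration = utils::modifyList(list(
      desinusoid_amplitude = NULL, average_window = 5L,
      average_stride = 5L, two_pass = TRUE), registration,
      keep.null = TRUE),
    detector = utils::modifyList(list(
      kind = "classical", threshold = 0.90, min_area_px = 3L,
      train_frames = 12L), detector),
    tracking = utils::modifyList(list(
      max_link_dist_um = 13, max_gap_frames = 0L, jump_factor = 5,
      window_s = NULL), tracking, keep.null = TRUE),
    vessels = utils::modifyList(list(
      timepoints = c("baseline", "6h", "24h", "72h", "10d"),
      arteriole = list(velocity_mm_s = c(20, 24, 29.6, 24, 21),
                       diameter_um = c(18, 18.2, 18.5, 18.2, 18)),
      venule = list(velocity_mm_s = c(8, 8.6, 7.9, 8.4, 8.1),
                    diameter_um = c(30, 32.4, 39.0, 33.5, 30.8))),
      vessels),
    velocimetry = utils::modifyList(list(
      window_ms = 20, cardiac_freq_hz = 6, pulsatility_fraction = 0.2,
      kymo_duration_s = 0.5, um_per_px = 1), velocimetry)
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  required <- c("seed", "outdir", "cell_video", "registration", "detector",
                "tracking", "vessels", "velocimetry")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop("pipeline config missing block(s): ", paste(missing, collapse = ", "))
  }
  if (!cfg$detector$kind %in% c("learned", "classical")) {
    stop("detector kind must be 'learned' or 'classical'")
  }
  vs <- cfg$vessels
  for (vt in c("arteriole", "venule")) {
    if (length(vs[[vt]]$velocity_mm_s) != length(vs$timepoints) ||
          length(vs[[vt]]$diameter_um) != length(vs$timepoints)) {
      stop(vt, " velocity/diameter series must match the timepoints")
    }
  }
  invisible(cfg)
}

pipe_log <- function(cfg, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  if (cfg$log_level != "quiet") message(msg)
  logfile <- file.path(cfg$outdir, "pipeline.log")
  cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the full synthetic end-to-end study
#'
#' Orchestrates the whole analysis on simulated data: cell-video synthesis,
#' de-sinusoiding, registration, 5-frame temporal averaging, cell detection
#' and counting, track linking with QC, motility metrics; per-vessel
#' kymograph velocimetry with cycle averaging, motion-contrast diametry and
#' flow; and the longitudinal arteriole-venule analysis (relative changes,
#' flow-conservation fit, V/D^2 decomposition). Writes CSV tables, a
#' deterministic JSON metrics report (`report.json`), the effective
#' configuration (`config.json`), a provenance log, and figures when
#' ggplot2 is available. Identical config and seed give a byte-identical
#' report.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  seed <- config$seed

  # ---- cell arm -----------------------------------------------------------
  pipe_log(config, "simulate: cell video")
  sim_args <- config$cell_video
  sim_args$rng_seed <- seed + 11L
  sim <- simulate_cell_video(do.call(simulation_config, sim_args))
  stack <- sim$stack

  amp <- config$registration$desinusoid_amplitude %||%
    sim$config$scan_distortion_amplitude
  if (amp > 0) {
    pipe_log(config, "desinusoid: amplitude ", amp)
    stack <- desinusoid_video(stack, amp)
  }

  det_cfg <- detector_config(
    kind = config$detector$kind,
    um_per_px = stack$um_per_px,
    cell_contrast = sim$config$cell_contrast,
    seed = seed + 23L)
  model <- if (det_cfg$kind == "classical") {
    train_detector(list(), NULL, det_cfg)
  } else {
    ntr <- config$detector$train_frames
    tr_sims <- lapply(seq_len(ntr), function(i) {
      args <- config$cell_video
      args$rng_seed <- seed + 1000L + i
      args$n_frames <- 1L
      args$eye_motion_sigma_px <- 0
      args$scan_distortion_amplitude <- 0
      simulate_cell_video(do.call(simulation_config, args))
    })
    train_detector(
      lapply(tr_sims, function(s) s$stack$frames[[1]]),
      lapply(tr_sims, function(s) make_label_map(
        as.matrix(s$truth[, c("row_um", "col_um")]) / s$stack$um_per_px,
        dim(s$stack$frames[[1]]), radius_px_of(det_cfg))),
      det_cfg)
  }

  pipe_log(config, "register: ", n_frames(stack), " frames",
           if (config$registration$two_pass) " (two-pass, cell-masked)")
  reg <- if (config$registration$two_pass) {
    register_video_robust(stack, model,
                          window = config$registration$average_window,
                          stride = config$registration$average_stride,
                          threshold = config$detector$threshold,
                          min_area_px = config$detector$min_area_px)
  } else {
    register_video(stack)
  }
  utils::write.csv(data.frame(frame = seq_len(nrow(reg$shifts)),
                              dr = reg$shifts[, 1], dc = reg$shifts[, 2]),
                   file.path(config$outdir, "shifts.csv"),
                   row.names = FALSE)

  avg <- temporal_average(reg$stack, config$registration$average_window,
                          config$registration$average_stride)
  pipe_log(config, "average: ", n_frames(avg), " frames of window ",
           avg$average_window)

  detections <- detect_stack(model, avg,
                             threshold = config$detector$threshold,
                             min_area_px = config$detector$min_area_px)
  pipe_log(config, "detect: ", nrow(detections), " detections (",
           det_cfg$kind, ")")
  utils::write.csv(detections, file.path(config$outdir, "detections.csv"),
                   row.names = FALSE)

  navail <- n_frames(avg)
  count <- count_cells(detections, n_frames_available = navail,
                       allow_fewer = navail < 25)
  field_um <- dim(avg$frames[[1]]) * avg$um_per_px
  density <- cell_density(count, field_um)

  tracks <- link_detections(detections,
                            max_link_dist_um = config$tracking$max_link_dist_um,
                            max_gap_frames = config$tracking$max_gap_frames,
                            frame_times = avg$timestamps)
  tracks <- qc_tracks(tracks, jump_factor = config$tracking$jump_factor)
  window_s <- config$tracking$window_s %||%
    (max(avg$timestamps) - min(avg$timestamps))
  metrics <- motility_metrics(tracks, window_s = window_s,
                              allow_shorter = FALSE)
  traces <- normalize_traces(tracks)
  pipe_log(config, "track: ", length(unique(tracks$cell_id)), " tracks, ",
           nrow(metrics), " with full ", round(window_s, 1), " s window")
  utils::write.csv(tracks, file.path(config$outdir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics, file.path(config$outdir, "motility_metrics.csv"),
                   row.names = FALSE)

  # ---- vessel arm ---------------------------------------------------------
  vs <- config$vessels; vm <- config$velocimetry
  rows <- list()
  vi <- 0L
  for (vt in c("arteriole", "venule")) {
    for (j in seq_along(vs$timepoints)) {
      vi <- vi + 1L
      kcfg <- vessel_sim_config(
        true_velocity_mm_s = vs[[vt]]$velocity_mm_s[j],
        lumen_diameter_um = vs[[vt]]$diameter_um[j],
        duration_s = vm$kymo_duration_s, um_per_px = vm$um_per_px,
        pulsatility_fraction = vm$pulsatility_fraction,
        cardiac_freq_hz = vm$cardiac_freq_hz,
        rng_seed = seed + 300L + vi)
      ksim <- simulate_vessel_kymograph(kcfg)
      vel <- cycle_average_velocity(
        estimate_velocity(ksim$kymo, window_ms = vm$window_ms),
        cardiac_freq_hz = vm$cardiac_freq_hz)
      vsim <- simulate_vessel_video(vs[[vt]]$diameter_um[j],
                                    angle_deg = 15 * (vi %% 3),
                                    um_per_px = vm$um_per_px,
                                    rng_seed = seed + 600L + vi)
      dia <- measure_diameter(build_motion_contrast(vsim$stack))
      rows[[vi]] <- vessel_measurement(
        vessel_id = paste0(vt, "_1"), vessel_type = vt,
        timepoint = vs$timepoints[j], velocity_mm_s = vel,
        diameter_um = dia)
    }
  }
  measurements <- do.call(rbind, rows)
  pipe_log(config, "flow: ", nrow(measurements), " vessel measurements")
  utils::write.csv(measurements,
                   file.path(config$outdir, "vessel_measurements.csv"),
                   row.names = FALSE)

  longi <- longitudinal_changes(measurements,
                                timepoint_levels = vs$timepoints)
  utils::write.csv(longi, file.path(config$outdir, "longitudinal.csv"),
                   row.names = FALSE)
  art <- longi[longi$vessel_type == "arteriole", ]
  ven <- longi[longi$vessel_type == "venule", ]
  cons <- flow_conservation_fit(art$dq_pct, ven$dq_pct)

  report <- list(
    units = list(displacement = "um", velocity = "mm/s", flow = "nL/s",
                 density = "cells/mm^2", change = "percent"),
    seed = seed,
    cells = list(
      n_true = sim$config$n_cells,
      count_first_25 = count,
      density_cells_mm2 = density,
      n_tracks = length(unique(tracks$cell_id)),
      n_accepted = length(unique(tracks$cell_id[
        tracks$qc_status == "accepted"])),
      motility = list(
        n = nrow(metrics),
        mean_displacement_um = mean(metrics$displacement_um),
        sd_displacement_um = if (nrow(metrics) > 1)
          stats::sd(metrics$displacement_um) else NA,
        mean_confinement_ratio = mean(metrics$confinement_ratio,
                                      na.rm = TRUE),
        window_s = window_s)),
    vessels = list(
      measurements = measurements,
      arteriole_dv_pct = art$dv_pct, arteriole_dd_pct = art$dd_pct,
      arteriole_dq_pct = art$dq_pct,
      venule_dv_pct = ven$dv_pct, venule_dd_pct = ven$dd_pct,
      venule_dq_pct = ven$dq_pct,
      arteriole_v_over_d2_pct = art$v_over_d2_pct,
      venule_v_over_d2_pct = ven$v_over_d2_pct,
      conservation = cons))
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       na = "null")
  jsonlite::write_json(unclass(config),
                       file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  save_pipeline_figures(config, traces, longi, art, ven)
  pipe_log(config, "done in ",
           round(as.numeric(Sys.time()) - as.numeric(t_start), 1), " s")
  invisible(report)
}

# Figures are best-effort: skipped silently where no graphics device or
# ggplot2 is available.
save_pipeline_figures <- function(config, traces, longi, art, ven) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) return(invisible())
  try({
    p1 <- plot_traces(traces)
    p2 <- plot_conservation(art$dq_pct, ven$dq_pct)
    ggplot2::ggsave(file.path(config$outdir, "traces.pdf"), p1,
                    width = 5, height = 5)
    ggplot2::ggsave(file.path(config$outdir, "conservation.pdf"), p2,
                    width = 5, height = 4)
  }, silent = TRUE)
  invisible()
}

#' Rose plot of origin-centred displacement traces
#'
#' @param traces data.frame from [normalize_traces()].
#' @param reference_radius_um radius of the typical-cell-size reference
#'   circle (default 13).
#' @return a ggplot object.
#' @export
plot_traces <- function(traces, reference_radius_um = 13) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  th <- seq(0, 2 * pi, length.out = 181)
  circ <- data.frame(dcol_um = reference_radius_um * cos(th),
                     drow_um = reference_radius_um * sin(th))
  ggplot2::ggplot(traces,
                  ggplot2::aes(x = dcol_um, y = drow_um,
                               group = cell_id)) +
    ggplot2::geom_path(alpha = 0.6) +
    ggplot2::geom_path(data = circ, ggplot2::aes(group = NULL),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x displacement (um)", y = "y displacement (um)") +
    ggplot2::theme_minimal()
}

#' Arteriole-venule flow-conservation scatter
#'
#' @param arteriole_dq,venule_dq paired percent flow changes.
#' @return a ggplot object.
#' @export
plot_conservation <- function(arteriole_dq, venule_dq) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- data.frame(a = arteriole_dq, v = venule_dq)
  ggplot2::ggplot(df, ggplot2::aes(x = a, y = v)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "black", linewidth = 0.4) +
    ggplot2::labs(x = "arteriole flow change (%)",
                  y = "venule flow change (%)") +
    ggplot2::theme_minimal()
}
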