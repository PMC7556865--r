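#' Simulation settings for synthetic AOSLO cell videos
#'
#' Describes a synthetic phase-contrast retinal video: field geometry and
#' calibration, the cell population and its motion model, instrument effects
#' (inter-frame eye motion, sinusoidal fast-axis scan distortion, sensor
#' noise) and the random seed. The scale convention is
#' `um_per_px = field_size_deg * um_per_deg / ncol`: the field of view in
#' degrees of visual angle maps onto the fast-axis width of the frame.
#'
#' Cells are rendered as radial difference-of-Gaussians profiles (dark core,
#' bright annulus) to emulate the phase-contrast appearance of translucent
#' immune cells, at a nominal 13 um diameter. The background is a band-limited
#' texture standing in for out-of-focus retinal backscatter, which gives frame
#' registration structure to lock onto.
#'
#' @param field_size_deg field of view in degrees of visual angle (2-5).
#' @param um_per_deg retinal scale in micrometres per degree (default 34,
#'   i.e. 2-5 degrees spanning 68-170 um).
#' @param frame_shape integer `(rows, cols)`; default `c(480, 608)`, the
#'   native frame geometry.
#' @param frame_rate frames per second (default 25).
#' @param n_frames number of frames to simulate.
#' @param cell_diameter_um nominal cell diameter (default 13).
#' @param n_cells number of cells (>= 0).
#' @param motion_model `"stationary"`, `"drift"` or `"random_walk"`.
#' @param drift_velocity_um_s length-2 drift velocity `(row, col)` in um/s.
#' @param step_sigma_um random-walk per-frame, per-axis step SD in um.
#' @param eye_motion_sigma_px SD of the integer-rounded Gaussian inter-frame
#'   translation emulating residual eye motion.
#' @param scan_distortion_amplitude sinusoidal fast-axis distortion mixing
#'   weight in `[0, 1]` (0 = none).
#' @param noise_sigma additive Gaussian sensor noise SD, intensity units.
#' @param background_level mean background intensity.
#' @param background_texture_sd SD of the band-limited background texture.
#' @param texture_smooth_um Gaussian correlation length (um) of the
#'   texture; converted to pixels at the configured scale so the simulated
#'   scene is resolution-independent.
#' @param cell_contrast amplitude of the cell profile, intensity units.
#' @param rng_seed integer seed; identical configs give bit-identical output.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(field_size_deg = 5, um_per_deg = 34,
                              frame_shape = c(480, 608), frame_rate = 25,
                              n_frames = 100, cell_diameter_um = 13,
                              n_cells = 10,
                              motion_model = c("stationary", "drift",
                                               "random_walk"),
                              drift_velocity_um_s = c(0, 0),
                              step_sigma_um = 0.3,
                              eye_motion_sigma_px = 0,
                              scan_distortion_amplitude = 0,
                              noise_sigma = 2,
                              background_level = 100,
                              background_texture_sd = 6,
                              texture_smooth_um = 8,
                              cell_contrast = 40,
                              rng_seed = 1L) {
  motion_model <- match.arg(motion_model)
  frame_shape <- as.integer(frame_shape)
  if (length(frame_shape) != 2 || any(frame_shape <= 0)) {
    stop("frame_shape must be two positive integers (rows, cols)")
  }
  if (field_size_deg <= 0 || um_per_deg <= 0) {
    stop("field_size_deg and um_per_deg must be positive")
  }
  if (n_cells < 0) stop("n_cells must be >= 0")
  for (nm in c("step_sigma_um", "eye_motion_sigma_px", "noise_sigma",
               "background_texture_sd")) {
    if (get(nm) < 0) stop(nm, " must be >= 0")
  }
  if (scan_distortion_amplitude < 0 || scan_distortion_amplitude > 1) {
    stop("scan_distortion_amplitude must lie in [0, 1]")
  }
  if (length(drift_velocity_um_s) != 2) {
    stop("drift_velocity_um_s must be a length-2 vector")
  }
  structure(
    list(field_size_deg = field_size_deg, um_per_deg = um_per_deg,
         frame_shape = frame_shape, frame_rate = frame_rate,
         n_frames = as.integer(n_frames),
         cell_diameter_um = cell_diameter_um, n_cells = as.integer(n_cells),
         motion_model = motion_model,
         drift_velocity_um_s = drift_velocity_um_s,
         step_sigma_um = step_sigma_um,
         eye_motion_sigma_px = eye_motion_sigma_px,
         scan_distortion_amplitude = scan_distortion_amplitude,
         noise_sigma = noise_sigma, background_level = background_level,
         background_texture_sd = background_texture_sd,
         texture_smooth_um = texture_smooth_um, cell_contrast = cell_contrast,
         rng_seed = as.integer(rng_seed)),
    class = "simulation_config"
  )
}

#' Micrometres per pixel implied by a simulation config
#' @param config a [simulation_config()].
#' @return scalar um/px.
#' @export
config_um_per_px <- function(config) {
  config$field_size_deg * config$um_per_deg / config$frame_shape[2]
}

# Run expr with a private, seeded RNG stream; global RNG state untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Band-limited texture: Gaussian-smoothed white noise rescaled to target SD.
make_background <- function(rows, cols, level, texture_sd, smooth_px) {
  w <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (texture_sd <= 0) return(matrix(level, rows, cols))
  if (smooth_px > 0) {
    side <- 2L * ceiling(3 * smooth_px) + 1L
    side <- min(side, 2L * ((min(rows, cols) - 1L) %/% 2L) + 1L)
    k <- EBImage::makeBrush(side, shape = "gaussian", sigma = smooth_px)
    w <- EBImage::filter2(w, k)
  }
  level + w * (texture_sd / stats::sd(as.vector(w)))
}

# Radial phase-contrast cell profile: dark core, bright annulus.
# d = distance from centre in px, radius_px = nominal cell radius in px.
cell_profile <- function(d, radius_px, amplitude) {
  s_out <- radius_px
  s_in <- radius_px / 2
  amplitude * (exp(-d^2 / (2 * s_out^2)) - 1.6 * exp(-d^2 / (2 * s_in^2)))
}

# Add one cell profile into `frame` at continuous (row, col) px position.
stamp_cell <- function(frame, r, c, radius_px, amplitude) {
  ext <- ceiling(3 * radius_px)
  r0 <- max(1L, floor(r) - ext); r1 <- min(nrow(frame), ceiling(r) + ext)
  c0 <- max(1L, floor(c) - ext); c1 <- min(ncol(frame), ceiling(c) + ext)
  if (r0 > r1 || c0 > c1) return(frame)
  d <- sqrt(outer((r0:r1 - r)^2, (c0:c1 - c)^2, "+"))
  frame[r0:r1, c0:c1] <- frame[r0:r1, c0:c1] +
    cell_profile(d, radius_px, amplitude)
  frame
}

#' Simulate a phase-contrast cell video with exact ground truth
#'
#' Generates a synthetic time-lapse of immune-like cells on a textured
#' background, optionally with inter-frame eye-motion translation, sinusoidal
#' fast-axis scan distortion and sensor noise. The returned ground truth
#' records exact sub-pixel cell centres per frame *before* eye motion and
#' noise, in micrometres (pixel position times the field scale), together
#' with the true per-frame eye-motion shifts.
#'
#' Eye motion is emulated by rendering onto a padded canvas and cropping at a
#' per-frame integer offset, so shifted frames carry no border artefacts.
#' Cells are clamped at the field edges rather than wrapped.
#'
#' @param config a [simulation_config()].
#' @return list with elements `stack` (a [video_stack()], stage `"raw"`),
#'   `truth` (data.frame `frame, cell_id, row_um, col_um`), `shifts`
#'   (n_frames x 2 integer matrix of applied eye-motion translations,
#'   `(row, col)`), and `config`.
#' @export
simulate_cell_video <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$rng_seed, {
    rows <- config$frame_shape[1]; cols <- config$frame_shape[2]
    upp <- config_um_per_px(config)
    radius_px <- (config$cell_diameter_um / 2) / upp
    dt <- 1 / config$frame_rate
    nf <- config$n_frames; nc <- config$n_cells

    # true trajectories in px (continuous), clamped to field.
    # Initial placement is hard-core: cells are solid bodies, so centres are
    # rejection-sampled to at least one cell diameter apart, and at least one
    # diameter from the field edge so no profile starts clipped.
    margin <- min(config$cell_diameter_um / upp, rows / 4, cols / 4)
    min_space_px <- config$cell_diameter_um / upp
    pos_r <- matrix(0, nf, max(nc, 1)); pos_c <- matrix(0, nf, max(nc, 1))
    if (nc > 0) {
      r0 <- numeric(nc); c0 <- numeric(nc)
      for (k in seq_len(nc)) {
        for (try in seq_len(200L)) {
          rr <- stats::runif(1, margin, rows - 1 - margin)
          cc <- stats::runif(1, margin, cols - 1 - margin)
          if (k == 1 || all(sqrt((r0[seq_len(k - 1)] - rr)^2 +
                                   (c0[seq_len(k - 1)] - cc)^2) >=
                              min_space_px)) break
        }
        r0[k] <- rr; c0[k] <- cc
      }
      if (config$motion_model == "stationary") {
        pos_r <- matrix(r0, nf, nc, byrow = TRUE)
        pos_c <- matrix(c0, nf, nc, byrow = TRUE)
      } else if (config$motion_model == "drift") {
        t_s <- (seq_len(nf) - 1) * dt
        pos_r <- outer(t_s, rep(config$drift_velocity_um_s[1] / upp, nc)) +
          matrix(r0, nf, nc, byrow = TRUE)
        pos_c <- outer(t_s, rep(config$drift_velocity_um_s[2] / upp, nc)) +
          matrix(c0, nf, nc, byrow = TRUE)
      } else {
        sig_px <- config$step_sigma_um / upp
        step_r <- matrix(stats::rnorm((nf - 1) * nc, 0, sig_px), nf - 1, nc)
        step_c <- matrix(stats::rnorm((nf - 1) * nc, 0, sig_px), nf - 1, nc)
        cs_r <- matrix(apply(step_r, 2, cumsum), nf - 1, nc)
        cs_c <- matrix(apply(step_c, 2, cumsum), nf - 1, nc)
        pos_r <- rbind(r0, sweep(cs_r, 2, r0, "+"))
        pos_c <- rbind(c0, sweep(cs_c, 2, c0, "+"))
        dimnames(pos_r) <- NULL; dimnames(pos_c) <- NULL
      }
      pos_r <- pmin(pmax(pos_r, 0), rows - 1)
      pos_c <- pmin(pmax(pos_c, 0), cols - 1)
    }

    # eye-motion integer shifts
    shifts <- matrix(0L, nf, 2)
    if (config$eye_motion_sigma_px > 0) {
      shifts <- matrix(as.integer(round(
        stats::rnorm(2 * nf, 0, config$eye_motion_sigma_px))), nf, 2)
    }
    pad <- max(abs(shifts)) + 1L

    canvas <- make_background(rows + 2L * pad, cols + 2L * pad,
                              config$background_level,
                              config$background_texture_sd,
                              config$texture_smooth_um / upp)

    frames <- vector("list", nf)
    for (f in seq_len(nf)) {
      dr <- shifts[f, 1]; dc <- shifts[f, 2]
      fr <- canvas[(pad + 1 - dr):(pad + rows - dr),
                   (pad + 1 - dc):(pad + cols - dc)]
      if (nc > 0) {
        for (k in seq_len(nc)) {
          fr <- stamp_cell(fr, pos_r[f, k] + 1 + dr, pos_c[f, k] + 1 + dc,
                           radius_px, config$cell_contrast)
        }
      }
      if (config$scan_distortion_amplitude > 0) {
        fr <- apply_scan_distortion(fr, config$scan_distortion_amplitude)
      }
      if (config$noise_sigma > 0) {
        fr <- fr + matrix(stats::rnorm(rows * cols, 0, config$noise_sigma),
                          rows, cols)
      }
      frames[[f]] <- fr
    }

    truth <- if (nc > 0) {
      data.frame(
        frame = rep(seq_len(nf), nc),
        cell_id = rep(seq_len(nc), each = nf),
        row_um = as.vector(pos_r) * upp,
        col_um = as.vector(pos_c) * upp
      )
    } else {
      data.frame(frame = integer(), cell_id = integer(),
                 row_um = numeric(), col_um = numeric())
    }

    list(stack = video_stack(frames, um_per_px = upp,
                             frame_interval_s = dt, stage = "raw"),
         truth = truth[order(truth$frame, truth$cell_id), ],
         shifts = shifts, config = config)
  })
}

#' Apply random inter-frame eye motion to a stack
#'
#' Translates every frame by an independent integer-rounded Gaussian draw,
#' filling exposed borders with the stack's median intensity. The applied
#' shifts are returned so registration can be verified against truth: the
#' shift a registration routine must estimate for frame `f` is
#' `-shifts[f, ]`.
#'
#' @param stack a [video_stack()].
#' @param sigma_px SD of the per-axis Gaussian shift (>= 0).
#' @param rng_seed integer seed.
#' @return list `stack` (translated copy), `shifts` (n x 2 integer matrix).
#' @export
apply_eye_motion <- function(stack, sigma_px, rng_seed = 1L) {
  stopifnot(inherits(stack, "video_stack"))
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  n <- n_frames(stack)
  if (sigma_px == 0) {
    return(list(stack = stack, shifts = matrix(0L, n, 2)))
  }
  with_seed(rng_seed, {
    shifts <- matrix(as.integer(round(stats::rnorm(2 * n, 0, sigma_px))), n, 2)
    fill <- stats::median(unlist(lapply(stack$frames, stats::median)))
    stack$frames <- lapply(seq_len(n), function(f) {
      translate_frame(stack$frames[[f]], shifts[f, 1], shifts[f, 2],
                      fill = fill)
    })
    list(stack = stack, shifts = shifts)
  })
}

# Integer translation of a matrix by (dr, dc); exposed pixels get `fill`.
translate_frame <- function(frame, dr, dc, fill = NA_real_) {
  R <- nrow(frame); C <- ncol(frame)
  out <- matrix(fill, R, C)
  sr <- max(1, 1 + dr):min(R, R + dr)
  sc <- max(1, 1 + dc):min(C, C + dc)
  if (length(sr) > 0 && length(sc) > 0) {
    out[sr, sc] <- frame[sr - dr, sc - dc]
  }
  out
}

# Normalized fast-axis coordinate map mixing linear and sinusoidal sampling.
# u in [0,1] -> x in [0,1]; monotone for a in [0,1]; identity at a = 0;
# odd-symmetric about the centre (u = 0.5 maps to 0.5).
sinusoid_map <- function(u, amplitude) {
  (1 - amplitude) * u + amplitude * (1 - cos(pi * u)) / 2
}

#' Apply sinusoidal fast-axis scan distortion to a frame
#'
#' Emulates the nonuniform sampling of a resonant raster scanner: output
#' column at normalized position `u` takes the intensity at true position
#' `x = (1-a)*u + a*(1-cos(pi*u))/2` (linear interpolation). The map is
#' monotone and invertible for `a` in `[0, 1]`; [desinusoid_frame()] applies
#' the inverse resampling.
#'
#' @param frame numeric matrix.
#' @param amplitude mixing weight `a` in `[0, 1]`; 0 is the identity.
#' @return distorted matrix, same dimensions.
#' @export
apply_scan_distortion <- function(frame, amplitude) {
  check_amplitude(amplitude)
  if (amplitude == 0) return(frame)
  C <- ncol(frame)
  u <- (seq_len(C) - 1) / (C - 1)
  resample_cols(frame, sinusoid_map(u, amplitude) * (C - 1) + 1)
}

check_amplitude <- function(amplitude) {
  if (!is.numeric(amplitude) || length(amplitude) != 1 ||
      amplitude < 0 || amplitude > 1) {
    stop("amplitude must be a scalar in [0, 1]")
  }
}

# Sample every row of `frame` at (1-based, possibly fractional) column
# positions `x`, linear interpolation, clamped at the borders.
resample_cols <- function(frame, x) {
  C <- ncol(frame)
  x <- pmin(pmax(x, 1), C)
  lo <- pmin(floor(x), C - 1)
  w <- x - lo
  frame[, lo, drop = FALSE] * rep(1 - w, each = nrow(frame)) +
    frame[, lo + 1, drop = FALSE] * rep(w, each = nrow(frame))
}
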