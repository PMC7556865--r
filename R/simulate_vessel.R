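#' Simulation settings for synthetic vessel kymographs
#'
#' Describes a single-vessel line-scan acquisition: a fast beam repeatedly
#' samples a line through the vessel at `line_rate_hz`; blood cells crossing
#' the line leave slanted streaks in the space-time image whose slope is the
#' instantaneous velocity. Velocity is pulsatile,
#' `v(t) = V0 * (1 + m * sin(2*pi*f_c*t))`, so the time average over an
#' integer number of cardiac cycles equals `V0` exactly.
#'
#' The precondition `line_rate_hz > 2 * |V0| * 1000 / um_per_px` guarantees a
#' cell advances less than half a pixel per line, i.e. streaks are resolvable.
#'
#' @param true_velocity_mm_s signed cycle-mean velocity `V0` (mm/s).
#' @param lumen_diameter_um inner lumen diameter (um).
#' @param line_rate_hz line-scan rate (default 15000 Hz).
#' @param duration_s recording length in seconds.
#' @param um_per_px micrometres per row of the kymograph.
#' @param pulsatility_fraction cardiac modulation depth `m` in `[0, 1)`.
#' @param cardiac_freq_hz cardiac frequency (default 6 Hz, mouse).
#' @param streak_density expected streaks per 100 ms.
#' @param streak_sigma_um Gaussian half-width of a cell streak (um).
#' @param streak_amplitude streak intensity above the lumen background.
#' @param noise_sigma additive Gaussian noise SD, intensity units.
#' @param rng_seed integer seed.
#' @return an object of class `vessel_sim_config`.
#' @export
vessel_sim_config <- function(true_velocity_mm_s, lumen_diameter_um,
                              line_rate_hz = 15000, duration_s = 0.5,
                              um_per_px = 1, pulsatility_fraction = 0,
                              cardiac_freq_hz = 6, streak_density = 40,
                              streak_sigma_um = 2, streak_amplitude = 60,
                              noise_sigma = 3, rng_seed = 1L) {
  if (lumen_diameter_um <= 0) stop("lumen_diameter_um must be positive")
  if (um_per_px <= 0) stop("um_per_px must be positive")
  if (pulsatility_fraction < 0 || pulsatility_fraction >= 1) {
    stop("pulsatility_fraction must lie in [0, 1)")
  }
  # streaks stay connected only if a cell advances less than about twice its
  # streak width per line period
  if (abs(true_velocity_mm_s) * 1000 / line_rate_hz >= 2 * streak_sigma_um) {
    stop("line rate too low to resolve streaks at this velocity/scale")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(
    list(true_velocity_mm_s = true_velocity_mm_s,
         lumen_diameter_um = lumen_diameter_um, line_rate_hz = line_rate_hz,
         duration_s = duration_s, um_per_px = um_per_px,
         pulsatility_fraction = pulsatility_fraction,
         cardiac_freq_hz = cardiac_freq_hz, streak_density = streak_density,
         streak_sigma_um = streak_sigma_um,
         streak_amplitude = streak_amplitude, noise_sigma = noise_sigma,
         rng_seed = as.integer(rng_seed)),
    class = "vessel_sim_config"
  )
}

# Integrated displacement (um) of the pulsatile flow between 0 and t:
# S(t) = integral of V0*(1+m*sin(2*pi*f*s)) ds, in um (V0 in mm/s -> um/s).
flow_displacement_um <- function(t, v0_mm_s, m, f_hz) {
  v0 <- v0_mm_s * 1000
  if (m == 0 || f_hz <= 0) return(v0 * t)
  v0 * (t + m / (2 * pi * f_hz) * (1 - cos(2 * pi * f_hz * t)))
}

#' Simulate a single-vessel space-time image with known truth
#'
#' Renders a kymograph (rows = position along the scanned line, columns =
#' time at the line rate) containing a bright lumen band of known width and
#' Gaussian cell streaks advected by the pulsatile velocity
#' `v(t) = V0*(1 + m*sin(2*pi*f_c*t))`. Cells enter the band at one edge at
#' Poisson-distributed times and traverse it; reversing the sign of `V0`
#' mirrors the streak slopes.
#'
#' The returned truth carries the generative parameters and, for each streak,
#' its exact `(t, x)` path samples inside the band, which an independent
#' per-streak regression can turn into a reference velocity.
#'
#' @param config a [vessel_sim_config()].
#' @return list with `kymo` (a [kymograph()]), and `truth` (list with `v0_mm_s`,
#'   `m`, `cardiac_freq_hz`, `diameter_um`, `band_rows` (lumen row range),
#'   and `streaks`, a data.frame `streak_id, t_s, x_um` of true path samples).
#' @export
simulate_vessel_kymograph <- function(config) {
  stopifnot(inherits(config, "vessel_sim_config"))
  with_seed(config$rng_seed, {
    upp <- config$um_per_px
    lr <- config$line_rate_hz
    n_cols <- as.integer(round(config$duration_s * lr))
    margin_um <- max(10, config$lumen_diameter_um / 4)
    band_um <- config$lumen_diameter_um
    height_um <- band_um + 2 * margin_um
    n_rows <- as.integer(ceiling(height_um / upp))
    band_lo_um <- margin_um
    band_hi_um <- margin_um + band_um

    t_cols <- (seq_len(n_cols) - 1) / lr
    v0 <- config$true_velocity_mm_s
    m <- config$pulsatility_fraction
    fc <- config$cardiac_freq_hz

    # lumen band, softly anti-aliased edges, brighter than surround
    row_um <- (seq_len(n_rows) - 1) * upp
    in_band <- pmin(pmax((band_um / 2 + 0.5 * upp -
                            abs(row_um - (band_lo_um + band_um / 2))) / upp,
                         0), 1)
    img <- matrix(rep(50 + 30 * in_band, n_cols), n_rows, n_cols)

    # entry times: Poisson stream at streak_density per 100 ms, entering
    # before t=0 as well so the image is populated from the first column
    rate_s <- config$streak_density / 0.1
    travel_s <- if (abs(v0) > 0) {
      band_um / (abs(v0) * 1000) * 2  # generous traversal bound
    } else {
      config$duration_s
    }
    n_exp <- stats::rpois(1, rate_s * (config$duration_s + travel_s))
    t_enter <- sort(stats::runif(n_exp, -travel_s, config$duration_s))
    entry_xs <- if (v0 > 0) {
      rep(band_lo_um, length(t_enter))
    } else if (v0 < 0) {
      rep(band_hi_um, length(t_enter))
    } else {
      stats::runif(length(t_enter), band_lo_um, band_hi_um)
    }

    sig_px <- config$streak_sigma_um / upp
    streaks <- vector("list", length(t_enter))
    S_cols <- flow_displacement_um(t_cols, v0, m, fc)
    # at V0 = 0 a cell never leaves along the line; bound its dwell instead
    # (cells drift out of the thin scan plane), else streaks are static and
    # indistinguishable from the lumen background
    dwell_s <- if (v0 == 0) {
      stats::rexp(length(t_enter), rate = 1 / 0.02)
    } else {
      rep(Inf, length(t_enter))
    }
    for (k in seq_along(t_enter)) {
      Sk <- flow_displacement_um(t_enter[k], v0, m, fc)
      x_um <- entry_xs[k] + (S_cols - Sk)      # position along line, um
      sel <- which(t_cols >= t_enter[k] &
                     t_cols <= t_enter[k] + dwell_s[k] &
                     x_um >= band_lo_um - 2 * upp &
                     x_um <= band_hi_um + 2 * upp)
      if (length(sel) < 2) next
      rows_c <- x_um[sel] / upp + 1            # 1-based fractional row
      # stamp a vertical Gaussian at each selected column
      ext <- ceiling(3 * sig_px)
      for (i in seq_along(sel)) {
        rc <- rows_c[i]
        r0 <- max(1L, floor(rc) - ext); r1 <- min(n_rows, ceiling(rc) + ext)
        if (r0 > r1) next
        img[r0:r1, sel[i]] <- img[r0:r1, sel[i]] +
          config$streak_amplitude * exp(-((r0:r1) - rc)^2 / (2 * sig_px^2))
      }
      inside <- x_um[sel] >= band_lo_um & x_um[sel] <= band_hi_um
      if (!any(inside)) next
      streaks[[k]] <- data.frame(streak_id = k, t_s = t_cols[sel][inside],
                                 x_um = x_um[sel][inside])
    }
    streaks <- do.call(rbind, streaks[!vapply(streaks, is.null, logical(1))])
    if (is.null(streaks)) {
      streaks <- data.frame(streak_id = integer(), t_s = numeric(),
                            x_um = numeric())
    }

    if (config$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(n_rows * n_cols, 0,
                                       config$noise_sigma), n_rows, n_cols)
    }

    list(kymo = kymograph(img, um_per_px = upp, line_rate_hz = lr),
         truth = list(v0_mm_s = v0, m = m, cardiac_freq_hz = fc,
                      diameter_um = config$lumen_diameter_um,
                      band_rows = c(band_lo_um / upp + 1,
                                    band_hi_um / upp + 1),
                      streaks = streaks))
  })
}

#' Simulate a vessel video for motion-contrast diametry
#'
#' Produces a registered-stage video of a straight vessel of known lumen
#' diameter at an arbitrary in-plane angle: pixels inside the lumen carry
#' frame-to-frame fluctuating intensity (moving blood), pixels outside carry
#' a static texture plus sensor noise. The lumen edge is anti-aliased at
#' sub-pixel resolution so full-width-at-half-maximum diametry can recover
#' the true width to about a micrometre.
#'
#' @param diameter_um true inner lumen diameter (um).
#' @param angle_deg vessel axis angle, degrees counter-clockwise from the
#'   column axis.
#' @param shape integer `(rows, cols)` frame size in px.
#' @param um_per_px spatial scale.
#' @param n_frames number of frames (>= 10 for motion contrast).
#' @param flow_sd temporal SD of intra-lumen intensity (moving blood).
#' @param noise_sigma sensor noise SD everywhere.
#' @param rng_seed integer seed.
#' @return list `stack` (a [video_stack()], stage `"registered"`), `mask`
#'   (logical matrix, TRUE inside the lumen), `truth` (list with
#'   `diameter_um`, `angle_deg`, `center_px`).
#' @export
simulate_vessel_video <- function(diameter_um, angle_deg = 0,
                                  shape = c(96, 96), um_per_px = 1,
                                  n_frames = 40, flow_sd = 25,
                                  noise_sigma = 2, rng_seed = 1L) {
  stopifnot(diameter_um > 0, n_frames >= 2)
  with_seed(rng_seed, {
    R <- shape[1]; C <- shape[2]
    cr <- (R + 1) / 2; cc <- (C + 1) / 2
    th <- angle_deg * pi / 180
    # signed distance (um) of each pixel from the vessel centreline
    rr <- matrix(seq_len(R), R, C) - cr
    cs <- matrix(seq_len(C), R, C, byrow = TRUE) - cc
    d_um <- (rr * cos(th) - cs * sin(th)) * um_per_px
    # anti-aliased lumen membership in [0,1]
    w <- pmin(pmax((diameter_um / 2 + 0.5 * um_per_px - abs(d_um)) /
                     um_per_px, 0), 1)
    static_bg <- 80 + 8 * matrix(stats::rnorm(R * C), R, C)
    frames <- lapply(seq_len(n_frames), function(f) {
      flow <- matrix(stats::rnorm(R * C, 0, flow_sd), R, C)
      static_bg + w * (30 + flow) +
        matrix(stats::rnorm(R * C, 0, noise_sigma), R, C)
    })
    list(stack = video_stack(frames, um_per_px = um_per_px,
                             stage = "registered"),
         mask = w > 0.5,
         truth = list(diameter_um = diameter_um, angle_deg = angle_deg,
                      center_px = c(cr, cc)))
  })
}
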