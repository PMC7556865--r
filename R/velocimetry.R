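#' Estimate blood velocity from a kymograph
#'
#' Splits the space-time image into windows of `window_ms` columns and, in
#' each, measures the dominant streak slope by shifted-column
#' cross-correlation: columns a lag of `delta` line periods apart are
#' correlated as a function of row shift, and the correlation peak sits at
#' `slope * delta` rows. A first pass at `delta = 1` brackets the slope; a
#' second pass with an adaptively enlarged lag (bounded by the streak
#' traversal so correlated cell pairs remain in both columns) localises the
#' peak with parabolic sub-pixel refinement, giving sub-percent slope
#' resolution across two decades of velocity. Slope (rows/column) converts
#' to velocity as `v = slope * um_per_px * line_rate_hz / 1000` mm/s; the
#' sign of the slope carries the flow direction.
#'
#' Windows without usable streak contrast (normalised correlation peak
#' below `min_corr`) yield `NA`, never 0: a featureless window has no
#' defined velocity, and zero-filling would bias cycle averages.
#'
#' @param kymo a [kymograph()].
#' @param window_ms analysis window length in milliseconds (default 50).
#' @param v_max_mm_s magnitude bound of the slope search (default 60).
#' @param min_corr minimum normalised correlation at the peak for a window
#'   to count as defined (default 0.05).
#' @return data.frame `t_s` (window centre), `velocity_mm_s` (`NA` when
#'   undefined).
#' @export
estimate_velocity <- function(kymo, window_ms = 50, v_max_mm_s = 60,
                              min_corr = 0.05) {
  stopifnot(inherits(kymo, "kymograph"))
  img <- kymo$image
  ncols <- ncol(img)
  win <- max(16L, as.integer(round(window_ms / 1000 * kymo$line_rate_hz)))
  if (win > ncols) win <- ncols
  starts <- seq.int(1L, ncols - win + 1L, by = win)
  slope_per_mms <- 1000 / (kymo$um_per_px * kymo$line_rate_hz)
  s_max <- v_max_mm_s * slope_per_mms
  out <- data.frame(t_s = numeric(length(starts)),
                    velocity_mm_s = numeric(length(starts)))
  for (i in seq_along(starts)) {
    w <- img[, starts[i]:(starts[i] + win - 1L), drop = FALSE]
    w <- w - rowMeans(w)          # remove the static lumen-band profile
    fit <- xcorr_slope(w, s_max)
    out$t_s[i] <- (starts[i] + win / 2 - 1) / kymo$line_rate_hz
    out$velocity_mm_s[i] <- if (is.na(fit$slope) || fit$corr < min_corr) {
      NA_real_
    } else {
      fit$slope / slope_per_mms
    }
  }
  out
}

# Normalised cross-correlation between columns `delta` apart, as a function
# of row shift `shifts`. Returns the correlation curve.
column_pair_corr <- function(w, delta, shifts) {
  R <- nrow(w); C <- ncol(w)
  if (delta >= C) return(rep(NA_real_, length(shifts)))
  A <- w[, 1:(C - delta), drop = FALSE]
  B <- w[, (1 + delta):C, drop = FALSE]
  norm <- sqrt(sum(A^2) * sum(B^2))
  if (norm == 0) return(rep(NA_real_, length(shifts)))
  vapply(shifts, function(d) {
    ra <- max(1, 1 - d):min(R, R - d)
    if (length(ra) < 4) return(NA_real_)
    sum(A[ra, , drop = FALSE] * B[ra + d, , drop = FALSE]) / norm
  }, numeric(1))
}

# Two-stage cross-correlation slope fit; returns slope (rows/col) and the
# normalised correlation at the refined peak.
xcorr_slope <- function(w, s_max) {
  R <- nrow(w); C <- ncol(w)
  d_max <- min(R - 4, ceiling(s_max) + 2)
  shifts1 <- -d_max:d_max
  cc1 <- column_pair_corr(w, 1L, shifts1)
  if (all(is.na(cc1))) return(list(slope = NA_real_, corr = NA_real_))
  p1 <- which.max(cc1)
  s1 <- refine_peak(shifts1, cc1, p1)
  # second pass: larger lag for precision, bounded so a streak seen in one
  # column is still present delta columns later. The bound from the slope
  # (band traversal) can overestimate the feature lifetime (e.g. nearly
  # static streaks that dwell briefly), so if the correlation collapses at
  # the chosen lag it is halved until the peak survives.
  traversal <- R / max(abs(s1), 1e-9)
  delta2 <- max(2L, min(floor(traversal / 2), floor(C / 3), 150L))
  best1 <- max(cc1, na.rm = TRUE)
  repeat {
    # cover a generous slope interval around the bracket: the coarse s1 can
    # be off by tens of percent on a broad unit-lag correlation peak
    center <- s1 * delta2
    lo <- min(center / 1.8, center * 1.8) - 6
    hi <- max(center / 1.8, center * 1.8) + 6
    shifts2 <- floor(lo):ceiling(hi)
    shifts2 <- shifts2[abs(shifts2) <= R - 5]
    cc2 <- if (length(shifts2) >= 3) {
      column_pair_corr(w, delta2, shifts2)
    } else {
      NA_real_
    }
    ok <- !all(is.na(cc2)) && max(cc2, na.rm = TRUE) >= 0.5 * best1
    if (ok || delta2 <= 4L) break
    delta2 <- delta2 %/% 2L
  }
  if (!ok) return(list(slope = s1, corr = best1))
  p2 <- which.max(cc2)
  d2 <- refine_peak(shifts2, cc2, p2)
  list(slope = d2 / delta2, corr = max(cc2, na.rm = TRUE))
}

# Sub-pixel peak location by least-squares quadratic over +/-3 neighbours
# (robust on broad, noise-flattened correlation peaks); falls back to the
# 3-point parabola, then to the grid argmax.
refine_peak <- function(x, y, idx) {
  use <- max(1, idx - 3):min(length(y), idx + 3)
  use <- use[!is.na(y[use])]
  if (length(use) >= 5) {
    xs <- x[use] - x[idx]
    fit <- stats::lm.fit(cbind(1, xs, xs^2), y[use])
    a <- fit$coefficients[3]; b <- fit$coefficients[2]
    if (is.finite(a) && a < 0) {
      v <- -b / (2 * a)
      if (abs(v) <= max(abs(xs))) return(x[idx] + v)
    }
  }
  if (idx > 1 && idx < length(y) && !anyNA(y[(idx - 1):(idx + 1)])) {
    return(x[idx] + parabolic_offset(y[idx - 1], y[idx], y[idx + 1]))
  }
  x[idx]
}

#' Cycle-averaged velocity
#'
#' Mean of a velocity series over the largest whole number of cardiac
#' cycles it spans, excluding undefined (`NA`) windows. Averaging over an
#' integer number of cycles cancels the pulsatile modulation, so for
#' `v(t) = V0*(1 + m*sin(2*pi*f_c*t))` the result is `V0`.
#'
#' @param series data.frame from [estimate_velocity()] (`t_s`,
#'   `velocity_mm_s`), or a numeric vector with `t_s` supplied separately.
#' @param cardiac_freq_hz cardiac frequency in Hz (default 6, mouse).
#' @param t_s sample times (needed if `series` is a bare vector).
#' @return scalar mm/s.
#' @export
cycle_average_velocity <- function(series, cardiac_freq_hz = 6, t_s = NULL) {
  if (is.data.frame(series)) {
    t_s <- series$t_s
    v <- series$velocity_mm_s
  } else {
    v <- series
    if (is.null(t_s)) stop("t_s required for a bare velocity vector")
  }
  span <- max(t_s) - min(t_s)
  n_cycles <- floor(span * cardiac_freq_hz + 1e-9)
  if (n_cycles < 2) stop("series must span at least 2 cardiac cycles")
  t_end <- min(t_s) + n_cycles / cardiac_freq_hz
  keep <- t_s <= t_end + 1e-9 & !is.na(v)
  if (!any(keep)) stop("no defined velocity windows inside the cycle span")
  mean(v[keep])
}

#' Motion-contrast image of a registered stack
#'
#' Per-pixel temporal standard deviation divided by temporal mean: pixels
#' seeing moving blood fluctuate strongly and map bright, static tissue maps
#' near zero, and the ratio is invariant to a global intensity gain. Pixels
#' with non-positive temporal mean are set to 0 and counted in the returned
#' `n_zero_mean` flag.
#'
#' @param stack a [video_stack()] at stage `"registered"` with >= 10 frames.
#' @return object of class `motion_contrast`: list `image` (matrix),
#'   `um_per_px`, `n_frames`, `n_zero_mean`.
#' @export
build_motion_contrast <- function(stack) {
  stopifnot(inherits(stack, "video_stack"))
  if (stack$stage != "registered") {
    stop("motion contrast requires a registered stack (got '",
         stack$stage, "')")
  }
  n <- n_frames(stack)
  if (n < 10) stop("motion contrast needs >= 10 frames")
  acc <- Reduce(`+`, stack$frames) / n
  acc2 <- Reduce(`+`, lapply(stack$frames, function(m) m^2)) / n
  sdm <- sqrt(pmax(acc2 - acc^2, 0) * n / (n - 1))
  bad <- !is.finite(acc) | acc <= 0
  mc <- sdm / acc
  mc[bad] <- 0
  structure(list(image = mc, um_per_px = stack$um_per_px, n_frames = n,
                 n_zero_mean = sum(bad)),
            class = "motion_contrast")
}

#' Lumen diameter from a motion-contrast image
#'
#' Measures the inner lumen as the full width at half maximum (FWHM) of the
#' vessel's motion-contrast profile taken perpendicular to the locally
#' fitted centreline. The vessel axis is found by a weighted principal-axis
#' fit of the suprathreshold motion-contrast pixels (handling in-plane
#' vessel orientation/tortuosity); profiles are sampled at quarter-pixel
#' steps by bilinear interpolation at several stations along the axis and
#' averaged; the half-maximum crossings (above the tail baseline) are
#' located with sub-pixel linear interpolation.
#'
#' @param mc a [build_motion_contrast()] image.
#' @param center optional `(row, col)` point on the vessel (1-based px);
#'   defaults to the weighted centroid of the suprathreshold mask.
#' @param n_stations number of perpendicular profiles to average.
#' @param station_spacing_px spacing of stations along the axis.
#' @return diameter in micrometres.
#' @export
measure_diameter <- function(mc, center = NULL, n_stations = 11L,
                             station_spacing_px = 2) {
  stopifnot(inherits(mc, "motion_contrast"))
  img <- mc$image
  thr <- 0.5 * max(img)
  mask <- img > thr
  if (sum(mask) < 10) stop("no clear vessel signal in motion contrast")
  idx <- which(mask, arr.ind = TRUE)
  wgt <- img[mask]
  mu <- c(sum(idx[, 1] * wgt), sum(idx[, 2] * wgt)) / sum(wgt)
  if (is.null(center)) center <- mu
  # weighted principal axis = local vessel direction
  dr <- idx[, 1] - mu[1]; dc <- idx[, 2] - mu[2]
  cov <- matrix(c(sum(wgt * dr * dr), sum(wgt * dr * dc),
                  sum(wgt * dr * dc), sum(wgt * dc * dc)), 2, 2) / sum(wgt)
  ev <- eigen(cov, symmetric = TRUE)
  axis_v <- ev$vectors[, 1]          # along the vessel
  perp_v <- c(-axis_v[2], axis_v[1]) # across the vessel
  half_len_um <- max(nrow(img), ncol(img)) * mc$um_per_px
  step_px <- 0.25
  n_half <- ceiling(half_len_um / mc$um_per_px / step_px / 2)
  offs <- (-n_half:n_half) * step_px
  stations <- (-(n_stations %/% 2)):(n_stations %/% 2) * station_spacing_px
  prof_acc <- numeric(length(offs)); prof_cnt <- numeric(length(offs))
  for (s in stations) {
    pr <- center[1] + s * axis_v[1] + offs * perp_v[1]
    pc <- center[2] + s * axis_v[2] + offs * perp_v[2]
    v <- bilinear_sample(img, pr, pc)
    ok <- !is.na(v)
    prof_acc[ok] <- prof_acc[ok] + v[ok]
    prof_cnt[ok] <- prof_cnt[ok] + 1
  }
  prof <- prof_acc / pmax(prof_cnt, 1)
  prof[prof_cnt == 0] <- NA
  fwhm_px <- profile_fwhm(prof, step_px)
  if (is.na(fwhm_px)) stop("no single clear peak in the vessel profile")
  fwhm_px * mc$um_per_px
}

# Bilinear sampling of matrix m at fractional (row, col) vectors; NA
# outside the image.
bilinear_sample <- function(m, r, c) {
  R <- nrow(m); C <- ncol(m)
  out <- rep(NA_real_, length(r))
  ok <- r >= 1 & r <= R & c >= 1 & c <= C
  if (!any(ok)) return(out)
  r <- pmin(r[ok], R - 1e-9); c <- pmin(c[ok], C - 1e-9)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  v <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
  out[ok] <- v
  out
}

# FWHM of a single-peaked profile sampled at `step` spacing, with sub-pixel
# interpolation of the half-max crossings above the tail baseline.
profile_fwhm <- function(prof, step) {
  ok <- which(!is.na(prof))
  if (length(ok) < 5) return(NA_real_)
  p <- prof[ok]
  n <- length(p)
  tail_n <- max(3L, round(n * 0.1))
  baseline <- stats::median(c(p[seq_len(tail_n)], p[(n - tail_n + 1):n]))
  pk <- which.max(p)
  half <- baseline + (p[pk] - baseline) / 2
  left <- NA_real_; right <- NA_real_
  for (i in seq(pk, 2)) {
    if (p[i - 1] <= half && p[i] > half) {
      left <- (i - 1) + (half - p[i - 1]) / (p[i] - p[i - 1])
      break
    }
  }
  for (i in seq(pk, n - 1)) {
    if (p[i + 1] <= half && p[i] > half) {
      right <- i + (p[i] - half) / (p[i] - p[i + 1])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) * step
}

#' Volumetric flow from velocity and diameter
#'
#' `Q = k * (pi/4) * D^2 * V` with `D` in micrometres and `V` in mm/s,
#' returned in nL/s. The profile factor `k` corrects centreline to
#' cross-section mean velocity; it defaults to 1, under which relative flow
#' changes are exact and absolute flows are proportional.
#'
#' @param velocity_mm_s signed velocity in mm/s.
#' @param diameter_um lumen diameter in micrometres (> 0).
#' @param k velocity profile factor (default 1).
#' @return flow in nL/s.
#' @export
compute_flow <- function(velocity_mm_s, diameter_um, k = 1.0) {
  if (any(diameter_um <= 0)) stop("diameter must be positive")
  k * (pi / 4) * (diameter_um * 1e-3)^2 * velocity_mm_s * 1e3
}

#' One vessel measurement record
#'
#' @param vessel_id identifier.
#' @param vessel_type `"arteriole"` or `"venule"`.
#' @param timepoint timepoint label (e.g. `"baseline"`, `"6h"`).
#' @param velocity_mm_s cycle-averaged velocity.
#' @param diameter_um lumen diameter.
#' @param k profile factor used for the flow.
#' @return one-row data.frame including the derived `flow_nl_s`.
#' @export
vessel_measurement <- function(vessel_id, vessel_type, timepoint,
                               velocity_mm_s, diameter_um, k = 1.0) {
  vessel_type <- match.arg(vessel_type, c("arteriole", "venule"))
  data.frame(vessel_id = vessel_id, vessel_type = vessel_type,
             timepoint = timepoint, velocity_mm_s = velocity_mm_s,
             diameter_um = diameter_um,
             flow_nl_s = compute_flow(velocity_mm_s, diameter_um, k), k = k)
}
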