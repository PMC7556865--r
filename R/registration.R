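#' Correct sinusoidal fast-axis scan distortion
#'
#' Inverse resampling of [apply_scan_distortion()]: restores uniform spatial
#' sampling along the fast (column) axis given the distortion amplitude of
#' the acquisition. The forward map is
#' `x = (1-a)*u + a*(1-cos(pi*u))/2`; this routine evaluates its numerical
#' inverse on a fine grid and resamples each row by linear interpolation.
#' The map is not an involution, so correcting an already corrected frame is
#' *not* a no-op; the stack `stage` flag guards against that misuse.
#'
#' @param frame numeric matrix.
#' @param amplitude distortion amplitude `a` in `[0, 1]` (0 = identity).
#' @return corrected matrix, same dimensions.
#' @export
desinusoid_frame <- function(frame, amplitude) {
  check_amplitude(amplitude)
  if (amplitude == 0) return(frame)
  C <- ncol(frame)
  grid <- seq(0, 1, length.out = 10L * C)
  inv <- stats::approx(sinusoid_map(grid, amplitude), grid,
                       xout = (seq_len(C) - 1) / (C - 1), rule = 2)$y
  resample_cols(frame, inv * (C - 1) + 1)
}

#' Desinusoid every frame of a stack
#'
#' @param stack a [video_stack()] at stage `"raw"`.
#' @param amplitude distortion amplitude in `[0, 1]`.
#' @return the corrected stack at stage `"desinusoided"`.
#' @export
desinusoid_video <- function(stack, amplitude) {
  stopifnot(inherits(stack, "video_stack"))
  if (stack$stage != "raw") {
    stop("desinusoiding expects a raw stack (got stage '", stack$stage, "')")
  }
  stack$frames <- lapply(stack$frames, desinusoid_frame, amplitude = amplitude)
  advance_stage(stack, "desinusoided")
}

#' Estimate the translation aligning a frame to a reference
#'
#' Whole-frame FFT cross-correlation with parabolic sub-pixel refinement of
#' the correlation peak. The returned `(row, col)` shift is the translation
#' to *apply to the frame* so it aligns with the reference: if the frame is
#' the reference translated by `(+5, -3)` px, the estimate is `(-5, +3)`.
#' For integer shifts of a well-textured scene the integer part is exact.
#'
#' @param frame numeric matrix (NA allowed; replaced by the frame mean).
#' @param reference numeric matrix, same dimensions, non-constant.
#' @param subpixel add parabolic sub-pixel refinement (default TRUE).
#' @return numeric length-2 `(row, col)` shift in pixels.
#' @export
estimate_shift <- function(frame, reference, subpixel = TRUE) {
  if (!all(dim(frame) == dim(reference))) {
    stop("frame and reference must have the same dimensions")
  }
  f <- fill_na(frame); g <- fill_na(reference)
  if (stats::sd(f) == 0 || stats::sd(g) == 0) {
    stop("cannot register a constant (zero-variance) frame")
  }
  f <- f - mean(f); g <- g - mean(g)
  R <- nrow(f); C <- ncol(f)
  # cross-correlation of reference with frame; peak at the frame's offset
  cc <- Re(stats::fft(stats::fft(g) * Conj(stats::fft(f)), inverse = TRUE))
  p <- which.max(cc)
  pr <- (p - 1) %% R; pc <- (p - 1) %/% R
  dr <- if (pr > R / 2) pr - R else pr
  dc <- if (pc > C / 2) pc - C else pc
  if (subpixel) {
    dr <- dr + parabolic_offset(cc[wrap_index(pr - 1, R) + 1, pc + 1],
                                cc[pr + 1, pc + 1],
                                cc[wrap_index(pr + 1, R) + 1, pc + 1])
    dc <- dc + parabolic_offset(cc[pr + 1, wrap_index(pc - 1, C) + 1],
                                cc[pr + 1, pc + 1],
                                cc[pr + 1, wrap_index(pc + 1, C) + 1])
  }
  c(dr, dc)
}

wrap_index <- function(i, n) ((i %% n) + n) %% n

# Vertex offset of the parabola through (-1, ym), (0, y0), (+1, yp).
parabolic_offset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym - yp) / den
  if (!is.finite(off) || abs(off) > 1) 0 else off
}

fill_na <- function(m) {
  if (anyNA(m)) m[is.na(m)] <- mean(m, na.rm = TRUE)
  m
}

# Sharpness score used to pick a registration reference frame.
frame_sharpness <- function(frame) {
  f <- fill_na(frame)
  mean(diff(f)^2) + mean(t(diff(t(f)))^2)
}

#' Register a stack by whole-frame translation
#'
#' Estimates each frame's translation relative to a reference frame by FFT
#' cross-correlation and applies the rounded integer shift. Pixels carried
#' out of the field are set to `NA` (a sentinel that downstream temporal
#' averaging excludes, avoiding edge-darkening bias).
#'
#' By default the reference is the frame of median sharpness within the
#' first second of the recording, which is robust to transient blinks or
#' media opacity.
#'
#' When the field contains bright *moving* objects (migrating cells) whose
#' correlation energy rivals the static background, the correlation peak is
#' dragged along with them. The `exclude` argument implements the standard
#' cure — moving-object masking: listed disks (in raw-frame pixel
#' coordinates) are replaced by the frame median *for shift estimation
#' only*, so the static scene alone drives alignment. A first registration
#' pass plus detection supplies the disks; see [raw_exclusion_disks()].
#'
#' @param stack a [video_stack()] at stage `"raw"` or `"desinusoided"`
#'   (a registered stack is accepted and passes through idempotently).
#' @param reference_index 1-based reference frame index, or `NULL` for the
#'   median-sharpness default.
#' @param exclude optional data.frame `frame, row_px, col_px, radius_px`
#'   (1-based raw-frame coordinates) of moving-object disks to mask during
#'   shift estimation.
#' @param fill_image optional static background image (e.g.
#'   [static_background()] of a first-pass registration): masked disks are
#'   filled from it instead of with the frame median, so the estimation
#'   frames contain no moving structure at all — a flat fill still leaves a
#'   moving hole whose boundary can drag the correlation peak slightly.
#' @param fill_shifts the first-pass shift matrix mapping raw coordinates
#'   into `fill_image` coordinates (raw position + shift).
#' @return list `stack` (stage `"registered"`) and `shifts` (n x 2 matrix of
#'   applied `(row, col)` shifts, reference row = `(0, 0)`).
#' @export
register_video <- function(stack, reference_index = NULL, exclude = NULL,
                           fill_image = NULL, fill_shifts = NULL) {
  stopifnot(inherits(stack, "video_stack"))
  if (stack$stage == "averaged") {
    stop("cannot register an averaged stack")
  }
  n <- n_frames(stack)
  est_frame <- function(f) {
    fr <- stack$frames[[f]]
    if (is.null(exclude)) return(fr)
    rows <- exclude[exclude$frame == f, , drop = FALSE]
    if (nrow(rows) == 0) return(fr)
    med <- stats::median(fr, na.rm = TRUE)
    fs <- if (!is.null(fill_shifts)) fill_shifts[f, ] else c(0, 0)
    for (i in seq_len(nrow(rows))) {
      fr <- mask_disk(fr, rows$row_px[i], rows$col_px[i],
                      rows$radius_px[i], med, fill_image, fs)
    }
    fr
  }
  if (is.null(reference_index)) {
    n_first <- max(1L, min(n, round(1 / stack$frame_interval_s)))
    sharp <- vapply(stack$frames[seq_len(n_first)], frame_sharpness,
                    numeric(1))
    reference_index <- which(rank(sharp, ties.method = "first") ==
                               ceiling(n_first / 2))[1]
  }
  ref <- est_frame(reference_index)
  shifts <- matrix(0, n, 2)
  for (f in seq_len(n)) {
    if (f == reference_index) next
    shifts[f, ] <- round(estimate_shift(est_frame(f), ref,
                                        subpixel = TRUE))
  }
  stack$frames <- lapply(seq_len(n), function(f) {
    if (all(shifts[f, ] == 0)) stack$frames[[f]]
    else translate_frame(stack$frames[[f]], shifts[f, 1], shifts[f, 2],
                         fill = NA_real_)
  })
  list(stack = advance_stage(stack, "registered"), shifts = shifts)
}

mask_disk <- function(frame, r, c, radius, fill, fill_image = NULL,
                      fill_shift = c(0, 0)) {
  r0 <- max(1L, floor(r - radius)); r1 <- min(nrow(frame), ceiling(r + radius))
  c0 <- max(1L, floor(c - radius)); c1 <- min(ncol(frame), ceiling(c + radius))
  if (r0 > r1 || c0 > c1) return(frame)
  d2 <- outer((r0:r1 - r)^2, (c0:c1 - c)^2, "+")
  patch <- frame[r0:r1, c0:c1]
  inside <- d2 <= radius^2
  if (is.null(fill_image)) {
    patch[inside] <- fill
  } else {
    rr <- pmin(pmax((r0:r1) + round(fill_shift[1]), 1L), nrow(fill_image))
    cc <- pmin(pmax((c0:c1) + round(fill_shift[2]), 1L), ncol(fill_image))
    vals <- fill_image[rr, cc]
    vals[is.na(vals)] <- fill
    patch[inside] <- vals[inside]
  }
  frame[r0:r1, c0:c1] <- patch
  frame
}

#' Static background estimate of a registered stack
#'
#' Pixelwise temporal median over a subsample of frames: structures that
#' stay put survive, objects that move far enough are suppressed. Used to
#' fill moving-object masks during second-pass registration.
#'
#' @param stack a registered [video_stack()].
#' @param step use every `step`-th frame (default chosen to use about 250).
#' @return numeric matrix, `NA` where no frame had valid data.
#' @export
static_background <- function(stack,
                              step = max(1L, n_frames(stack) %/% 250L)) {
  stopifnot(inherits(stack, "video_stack"))
  idx <- seq.int(1L, n_frames(stack), by = step)
  arr <- vapply(stack$frames[idx], as.vector,
                numeric(length(stack$frames[[1]])))
  med <- apply(arr, 1, stats::median, na.rm = TRUE)
  matrix(med, nrow(stack$frames[[1]]), ncol(stack$frames[[1]]))
}

#' Map averaged-frame detections to raw-frame exclusion disks
#'
#' Converts detections made on a registered, temporally averaged stack back
#' into raw-frame coordinates so a second registration pass can mask the
#' moving cells ([register_video()]'s `exclude` argument). Averaged frame
#' `f` covers raw frames `(f-1)*stride + 1 .. (f-1)*stride + window`, and a
#' registered position maps to a raw position by subtracting the shift that
#' was applied to that raw frame.
#'
#' @param detections data.frame with `frame` (averaged index), `row_px`,
#'   `col_px` (0-based registered coordinates).
#' @param shifts the first-pass shift matrix from [register_video()].
#' @param window,stride the [temporal_average()] parameters used.
#' @param radius_px mask radius around each cell (a generous multiple of
#'   the cell radius absorbs first-pass position error).
#' @return data.frame `frame, row_px, col_px, radius_px` in 1-based raw
#'   coordinates.
#' @export
raw_exclusion_disks <- function(detections, shifts, window = 5L,
                                stride = window, radius_px) {
  rows <- lapply(seq_len(nrow(detections)), function(i) {
    f_avg <- detections$frame[i]
    raw <- (f_avg - 1L) * stride + seq_len(window)
    raw <- raw[raw <= nrow(shifts)]
    data.frame(frame = raw,
               row_px = detections$row_px[i] + 1 - shifts[raw, 1],
               col_px = detections$col_px[i] + 1 - shifts[raw, 2],
               radius_px = radius_px)
  })
  do.call(rbind, rows)
}

#' Two-pass registration robust to migrating cells
#'
#' Fields whose moving cells carry correlation energy comparable to the
#' static background defeat single-pass registration: the correlation peak
#' is dragged along with the cells, which shows up as a slow common-mode
#' position drift in every track. This wrapper implements the standard
#' moving-object-masking cure: register once, detect cells on the averaged
#' first pass, interpolate their positions along linked tracks (so
#' transient detection dropouts stay masked), map them back to raw-frame
#' coordinates, and re-estimate all shifts with generous disks around every
#' cell replaced by a static-background estimate. Only shift *estimation*
#' sees the masks; the returned frames are the original data translated by
#' the refined shifts.
#'
#' @param stack a raw or desinusoided [video_stack()].
#' @param model a [train_detector()] model for the first-pass detection.
#' @param window,stride temporal-averaging parameters for the first-pass
#'   detection (defaults 5/5, the detection pre-processing).
#' @param mask_radius_factor exclusion-disk radius as a multiple of the
#'   nominal cell radius (default 3.5 — covers the full rendered profile).
#' @param threshold,min_area_px passed to [detect_stack()].
#' @param reference_index optional fixed reference frame.
#' @return as [register_video()]: list `stack`, `shifts`.
#' @export
register_video_robust <- function(stack, model, window = 5L,
                                  stride = window,
                                  mask_radius_factor = 3.5,
                                  threshold = 0.90, min_area_px = 3L,
                                  reference_index = NULL) {
  stopifnot(inherits(stack, "video_stack"),
            inherits(model, "detector_model"))
  pass1 <- register_video(stack, reference_index)
  avg1 <- temporal_average(pass1$stack, window, stride)
  det1 <- detect_stack(model, avg1, threshold = threshold,
                       min_area_px = min_area_px, refine = "none")
  if (is.null(det1) || nrow(det1) == 0) return(pass1)
  tr1 <- link_detections(det1, max_gap_frames = 10L,
                         frame_times = avg1$timestamps)
  upp <- stack$um_per_px
  det_full <- do.call(rbind, lapply(track_split(tr1), function(g) {
    fr <- min(g$frame):max(g$frame)
    data.frame(frame = fr,
               row_px = stats::approx(g$frame, g$row_um / upp, fr)$y,
               col_px = stats::approx(g$frame, g$col_um / upp, fr)$y)
  }))
  excl <- raw_exclusion_disks(det_full, pass1$shifts, window, stride,
                              radius_px = mask_radius_factor *
                                model$radius_px)
  bg <- static_background(pass1$stack)
  shifts1 <- pass1$shifts
  rm(pass1, avg1)
  register_video(stack, reference_index, exclude = excl,
                 fill_image = bg, fill_shifts = shifts1)
}

#' Temporal (running) frame averaging
#'
#' Averages `window` consecutive registered frames, advancing by `stride`
#' frames between outputs, excluding `NA` sentinel pixels from each mean.
#' With `stride = window` this implements the non-overlapping 5-frame
#' pre-averaging used before cell detection; with `stride = 1` it gives the
#' 25-50-frame running averages used for time-lapse display. Output frame
#' timestamps are the centres of their source windows, and the output count
#' is exactly `floor((n - window) / stride) + 1`.
#'
#' @param stack a [video_stack()] at stage `"registered"` (`"averaged"` input
#'   with `window = 1` passes through).
#' @param window frames per average, `1 <= window <= n`.
#' @param stride frames between consecutive windows (default `window`).
#' @return an averaged [video_stack()] with `average_window` recorded.
#' @export
temporal_average <- function(stack, window = 5L, stride = window) {
  stopifnot(inherits(stack, "video_stack"))
  n <- n_frames(stack)
  window <- as.integer(window); stride <- as.integer(stride)
  if (window < 1 || window > n) stop("window must lie in [1, n_frames]")
  if (stride < 1) stop("stride must be >= 1")
  if (window > 1 && stack$stage != "registered") {
    stop("temporal averaging expects a registered stack (got stage '",
         stack$stage, "')")
  }
  starts <- seq.int(1L, n - window + 1L, by = stride)
  frames <- vector("list", length(starts))
  ts <- numeric(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window - 1L)
    if (window == 1L) {
      frames[[i]] <- stack$frames[[idx]]
    } else {
      acc <- Reduce(`+`, lapply(stack$frames[idx], function(m) {
        m[is.na(m)] <- 0; m
      }))
      cnt <- Reduce(`+`, lapply(stack$frames[idx], function(m) {
        (!is.na(m)) * 1
      }))
      avg <- acc / cnt
      avg[cnt == 0] <- NA_real_
      frames[[i]] <- avg
    }
    ts[i] <- mean(stack$timestamps[idx])
  }
  video_stack(frames, um_per_px = stack$um_per_px,
              frame_interval_s = stride * stack$frame_interval_s,
              stage = if (window > 1) "averaged" else stack$stage,
              average_window = if (window > 1) window else
                stack$average_window,
              timestamps = ts)
}
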