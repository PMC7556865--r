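#' Calibrated video stack
#'
#' Container for a time-lapse image sequence with spatial calibration and a
#' processing-stage flag. Frames are 2-D numeric matrices (row = slow scan
#' axis, column = fast scan axis); intensities are arbitrary floating-point
#' units. Pixels lost to registration are `NA` and are excluded from temporal
#' averaging.
#'
#' The `stage` flag records provenance and may only move forward through
#' `raw -> desinusoided -> registered -> averaged`.
#'
#' @param frames list of numeric matrices, all the same dimension.
#' @param um_per_px spatial scale, micrometres per pixel (> 0).
#' @param frame_interval_s time between consecutive frames in seconds
#'   (default 1/25, the native 25 Hz frame rate).
#' @param stage processing stage, one of `"raw"`, `"desinusoided"`,
#'   `"registered"`, `"averaged"`.
#' @param average_window frame count used to form each frame if
#'   `stage == "averaged"`, otherwise `NA`.
#' @param timestamps optional per-frame times in seconds; defaults to
#'   `(0:(n-1)) * frame_interval_s`.
#' @return an object of class `video_stack`.
#' @export
video_stack <- function(frames, um_per_px, frame_interval_s = 1 / 25,
                        stage = "raw", average_window = NA_integer_,
                        timestamps = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all frames must have the same dimensions")
  }
  if (!is.numeric(um_per_px) || length(um_per_px) != 1 || um_per_px <= 0) {
    stop("um_per_px must be a positive scalar")
  }
  if (frame_interval_s <= 0) stop("frame_interval_s must be positive")
  stage <- match.arg(stage, c("raw", "desinusoided", "registered", "averaged"))
  if (is.null(timestamps)) {
    timestamps <- (seq_along(frames) - 1) * frame_interval_s
  }
  stopifnot(length(timestamps) == length(frames))
  structure(
    list(frames = frames, um_per_px = um_per_px,
         frame_interval_s = frame_interval_s, stage = stage,
         average_window = average_window, timestamps = timestamps),
    class = "video_stack"
  )
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "video_stack: %d frames of %d x %d px | %.4g um/px | %.3g s/frame | stage=%s%s\n",
    length(x$frames), d[1], d[2], x$um_per_px, x$frame_interval_s, x$stage,
    if (!is.na(x$average_window)) sprintf(" (window=%d)", x$average_window) else ""
  ))
  invisible(x)
}

#' @export
length.video_stack <- function(x) length(x$frames)

#' Number of frames in a stack
#' @param stack a [video_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) length(stack$frames)

stage_rank <- c(raw = 1L, desinusoided = 2L, registered = 3L, averaged = 4L)

advance_stage <- function(stack, new_stage) {
  if (stage_rank[[new_stage]] < stage_rank[[stack$stage]]) {
    stop(sprintf("stage may only advance forward (have '%s', requested '%s')",
                 stack$stage, new_stage))
  }
  stack$stage <- new_stage
  stack
}

#' Space-time (kymograph) image
#'
#' A line-scan image in the orientation used throughout the package: rows are
#' position along the scanned line (micrometres), columns are time (one column
#' per line period, `1/line_rate_hz` seconds). Blood cells moving along the
#' line appear as slanted streaks whose slope (rows per column) encodes
#' velocity.
#'
#' @param image numeric matrix, space (rows) by time (columns).
#' @param um_per_px micrometres per row.
#' @param line_rate_hz line-scan rate in Hz (default 15000, the resonant
#'   scanner line rate).
#' @param vessel_id optional identifier.
#' @return an object of class `kymograph`.
#' @export
kymograph <- function(image, um_per_px, line_rate_hz = 15000,
                      vessel_id = NA_character_) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (um_per_px <= 0) stop("um_per_px must be positive")
  if (line_rate_hz <= 0) stop("line_rate_hz must be positive")
  structure(
    list(image = image, um_per_px = um_per_px, line_rate_hz = line_rate_hz,
         vessel_id = vessel_id),
    class = "kymograph"
  )
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "kymograph: %d px (space) x %d lines (time) | %.4g um/px | %g Hz line rate\n",
    nrow(x$image), ncol(x$image), x$um_per_px, x$line_rate_hz))
  invisible(x)
}

#' Per-frame cell probability map
#'
#' @param values numeric matrix with values in `[0, 1]`.
#' @param frame_index 1-based index of the source frame.
#' @param um_per_px spatial scale of the source frame.
#' @return an object of class `probability_map`.
#' @export
probability_map <- function(values, frame_index = NA_integer_, um_per_px = 1) {
  stopifnot(is.matrix(values))
  if (any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE)) {
    stop("probability map values must lie in [0, 1]")
  }
  values <- pmin(pmax(values, 0), 1)
  structure(list(values = values, frame_index = frame_index,
                 um_per_px = um_per_px),
            class = "probability_map")
}
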