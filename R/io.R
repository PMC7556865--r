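#' Write a video stack as a multi-page 16-bit grayscale TIFF
#'
#' Intensities are affinely mapped onto the 16-bit range recorded in a JSON
#' sidecar (`<path>.json`) together with the calibration and provenance
#' fields, so [read_video()] restores the stack losslessly up to the 16-bit
#' quantisation (write-read-write round trips are bit-exact). `NA` sentinel
#' pixels are stored as intensity 0 with a sidecar flag.
#'
#' @param stack a [video_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_video <- function(stack, path) {
  stopifnot(inherits(stack, "video_stack"))
  rng <- range(unlist(lapply(stack$frames, range, na.rm = TRUE)))
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
  pages <- lapply(stack$frames, function(m) {
    q <- (m - rng[1]) / (rng[2] - rng[1])
    q[is.na(q)] <- 0
    round(q * 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(um_per_px = stack$um_per_px,
               frame_interval_s = stack$frame_interval_s,
               stage = stack$stage, average_window = stack$average_window,
               timestamps = stack$timestamps,
               intensity_min = rng[1], intensity_max = rng[2],
               na_as_zero = any(vapply(stack$frames, anyNA, logical(1))))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a video stack
#'
#' Calibration (at minimum `um_per_px` and `frame_interval_s`) comes from
#' the JSON sidecar written by [write_video()] or from the `calibration`
#' argument; without either the read fails naming the missing fields. RGB
#' input and pages of differing shape are format errors. 8- and 16-bit
#' pages are promoted to floating-point intensities (rescaled to the
#' sidecar intensity range when present).
#'
#' @param path TIFF path.
#' @param calibration optional list overriding/standing in for the sidecar
#'   (`um_per_px`, `frame_interval_s`, optional `stage`).
#' @return a [video_stack()].
#' @export
read_video <- function(path, calibration = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list()
  }
  if (!is.null(calibration)) meta[names(calibration)] <- calibration
  missing <- setdiff(c("um_per_px", "frame_interval_s"), names(meta))
  if (length(missing) > 0) {
    stop("missing calibration field(s): ", paste(missing, collapse = ", "),
         " (provide a sidecar JSON or the `calibration` argument)")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) == 3) {
      stop("RGB/multichannel TIFF not supported: expected grayscale")
    }
  }
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) all(dim(p) == d1), logical(1)))) {
    stop("TIFF pages have mismatched dimensions")
  }
  lo <- meta$intensity_min %||% 0
  hi <- meta$intensity_max %||% 1
  frames <- lapply(pages, function(p) p * (hi - lo) + lo)
  video_stack(frames, um_per_px = meta$um_per_px,
              frame_interval_s = meta$frame_interval_s,
              stage = meta$stage %||% "raw",
              average_window = meta$average_window %||% NA_integer_,
              timestamps = meta$timestamps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a kymograph as a single-page TIFF with JSON sidecar
#' @param kymo a [kymograph()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "kymograph"))
  rng <- range(kymo$image)
  if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
  q <- round((kymo$image - rng[1]) / (rng[2] - rng[1]) * 65535) / 65535
  tiff::writeTIFF(q, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(um_per_px = kymo$um_per_px, line_rate_hz = kymo$line_rate_hz,
         vessel_id = kymo$vessel_id, intensity_min = rng[1],
         intensity_max = rng[2]),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a kymograph TIFF written by [write_kymograph()]
#' @param path TIFF path.
#' @return a [kymograph()].
#' @export
read_kymograph <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  kymograph(img * (meta$intensity_max - meta$intensity_min) +
              meta$intensity_min,
            um_per_px = meta$um_per_px, line_rate_hz = meta$line_rate_hz,
            vessel_id = meta$vessel_id %||% NA_character_)
}

#' Write ground-truth cell positions as CSV
#'
#' Columns `frame,cell_id,row_um,col_um`; 0-based pixel origin, positions
#' in micrometres.
#'
#' @param truth data.frame from [simulate_cell_video()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth[, c("frame", "cell_id", "row_um", "col_um")],
                   path, row.names = FALSE)
  invisible(path)
}
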