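#' Link per-frame detections into tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames:
#' candidate pairs within `max_link_dist_um` are accepted in increasing
#' distance order (ties resolved toward the lower cell id), each detection
#' linked at most once per frame transition. Unmatched detections seed new
#' tracks. A track survives up to `max_gap_frames` consecutive frames
#' without a detection (default 0: any miss ends the track).
#'
#' The default link radius of 13 um (one nominal cell diameter) reflects
#' that immune cells move far less than a diameter per 0.2 s averaged-frame
#' interval.
#'
#' @param detections data.frame from [detect_stack()] (needs `frame`,
#'   `row_um`, `col_um`), sorted by frame.
#' @param max_link_dist_um maximum link distance in micrometres.
#' @param max_gap_frames tolerated missing frames within a track.
#' @param frame_times optional vector mapping frame index to seconds;
#'   defaults to `(frame - 1) * frame_interval_s`.
#' @param frame_interval_s seconds per frame (used when `frame_times` is
#'   `NULL`; default 0.2, the 5-frame average of a 25 Hz recording).
#' @return data.frame `cell_id, frame, time_s, row_um, col_um` with class
#'   `"cell_tracks"`; `qc_status` is added by [qc_tracks()].
#' @export
link_detections <- function(detections, max_link_dist_um = 13,
                            max_gap_frames = 0L, frame_times = NULL,
                            frame_interval_s = 0.2) {
  if (nrow(detections) == 0) {
    out <- data.frame(cell_id = integer(), frame = integer(),
                      time_s = numeric(), row_um = numeric(),
                      col_um = numeric())
    class(out) <- c("cell_tracks", "data.frame")
    return(out)
  }
  det <- detections[order(detections$frame), ]
  det$cell_id <- NA_integer_
  frames <- sort(unique(det$frame))
  next_id <- 0L
  # active track heads: cell_id, last frame, last position
  head_id <- integer(0); head_frame <- integer(0)
  head_r <- numeric(0); head_c <- numeric(0)
  for (f in frames) {
    cur <- which(det$frame == f)
    alive <- which(f - head_frame <= max_gap_frames + 1L & head_frame < f)
    assigned <- rep(NA_integer_, length(cur))
    if (length(alive) > 0 && length(cur) > 0) {
      d <- sqrt(outer(det$row_um[cur], head_r[alive], "-")^2 +
                  outer(det$col_um[cur], head_c[alive], "-")^2)
      cand <- which(d <= max_link_dist_um, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        # increasing distance, ties to the lower cell id: deterministic
        ord <- order(d[cand], head_id[alive][cand[, 2]])
        used_head <- logical(length(alive))
        for (i in ord) {
          ci <- cand[i, 1]; hi <- cand[i, 2]
          if (is.na(assigned[ci]) && !used_head[hi]) {
            assigned[ci] <- alive[hi]
            used_head[hi] <- TRUE
          }
        }
      }
    }
    for (i in seq_along(cur)) {
      if (is.na(assigned[i])) {
        next_id <- next_id + 1L
        det$cell_id[cur[i]] <- next_id
        head_id <- c(head_id, next_id)
        head_frame <- c(head_frame, f)
        head_r <- c(head_r, det$row_um[cur[i]])
        head_c <- c(head_c, det$col_um[cur[i]])
      } else {
        hi <- assigned[i]
        det$cell_id[cur[i]] <- head_id[hi]
        head_frame[hi] <- f
        head_r[hi] <- det$row_um[cur[i]]
        head_c[hi] <- det$col_um[cur[i]]
      }
    }
  }
  if (is.null(frame_times)) {
    det$time_s <- (det$frame - 1) * frame_interval_s
  } else {
    det$time_s <- frame_times[det$frame]
  }
  out <- det[order(det$cell_id, det$frame),
             c("cell_id", "frame", "time_s", "row_um", "col_um")]
  rownames(out) <- NULL
  class(out) <- c("cell_tracks", "data.frame")
  out
}

track_split <- function(tracks) split(as.data.frame(tracks), tracks$cell_id)

#' Flag tracks with implausible single-step jumps
#'
#' Automates the visual rejection of incorrect linkages (e.g. a trace that
#' jumps between two adjacent cells): a track is `"flagged"` when any single
#' step exceeds `jump_factor` times that track's own median step length, and
#' `"accepted"` otherwise. Flagged tracks are excluded from metric summaries
#' by default.
#'
#' @param tracks a `cell_tracks` data.frame from [link_detections()].
#' @param jump_factor multiple of the reference step that counts as a jump
#'   (> 1; default 5).
#' @param min_step_um floor on the reference step (default 1 um, about one
#'   pixel of centroid-localisation noise): for cells moving below that
#'   noise the median step is essentially zero and a ratio test alone would
#'   flag every slow cell, so the reference step is
#'   `max(median step, min_step_um)`. The default jump threshold (5 um) stays
#'   well below the adjacent-cell scale (13 um) the rule is meant to catch.
#' @param min_samples tracks shorter than this are flagged as untrackable
#'   (default 2, the minimum for any step).
#' @return the tracks with a `qc_status` column (`accepted`/`flagged`).
#' @export
qc_tracks <- function(tracks, jump_factor = 5, min_step_um = 1,
                      min_samples = 2L) {
  if (jump_factor <= 1) stop("jump_factor must be > 1")
  tracks$qc_status <- "accepted"
  for (tr in track_split(tracks)) {
    steps <- sqrt(diff(tr$row_um)^2 + diff(tr$col_um)^2)
    ref <- max(stats::median(steps), min_step_um)
    bad <- nrow(tr) < min_samples ||
      (length(steps) > 0 && any(steps > jump_factor * ref))
    if (bad) tracks$qc_status[tracks$cell_id == tr$cell_id[1]] <- "flagged"
  }
  tracks
}

window_endpoints <- function(tr, window_s) {
  t0 <- tr$time_s[1]
  span <- tr$time_s[nrow(tr)] - t0
  if (span + 1e-9 < window_s) return(NULL)
  i0 <- which.min(abs(tr$time_s - t0))
  i1 <- which.min(abs(tr$time_s - (t0 + window_s)))
  c(i0, i1)
}

#' Net displacement of one track over a time window
#'
#' Euclidean distance between the sample nearest the track start and the
#' sample nearest `window_s` later. The 100 s default window matches the
#' motility observation interval per recording.
#'
#' @param track samples of one cell (`time_s`, `row_um`, `col_um`),
#'   time-ordered.
#' @param window_s window length in seconds (default 100).
#' @param allow_shorter if `TRUE`, a track shorter than the window yields
#'   its full-span displacement with a warning instead of an error.
#' @return displacement in micrometres.
#' @export
displacement <- function(track, window_s = 100, allow_shorter = FALSE) {
  track <- as.data.frame(track)
  ep <- window_endpoints(track, window_s)
  if (is.null(ep)) {
    if (!allow_shorter) {
      stop("track spans less than the ", window_s,
           " s window; set allow_shorter = TRUE for full-span displacement")
    }
    warning("track shorter than window; returning full-span displacement")
    ep <- c(1L, nrow(track))
  }
  sqrt((track$row_um[ep[2]] - track$row_um[ep[1]])^2 +
         (track$col_um[ep[2]] - track$col_um[ep[1]])^2)
}

#' Total path length of one track over a time window
#'
#' Sum of consecutive-step Euclidean lengths between the same window
#' endpoints used by [displacement()].
#'
#' @inheritParams displacement
#' @return path length in micrometres.
#' @export
path_length <- function(track, window_s = 100, allow_shorter = FALSE) {
  track <- as.data.frame(track)
  ep <- window_endpoints(track, window_s)
  if (is.null(ep)) {
    if (!allow_shorter) {
      stop("track spans less than the ", window_s, " s window")
    }
    ep <- c(1L, nrow(track))
  }
  idx <- ep[1]:ep[2]
  sum(sqrt(diff(track$row_um[idx])^2 + diff(track$col_um[idx])^2))
}

#' Confinement ratio of one track
#'
#' Net displacement divided by total path length over the same window:
#' 1 for ballistic (straight, monotone) motion, tending to 0 for confined
#' wandering. For a zero path length the ratio is undefined and `NA` is
#' returned — deliberately not 0, which would mean "maximally confined".
#'
#' @inheritParams displacement
#' @return ratio in `[0, 1]`, or `NA_real_` for a zero path length (the
#'   ratio is undefined for a cell that never moved, not 0).
#' @export
confinement_ratio <- function(track, window_s = 100, allow_shorter = FALSE) {
  pl <- path_length(track, window_s, allow_shorter)
  if (pl <= 0) return(NA_real_)
  min(displacement(track, window_s, allow_shorter) / pl, 1)
}

#' Motility metrics for every accepted track
#'
#' @param tracks a `cell_tracks` data.frame, ideally after [qc_tracks()].
#' @param window_s metric window in seconds (default 100).
#' @param include_flagged include tracks flagged by QC (default FALSE).
#' @param allow_shorter pass through to the per-track metrics.
#' @return data.frame `cell_id, n_samples, displacement_um, path_length_um,
#'   confinement_ratio, window_s`.
#' @export
motility_metrics <- function(tracks, window_s = 100,
                             include_flagged = FALSE,
                             allow_shorter = FALSE) {
  if (!"qc_status" %in% names(tracks)) tracks$qc_status <- "accepted"
  keep <- if (include_flagged) track_split(tracks) else
    track_split(tracks[tracks$qc_status == "accepted", ])
  rows <- lapply(keep, function(tr) {
    if (nrow(tr) < 2) return(NULL)
    if (is.null(window_endpoints(tr, window_s)) && !allow_shorter) {
      return(NULL)
    }
    disp <- displacement(tr, window_s, allow_shorter = TRUE)
    pl <- path_length(tr, window_s, allow_shorter = TRUE)
    data.frame(cell_id = tr$cell_id[1], n_samples = nrow(tr),
               displacement_um = disp, path_length_um = pl,
               confinement_ratio = if (pl > 0) min(disp / pl, 1) else
                 NA_real_,
               window_s = window_s)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(), n_samples = integer(),
                      displacement_um = numeric(),
                      path_length_um = numeric(),
                      confinement_ratio = numeric(), window_s = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Origin-centred displacement traces
#'
#' Translates every track so its first sample sits at `(0, 0)`, the form
#' used for rose plots of displacement against the 13 um typical-cell-radius
#' reference circle.
#'
#' @param tracks a `cell_tracks` data.frame.
#' @param include_flagged include QC-flagged tracks (default FALSE).
#' @return data.frame `cell_id, time_s, drow_um, dcol_um`.
#' @export
normalize_traces <- function(tracks, include_flagged = FALSE) {
  if (!"qc_status" %in% names(tracks)) tracks$qc_status <- "accepted"
  use <- if (include_flagged) tracks else
    tracks[tracks$qc_status == "accepted", ]
  out <- lapply(track_split(use), function(tr) {
    data.frame(cell_id = tr$cell_id, time_s = tr$time_s,
               drow_um = tr$row_um - tr$row_um[1],
               dcol_um = tr$col_um - tr$col_um[1])
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(), time_s = numeric(),
                      drow_um = numeric(), dcol_um = numeric())
  }
  rownames(out) <- NULL
  out
}
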