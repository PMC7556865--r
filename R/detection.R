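#' Detector settings
#'
#' Both detector kinds satisfy the same contract — image in, probability map
#' in `[0, 1]` out — so the downstream tracking pipeline is agnostic to which
#' produced the detections.
#'
#' * `"learned"`: a trainable heat-map regressor — ridge regression from a
#'   small bank of zero-mean multi-scale convolutional features (matched
#'   filter, differences of Gaussians, gradient magnitude) onto Gaussian
#'   label maps, followed by a peak calibration so true cell centres map
#'   close to probability 1. Closed-form, CPU-trainable, deterministic.
#' * `"classical"`: a training-free matched filter at the nominal cell scale
#'   whose response is normalised by the response to an ideal rendered cell
#'   of the configured contrast.
#'
#' Zero-mean features/filters make both detectors invariant to an additive
#' intensity offset.
#'
#' @param kind `"learned"` or `"classical"`.
#' @param cell_diameter_um nominal cell diameter (default 13 um).
#' @param um_per_px spatial scale of the frames the detector will see.
#' @param cell_contrast expected cell amplitude, intensity units (classical
#'   calibration only).
#' @param sensitivity calibration margin in (0, 1]: a cell at `sensitivity`
#'   times the nominal response still reaches probability 1. Absorbs
#'   contrast variability so the 0.90 detection threshold keeps cells of
#'   slightly sub-nominal contrast.
#' @param lambda ridge penalty for the learned regressor.
#' @param seed integer seed recorded in the training metadata.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(kind = c("learned", "classical"),
                            cell_diameter_um = 13, um_per_px = 1.33,
                            cell_contrast = 40, sensitivity = 0.75,
                            lambda = 1e-3, seed = 1L) {
  kind <- match.arg(kind)
  if (sensitivity <= 0 || sensitivity > 1) {
    stop("sensitivity must lie in (0, 1]")
  }
  structure(list(kind = kind, cell_diameter_um = cell_diameter_um,
                 um_per_px = um_per_px, cell_contrast = cell_contrast,
                 sensitivity = sensitivity, lambda = lambda,
                 seed = as.integer(seed)),
            class = "detector_config")
}

radius_px_of <- function(config) {
  (config$cell_diameter_um / 2) / config$um_per_px
}

gauss_brush <- function(sigma, trunc = 3.5, max_side = Inf) {
  side <- 2L * ceiling(trunc * sigma) + 1L
  if (side > max_side) side <- 2L * ((max_side - 1L) %/% 2L) + 1L
  k <- EBImage::makeBrush(side, shape = "gaussian", sigma = sigma)
  k / sum(k)
}

# Pad the smaller kernel so two brushes can be subtracted.
pad_to <- function(k, side) {
  if (nrow(k) == side) return(k)
  out <- matrix(0, side, side)
  off <- (side - nrow(k)) %/% 2
  out[(off + 1):(off + nrow(k)), (off + 1):(off + nrow(k))] <- k
  out
}

dog_kernel <- function(sigma_in, sigma_out, trunc = 3.5,
                       max_side = Inf) {
  a <- gauss_brush(sigma_in, trunc, max_side)
  b <- gauss_brush(sigma_out, trunc, max_side)
  side <- max(nrow(a), nrow(b))
  pad_to(a, side) - pad_to(b, side)   # zero-sum: offset invariant
}

# Zero-mean matched filter for the phase-contrast cell profile, scaled so
# the peak response to an ideal unit-amplitude cell equals 1.
matched_kernel <- function(radius_px) {
  ext <- ceiling(3 * radius_px)
  d <- sqrt(outer((-ext:ext)^2, (-ext:ext)^2, "+"))
  k <- cell_profile(d, radius_px, amplitude = 1)
  k <- k - mean(k)
  peak <- ideal_cell_response(k, radius_px)
  k / peak
}

# Response of filter k at the centre of an ideal unit-amplitude cell.
ideal_cell_response <- function(k, radius_px) {
  ext <- ceiling(3 * radius_px) + (nrow(k) %/% 2) + 2L
  side <- 2L * ext + 1L
  img <- stamp_cell(matrix(0, side, side), ext + 1, ext + 1, radius_px, 1)
  EBImage::filter2(img, k)[ext + 1, ext + 1]
}

# Classical detector response: matched filter followed by centre-surround
# background subtraction (removes smooth texture leakage), normalised so an
# ideal unit-amplitude cell peaks at 1.
classical_response <- function(frame, radius_px) {
  raw_op <- function(img) {
    m <- EBImage::filter2(img, matched_kernel(radius_px))
    m - EBImage::filter2(m, gauss_brush(2.5 * radius_px))
  }
  ext <- ceiling(3 * radius_px) * 4L + 8L
  side <- 2L * ext + 1L
  ideal <- stamp_cell(matrix(0, side, side), ext + 1, ext + 1, radius_px, 1)
  peak <- raw_op(ideal)[ext + 1, ext + 1]
  raw_op(frame) / peak
}

# Multi-scale zero-mean feature maps for the learned detector. The last
# channel spans the background-texture band (about 1.5-4 cell radii) so the
# regression can subtract the local texture estimate under each cell.
detector_features <- function(frame, radius_px) {
  mk <- matched_kernel(radius_px)
  m <- EBImage::filter2(frame, mk)
  d1k <- dog_kernel(radius_px / 3, radius_px)
  d1 <- EBImage::filter2(frame, d1k)
  gx <- EBImage::filter2(frame, matrix(c(-0.5, 0, 0.5), 1, 3))
  gy <- EBImage::filter2(frame, matrix(c(-0.5, 0, 0.5), 3, 1))
  g <- EBImage::filter2(sqrt(gx^2 + gy^2), gauss_brush(radius_px / 2))
  max_side <- min(dim(frame))
  tex <- EBImage::filter2(frame, dog_kernel(1.5 * radius_px, 4 * radius_px,
                                            trunc = 2, max_side = max_side))
  list(m = m, mpos2 = pmax(m, 0)^2, d1 = d1, g = g, tex = tex)
}

#' Build a Gaussian heat-map training target from centroids
#'
#' Stamps a unit-peak Gaussian kernel (`sigma = radius_px / 2`) at every
#' centroid; overlapping kernels are summed and the map clipped to `[0, 1]`.
#' This is the regression target the trainable detector learns to predict.
#'
#' @param centroids numeric n x 2 matrix of `(row, col)` centres in 0-based
#'   pixel coordinates (fractional allowed); `NULL` or 0-row for none.
#' @param shape integer `(rows, cols)`.
#' @param radius_px nominal cell radius in pixels.
#' @return numeric matrix in `[0, 1]` of dimension `shape`.
#' @export
make_label_map <- function(centroids, shape, radius_px) {
  out <- matrix(0, shape[1], shape[2])
  if (is.null(centroids) || nrow(centroids) == 0) return(out)
  centroids <- as.matrix(centroids)
  if (any(centroids[, 1] < 0 | centroids[, 1] > shape[1] - 1 |
            centroids[, 2] < 0 | centroids[, 2] > shape[2] - 1)) {
    stop("centroid outside frame bounds")
  }
  sig <- radius_px / 2
  ext <- ceiling(3.5 * sig)
  for (i in seq_len(nrow(centroids))) {
    r <- centroids[i, 1] + 1; c <- centroids[i, 2] + 1
    r0 <- max(1L, floor(r) - ext); r1 <- min(shape[1], ceiling(r) + ext)
    c0 <- max(1L, floor(c) - ext); c1 <- min(shape[2], ceiling(c) + ext)
    d2 <- outer((r0:r1 - r)^2, (c0:c1 - c)^2, "+")
    out[r0:r1, c0:c1] <- out[r0:r1, c0:c1] + exp(-d2 / (2 * sig^2))
  }
  pmin(out, 1)
}

#' Train (or instantiate) a cell detector
#'
#' For `kind = "learned"`, fits ridge-regression weights from the multi-scale
#' feature bank of every training frame onto its label map (closed form, no
#' stochastic optimisation, so identical data give identical models), then
#' calibrates an output scale so the lower quartile of predicted values at
#' label peaks maps to probability 1. For `kind = "classical"` no data are
#' needed beyond shape checks; the matched-filter model is built from the
#' config alone.
#'
#' @param frames list of numeric matrices (may be empty for classical).
#' @param targets list of label maps matching `frames` (see
#'   [make_label_map()]).
#' @param config a [detector_config()].
#' @return an object of class `detector_model` with elements `kind`,
#'   `radius_px`, `weights`/`intercept`/`scale` (learned), `sensitivity`,
#'   `training` metadata (n frames, training MAE, seed).
#' @export
train_detector <- function(frames, targets = NULL, config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  radius_px <- radius_px_of(config)
  if (config$kind == "classical") {
    mdl <- structure(
      list(kind = "classical", radius_px = radius_px,
           contrast = config$cell_contrast, sensitivity = config$sensitivity,
           training = list(n_frames = 0L, mae = NA_real_,
                           seed = config$seed)),
      class = "detector_model")
    return(mdl)
  }
  if (length(frames) == 0) stop("learned detector needs >= 1 training frame")
  if (is.null(targets) || length(targets) != length(frames)) {
    stop("targets must match frames one to one")
  }
  for (i in seq_along(frames)) {
    if (!all(dim(frames[[i]]) == dim(targets[[i]]))) {
      stop("frame/target shape mismatch at index ", i)
    }
  }
  feats <- lapply(frames, detector_features, radius_px = radius_px)
  X <- do.call(rbind, lapply(feats, function(f) {
    cbind(1, as.vector(f$m), as.vector(f$mpos2), as.vector(f$d1),
          as.vector(f$g), as.vector(f$tex))
  }))
  y <- unlist(lapply(targets, as.vector))
  XtX <- crossprod(X)
  pen <- diag(c(0, rep(config$lambda, ncol(X) - 1)))
  beta <- solve(XtX + pen, crossprod(X, y))
  pred <- as.vector(X %*% beta)
  # calibration: lower quartile of predictions at label peaks -> 1
  peak_px <- y >= 0.99
  scale <- if (any(peak_px)) {
    1 / max(stats::quantile(pred[peak_px], 0.25), 1e-6)
  } else 1
  structure(
    list(kind = "learned", radius_px = radius_px,
         intercept = beta[1], weights = beta[-1],
         scale = scale / config$sensitivity,
         sensitivity = config$sensitivity,
         training = list(n_frames = length(frames),
                         mae = mean(abs(pred - y)), seed = config$seed)),
    class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf("detector_model: kind=%s, radius=%.2f px", x$kind, x$radius_px))
  if (x$kind == "learned") {
    cat(sprintf(", trained on %d frames (MAE %.4f)",
                x$training$n_frames, x$training$mae))
  }
  cat("\n")
  invisible(x)
}

#' Predict a cell probability map for one frame
#'
#' @param model a [train_detector()] model.
#' @param frame numeric matrix.
#' @param frame_index optional index recorded in the output.
#' @param um_per_px optional scale recorded in the output.
#' @return a [probability_map()].
#' @export
predict_probability_map <- function(model, frame, frame_index = NA_integer_,
                                    um_per_px = 1) {
  stopifnot(inherits(model, "detector_model"), is.matrix(frame))
  frame <- fill_na(frame)
  if (model$kind == "classical") {
    lin <- classical_response(frame, model$radius_px) /
      (model$contrast * model$sensitivity)
  } else {
    f <- detector_features(frame, model$radius_px)
    lin <- (model$intercept +
              model$weights[1] * f$m + model$weights[2] * f$mpos2 +
              model$weights[3] * f$d1 + model$weights[4] * f$g +
              model$weights[5] * f$tex) *
      model$scale
  }
  pm <- probability_map(pmin(pmax(lin, 0), 1), frame_index = frame_index,
                        um_per_px = um_per_px)
  # the unclipped response keeps sub-pixel peak shape that the saturated
  # probability plateau loses; detect_centroids uses it for refinement
  attr(pm, "response") <- lin
  pm
}

# Sub-pixel peak refinement: least-squares 2-D quadratic over a (2h+1)^2
# neighbourhood of the integer peak of the response surface. Returns the
# refined (row, col) or the input when the fit is not concave.
quadratic_peak_2d <- function(resp, r, c, h = 2L) {
  R <- nrow(resp); C <- ncol(resp)
  if (r - h < 1 || r + h > R || c - h < 1 || c + h > C) return(c(r, c))
  xs <- rep(-h:h, times = 2 * h + 1)
  ys <- rep(-h:h, each = 2 * h + 1)
  z <- as.vector(resp[(r - h):(r + h), (c - h):(c + h)])
  X <- cbind(1, xs, ys, xs^2, ys^2, xs * ys)
  beta <- stats::lm.fit(X, z)$coefficients
  H <- matrix(c(2 * beta[4], beta[6], beta[6], 2 * beta[5]), 2, 2)
  if (!all(is.finite(H)) || det(H) <= 0 || H[1, 1] >= 0) return(c(r, c))
  off <- -solve(H, beta[2:3])
  if (any(abs(off) > h)) return(c(r, c))
  c(r + off[1], c + off[2])
}

# 8-connected labelling of a sparse binary mask (EBImage::bwlabel is
# 4-connected). Returns an integer matrix of component labels.
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  R <- nrow(mask); C <- ncol(mask)
  idx <- which(mask)
  nxt <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% R) + 1L
      c <- ((p - 1L) %/% R) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > R || cc < 1 || cc > C) next
        q <- (cc - 1L) * R + rr
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Extract cell detections from a probability map
#'
#' Binarises the map at `threshold` (values >= threshold are kept), labels
#' 8-connected components, drops components smaller than `min_area_px`, and
#' reports each remaining component at its intensity-weighted centroid.
#'
#' @param map a [probability_map()] (or a plain numeric matrix in `[0, 1]`).
#' @param threshold detection threshold in (0, 1); default 0.90, the
#'   operating point used for cell counting.
#' @param min_area_px minimum component area; default 3 px rejects
#'   single/double-pixel noise while keeping the compact suprathreshold
#'   core of a unit-peak Gaussian response.
#' @return data.frame `frame, row_px, col_px, row_um, col_um, area_px,
#'   peak_prob` (0-based fractional pixel coordinates; um via the map scale).
#' @export
detect_centroids <- function(map, threshold = 0.90, min_area_px = 3L) {
  if (is.matrix(map)) map <- probability_map(map)
  stopifnot(inherits(map, "probability_map"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  v <- map$values
  resp <- attr(map, "response")
  lab <- label_components8(v >= threshold)
  empty <- data.frame(frame = integer(), row_px = numeric(),
                      col_px = numeric(), row_um = numeric(),
                      col_um = numeric(), area_px = integer(),
                      peak_prob = numeric())
  if (max(lab) == 0L) return(empty)
  out <- lapply(seq_len(max(lab)), function(l) {
    px <- which(lab == l)
    if (length(px) < min_area_px) return(NULL)
    r <- ((px - 1L) %% nrow(v)) + 1L
    c <- ((px - 1L) %/% nrow(v)) + 1L
    w <- v[px]
    ctr <- c(sum(w * r) / sum(w), sum(w * c) / sum(w))
    if (!is.null(resp)) {
      pk <- px[which.max(resp[px])]
      ctr <- quadratic_peak_2d(resp, ((pk - 1L) %% nrow(v)) + 1L,
                               ((pk - 1L) %/% nrow(v)) + 1L)
    }
    data.frame(frame = map$frame_index,
               row_px = ctr[1] - 1, col_px = ctr[2] - 1,
               area_px = length(px), peak_prob = max(w))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  out$row_um <- out$row_px * map$um_per_px
  out$col_um <- out$col_px * map$um_per_px
  out[, c("frame", "row_px", "col_px", "row_um", "col_um", "area_px",
          "peak_prob")]
}

#' Refine a detection by fitting the cell appearance model
#'
#' Model-based sub-pixel localisation in image space: within a disk of
#' about one cell radius the smooth background texture is close to planar,
#' so the intensity is fit as `a + b*dx + c*dy + A*profile(|x - p|)` — a
#' local plane plus the radial phase-contrast cell profile — and the centre
#' `p` is optimised (Nelder-Mead over `p`, closed-form linear coefficients
#' at each step). This removes most of the centroid bias that a static
#' background gradient induces on weighted-centroid or response-peak
#' estimates.
#'
#' @param frame numeric matrix (the image the detection came from).
#' @param row_px,col_px starting centre, 0-based pixels.
#' @param radius_px nominal cell radius in pixels.
#' @return length-2 refined `(row_px, col_px)`, 0-based.
#' @export
refine_centroid_profile <- function(frame, row_px, col_px, radius_px) {
  r0 <- row_px + 1; c0 <- col_px + 1
  ext <- ceiling(1.3 * radius_px)
  rr <- max(1, round(r0) - ext):min(nrow(frame), round(r0) + ext)
  cc <- max(1, round(c0) - ext):min(ncol(frame), round(c0) + ext)
  if (length(rr) < 5 || length(cc) < 5) return(c(row_px, col_px))
  z <- as.vector(frame[rr, cc])
  if (anyNA(z)) {
    keep <- !is.na(z)
    if (sum(keep) < 20) return(c(row_px, col_px))
  } else {
    keep <- rep(TRUE, length(z))
  }
  gr <- rep(rr, times = length(cc))
  gc <- rep(cc, each = length(rr))
  rss <- function(p) {
    d <- sqrt((gr - p[1])^2 + (gc - p[2])^2)
    X <- cbind(1, gr - p[1], gc - p[2], cell_profile(d, radius_px, 1))
    fit <- stats::lm.fit(X[keep, , drop = FALSE], z[keep])
    sum(fit$residuals^2)
  }
  opt <- stats::optim(c(r0, c0), rss, method = "Nelder-Mead",
                      control = list(maxit = 80, reltol = 1e-8))
  if (max(abs(opt$par - c(r0, c0))) > radius_px) return(c(row_px, col_px))
  opt$par - 1
}

#' Run a detector over every frame of a stack
#'
#' @param model a [train_detector()] model.
#' @param stack a [video_stack()] (typically averaged).
#' @param threshold,min_area_px passed to [detect_centroids()].
#' @param refine `"profile"` re-localises every detection by the local
#'   plane + cell-profile fit ([refine_centroid_profile()]); `"none"` keeps
#'   the response-peak centroids.
#' @return data.frame of detections across frames (see [detect_centroids()]).
#' @export
detect_stack <- function(model, stack, threshold = 0.90, min_area_px = 3L,
                         refine = c("profile", "none")) {
  stopifnot(inherits(stack, "video_stack"))
  refine <- match.arg(refine)
  do.call(rbind, lapply(seq_len(n_frames(stack)), function(f) {
    pm <- predict_probability_map(model, stack$frames[[f]], frame_index = f,
                                  um_per_px = stack$um_per_px)
    det <- detect_centroids(pm, threshold = threshold,
                            min_area_px = min_area_px)
    if (refine == "profile" && nrow(det) > 0) {
      for (i in seq_len(nrow(det))) {
        p <- refine_centroid_profile(stack$frames[[f]], det$row_px[i],
                                     det$col_px[i], model$radius_px)
        det$row_px[i] <- p[1]; det$col_px[i] <- p[2]
      }
      det$row_um <- det$row_px * stack$um_per_px
      det$col_um <- det$col_px * stack$um_per_px
    }
    det
  }))
}

#' Cell count by the first-25-frame averaging rule
#'
#' The cell count of a video is the arithmetic mean of the per-frame
#' detection counts over the first `n_frames_for_count` (averaged) frames;
#' at the default 5-frame averaging of a 25 Hz recording, 25 averaged frames
#' span 5 s.
#'
#' @param detections data.frame with a `frame` column (frames with no
#'   detections simply contribute zero).
#' @param n_frames_available total frames in the analysed stack; defaults to
#'   the largest frame index seen.
#' @param n_frames_for_count frames entering the mean (default 25).
#' @param allow_fewer if `TRUE`, fewer available frames give the mean over
#'   what is available (with a warning) instead of an error.
#' @return scalar mean count (real-valued).
#' @export
count_cells <- function(detections,
                        n_frames_available = suppressWarnings(
                          max(detections$frame, 0)),
                        n_frames_for_count = 25L, allow_fewer = FALSE) {
  if (n_frames_available < n_frames_for_count) {
    if (!allow_fewer) {
      stop(sprintf(paste0(
        "only %d frames available but %d required for the counting rule; ",
        "set allow_fewer = TRUE to average over the available frames"),
        n_frames_available, n_frames_for_count))
    }
    warning("counting over ", n_frames_available, " frames instead of ",
            n_frames_for_count)
    n_frames_for_count <- n_frames_available
  }
  counts <- tabulate(detections$frame[detections$frame <= n_frames_for_count],
                     nbins = n_frames_for_count)
  mean(counts)
}

#' Cell density in cells per square millimetre
#'
#' @param count cell count (real-valued).
#' @param field_um length-2 `(height, width)` of the field in micrometres.
#' @return cells/mm^2.
#' @export
cell_density <- function(count, field_um) {
  if (any(field_um <= 0)) stop("field dimensions must be positive")
  count / (field_um[1] * field_um[2] * 1e-6)
}

#' Match detections to ground-truth positions and score F1
#'
#' Greedy nearest-first matching: candidate pairs within `radius_px` are
#' accepted in increasing distance order, each detection and each truth
#' position used at most once.
#'
#' @param detections data.frame with `row_px, col_px` (0-based).
#' @param truth_px numeric n x 2 matrix of true `(row, col)` centres
#'   (0-based px).
#' @param radius_px match radius (default 5 px).
#' @return list `tp, fp, fn, precision, recall, f1`.
#' @export
match_detections <- function(detections, truth_px, radius_px = 5) {
  nd <- nrow(detections); nt <- nrow(truth_px)
  if (nd == 0 || nt == 0) {
    tp <- 0L
  } else {
    d2 <- outer(detections$row_px, truth_px[, 1], "-")^2 +
      outer(detections$col_px, truth_px[, 2], "-")^2
    pairs <- which(d2 <= radius_px^2, arr.ind = TRUE)
    ord <- order(d2[pairs])
    used_d <- logical(nd); used_t <- logical(nt); tp <- 0L
    for (i in ord) {
      di <- pairs[i, 1]; ti <- pairs[i, 2]
      if (!used_d[di] && !used_t[ti]) {
        used_d[di] <- TRUE; used_t[ti] <- TRUE; tp <- tp + 1L
      }
    }
  }
  fp <- nd - tp; fn <- nt - tp
  precision <- if (nd > 0) tp / nd else 0
  recall <- if (nt > 0) tp / nt else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}
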