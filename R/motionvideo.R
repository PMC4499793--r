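#' 8-bit grayscale frame stack
#'
#' @param frames Integer array H x W x n, values in \[0, 255\].
#' @param fps Frame rate, Hz.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, fps) {
  stopifnot(length(dim(frames)) == 3)
  if (min(frames) < 0 || max(frames) > 255)
    stopf("pixel values must lie in [0, 255]")
  structure(list(frames = frames, fps = fps), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d at %g fps (%.1f s)\n",
              d[3], d[1], d[2], x$fps, d[3] / x$fps))
  invisible(x)
}

#' Background, difference image and motion map of a video
#'
#' Runs the recursive motion-energy pipeline: a running background
#' `BG_i = alpha * Frame_i + (1 - alpha) * BG_{i-1}` (initialised at the
#' first frame), the absolute difference image `|Frame_i - BG_i|`, and a
#' time-smoothed difference image, the motion map,
#' `map_i = beta * diffim_i + (1 - beta) * map_{i-1}`.  With alpha = 0.3 the
#' background is a weighted average over roughly the last 15 frames (the
#' weight of the frame k steps back is `alpha (1-alpha)^k`; see
#' [background_window_frames()]).
#'
#' @param stack A [frame_stack()] with at least 2 frames.
#' @param alpha Background update weight.
#' @param beta Motion-map smoothing weight.
#' @return An object of class `motion_map` holding the motion map and
#'   difference-image arrays (same shape as the frames), the final
#'   background, and the parameters.
#' @export
compute_motion_map <- function(stack, alpha = 0.3, beta = 0.9) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  if (d[3] < 2) stopf("need at least 2 frames")
  map <- array(0, dim = d)
  diffim <- array(0, dim = d)
  bg <- stack$frames[, , 1]
  prev_map <- abs(stack$frames[, , 1] - bg)  # zero
  map[, , 1] <- prev_map
  for (i in 2:d[3]) {
    fr <- stack$frames[, , i]
    bg <- alpha * fr + (1 - alpha) * bg
    di <- abs(fr - bg)
    diffim[, , i] <- di
    prev_map <- beta * di + (1 - beta) * prev_map
    map[, , i] <- prev_map
  }
  structure(list(map = map, diffim = diffim, bg = bg, alpha = alpha,
                 beta = beta, fps = stack$fps),
            class = "motion_map")
}

#' @export
print.motion_map <- function(x, ...) {
  d <- dim(x$map)
  cat(sprintf("<motion_map> %d frames %dx%d, alpha %.2f beta %.2f\n",
              d[3], d[1], d[2], x$alpha, x$beta))
  invisible(x)
}

#' Smallest background window covering a given recency weight
#'
#' For the recursive background with update weight `alpha`, the cumulative
#' weight of the last n frames is `1 - (1 - alpha)^n`; this returns the
#' smallest n reaching `coverage`.
#'
#' @param alpha Background update weight.
#' @param coverage Cumulative weight to reach.
#' @return Integer number of frames.
#' @export
background_window_frames <- function(alpha = 0.3, coverage = 0.995) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  as.integer(ceiling(log(1 - coverage) / log(1 - alpha)))
}

#' Motion index from a motion map
#'
#' Per frame, the number of map pixels exceeding the threshold (40 at 8-bit
#' resolution), normalised to the maximum over the video; an all-zero
#' series is left at zero.
#'
#' @param mm A [compute_motion_map()] result.
#' @param threshold Pixel threshold in 8-bit units.
#' @return An object of class `motion_index_series` (`values` in \[0, 1\],
#'   `fps`, `max_count`).
#' @export
motion_index <- function(mm, threshold = 40) {
  stopifnot(inherits(mm, "motion_map"))
  cnt <- apply(mm$map > threshold, 3, sum)
  mx <- max(cnt)
  structure(list(values = if (mx > 0) cnt / mx else cnt + 0,
                 fps = mm$fps, threshold = threshold, max_count = mx),
            class = "motion_index_series")
}

#' @export
print.motion_index_series <- function(x, ...) {
  cat(sprintf("<motion_index_series> %d frames, max count %d, mean %.3f\n",
              length(x$values), x$max_count, mean(x$values)))
  invisible(x)
}

#' Classify frames into quiet and movement epochs
#'
#' Quiet: runs of at least `min_frames` frames in which the motion index
#' changes by less than `rate_thr` per frame; movement: runs with
#' frame-to-frame change above the threshold; everything else (short runs)
#' is left unlabeled.  The first `warmup` frames are excluded to avoid the
#' background-initialisation transient.
#'
#' @param mi A [motion_index()] series.
#' @param rate_thr Rate-of-change threshold, a.u. per frame.
#' @param min_frames Minimum run length.
#' @param warmup Frames excluded at the start.
#' @return An object of class `epoch_labels`: per-frame `label`
#'   (`"quiet"`, `"movement"`, `"unlabeled"`) and a run-length `segments`
#'   data frame.
#' @export
classify_epochs <- function(mi, rate_thr = 0.025, min_frames = 30,
                            warmup = 15) {
  stopifnot(inherits(mi, "motion_index_series"))
  v <- mi$values
  n <- length(v)
  if (n < min_frames) stopf("series shorter than min_frames")
  rate <- c(0, abs(diff(v)))  # change attributed to the later frame
  fast <- rate > rate_thr
  label <- rep("unlabeled", n)
  r <- rle(fast[(warmup + 1):n])
  ends <- warmup + cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$lengths)) {
    if (r$lengths[j] < min_frames) next
    label[starts[j]:ends[j]] <- if (r$values[j]) "movement" else "quiet"
  }
  rl <- rle(label)
  e2 <- cumsum(rl$lengths)
  segments <- data.frame(start_frame = e2 - rl$lengths + 1L, end_frame = e2,
                         label = rl$values)
  structure(list(label = label, segments = segments, rate = rate,
                 rate_thr = rate_thr, min_frames = min_frames,
                 warmup = warmup, fps = mi$fps),
            class = "epoch_labels")
}

#' @export
print.epoch_labels <- function(x, ...) {
  tb <- table(x$label)
  cat("<epoch_labels> ",
      paste(sprintf("%s: %d", names(tb), tb), collapse = ", "), "\n")
  invisible(x)
}

#' Activity-triggered average of the motion map
#'
#' Weights every frame of the motion map by the neural event rate in the
#' matching frame-duration bin and averages:
#' `sum(rate_i * map_i) / sum(rate_i)`.
#'
#' @param mm A [compute_motion_map()] result.
#' @param rate A [rate_series_obj()] binned at the frame duration, or a
#'   numeric vector of per-frame rates.
#' @return Matrix, the weighted-average map.
#' @export
activity_triggered_map <- function(mm, rate) {
  stopifnot(inherits(mm, "motion_map"))
  w <- if (inherits(rate, "rate_series")) rate$values else as.numeric(rate)
  nfr <- dim(mm$map)[3]
  m <- min(nfr, length(w))
  w <- w[seq_len(m)]
  if (sum(w) == 0) stopf("all-zero rate series")
  out <- matrix(0, dim(mm$map)[1], dim(mm$map)[2])
  for (i in seq_len(m)) out <- out + w[i] * mm$map[, , i]
  out / sum(w)
}

#' Spatiotemporal principal components of the motion map
#'
#' Downsamples the map spatially, slides an 8-frame window across it
#' (stride 1), and extracts the principal components of the resulting
#' windows-by-pixels matrix.  Components are orthonormal; per-window
#' coefficients (scores) are returned for cross-correlation with neural
#' activity.
#'
#' @param mm A [compute_motion_map()] result.
#' @param window Frames per window.
#' @param keep Number of leading components to keep (reduced with a warning
#'   if the data support fewer).
#' @param downsample Spatial downsampling factor.
#' @return An object of class `motion_pcs`: `components` (array
#'   h x w x window x keep), `eigenvalues`, `coefficients` (windows x keep),
#'   and geometry fields.
#' @export
motion_pca <- function(mm, window = 8, keep = 50, downsample = 2) {
  stopifnot(inherits(mm, "motion_map"))
  d <- dim(mm$map)
  if (d[3] < window) stopf("need at least %d frames", window)
  h <- floor(d[1] / downsample); w <- floor(d[2] / downsample)
  small <- array(0, dim = c(h, w, d[3]))
  for (i in seq_len(d[3])) {
    blk <- mm$map[seq_len(h * downsample), seq_len(w * downsample), i]
    small[, , i] <- blk[seq(1, h * downsample, by = downsample),
                        seq(1, w * downsample, by = downsample)]
  }
  nw <- d[3] - window + 1L
  M <- matrix(0, nw, h * w * window)
  for (i in seq_len(nw))
    M[i, ] <- as.numeric(small[, , i:(i + window - 1L)])
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  avail <- ncol(pc$rotation)
  if (keep > avail) {
    warnf("only %d components available, keeping all", avail)
    keep <- avail
  }
  comps <- array(pc$rotation[, seq_len(keep)], dim = c(h, w, window, keep))
  structure(list(components = comps,
                 eigenvalues = pc$sdev[seq_len(keep)]^2,
                 all_eigenvalues = pc$sdev^2,
                 coefficients = pc$x[, seq_len(keep), drop = FALSE],
                 window = window, downsample = downsample, h = h, w = w,
                 fps = mm$fps),
            class = "motion_pcs")
}

#' @export
print.motion_pcs <- function(x, ...) {
  cat(sprintf("<motion_pcs> %d components of %dx%dx%d, leading eigenvalue %.3g\n",
              length(x$eigenvalues), x$h, x$w, x$window, x$eigenvalues[1]))
  invisible(x)
}

#' Framewise pixel change of one component within a region of interest
#'
#' `Delta = sum over ROI pixels of sum_i |PC[x,y,i] - PC[x,y,i-1]|`.
#'
#' @param pc_frames Array h x w x window (one spatiotemporal component).
#' @param roi Two-column matrix of (row, col) pixel coordinates.
#' @return The Delta statistic.
#' @export
roi_delta <- function(pc_frames, roi) {
  if (!nrow(roi)) stopf("empty ROI")
  d <- dim(pc_frames)
  if (max(roi[, 1]) > d[1] || max(roi[, 2]) > d[2] || min(roi) < 1)
    stopf("ROI outside frame bounds")
  tot <- 0
  for (i in 2:d[3]) {
    df <- abs(pc_frames[, , i] - pc_frames[, , i - 1])
    tot <- tot + sum(df[roi])
  }
  tot
}

#' Label motion components by participating body region
#'
#' A region (ROI) participates in a component's motion if its framewise
#' pixel change Delta exceeds the threshold.  Background ROIs, when given,
#' provide the null Delta distribution used to sanity-check the threshold.
#' Note that Delta scales with the component normalisation, so the
#' threshold is meaningful only for a fixed PC scaling.
#'
#' @param pcs A [motion_pca()] result, or an array h x w x window x k.
#' @param rois Named list of ROIs (two-column (row, col) index matrices).
#' @param threshold Delta threshold.
#' @param background_rois Optional list of background ROIs.
#' @return List: `delta` (components x ROIs matrix), `labels` (logical
#'   matrix Delta > threshold), `background_delta`.
#' @export
label_components <- function(pcs, rois, threshold = 3000,
                             background_rois = NULL) {
  comps <- if (inherits(pcs, "motion_pcs")) pcs$components else pcs
  k <- dim(comps)[4]
  delta <- matrix(0, k, length(rois),
                  dimnames = list(NULL, names(rois)))
  for (ci in seq_len(k))
    for (ri in seq_along(rois))
      delta[ci, ri] <- roi_delta(comps[, , , ci, drop = TRUE], rois[[ri]])
  bg <- NULL
  if (!is.null(background_rois)) {
    bg <- matrix(0, k, length(background_rois))
    for (ci in seq_len(k))
      for (ri in seq_along(background_rois))
        bg[ci, ri] <- roi_delta(comps[, , , ci, drop = TRUE],
                                background_rois[[ri]])
  }
  list(delta = delta, labels = delta > threshold, background_delta = bg,
       threshold = threshold)
}
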