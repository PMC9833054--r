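#' Keypoint time series from markerless pose estimation
#'
#' Container for trial-aligned pose tracks of the five tracked points
#' (`left_paw`, `right_paw`, `mouth`, `platform`, `spout`), each with pixel
#' coordinates and a per-frame tracking confidence. Image convention: y
#' increases downward, so a lifted paw has a *smaller* y than the platform.
#'
#' @param keypoints named list; each element a list with numeric vectors
#'   `x`, `y`, `confidence` of equal length.
#' @param rate sampling rate in Hz (behavioral camera, default 60).
#' @return A `pose_tracks` object: list with `t` (seconds from camera start),
#'   `rate` and `keypoints`.
#' @export
pose_tracks <- function(keypoints, rate = 60) {
  stopifnot(is.list(keypoints), length(keypoints) >= 1, !is.null(names(keypoints)))
  lens <- unique(unlist(lapply(keypoints, function(kp) {
    stopifnot(all(c("x", "y", "confidence") %in% names(kp)))
    c(length(kp$x), length(kp$y), length(kp$confidence))
  })))
  if (length(lens) != 1L) stop("all keypoint series must have equal length")
  for (nm in names(keypoints)) {
    conf <- keypoints[[nm]]$confidence
    if (any(conf < 0 | conf > 1, na.rm = TRUE)) {
      stop("confidence must lie in [0, 1] (keypoint ", nm, ")")
    }
  }
  structure(
    list(t = (seq_len(lens) - 1) / rate, rate = rate, keypoints = keypoints),
    class = "pose_tracks"
  )
}

#' @export
print.pose_tracks <- function(x, ...) {
  cat(sprintf("<pose_tracks> %d frames @ %g Hz (%.2f s), keypoints: %s\n",
              length(x$t), x$rate, length(x$t) / x$rate,
              paste(names(x$keypoints), collapse = ", ")))
  invisible(x)
}

#' Interpolate or mask low-confidence frames of one keypoint
#'
#' Frames with confidence below `conf_threshold` are unreliable. Gaps of at
#' most `max_gap` consecutive low-confidence frames are filled by linear
#' interpolation of x and y; longer gaps (and unreliable frames at the
#' stream edges) are masked.
#'
#' @param tracks a `pose_tracks` object.
#' @param keypoint keypoint name.
#' @param conf_threshold confidence below which a frame is unreliable
#'   (default 0.5).
#' @param max_gap longest gap, in frames, that is interpolated (default 5).
#' @return list with numeric vectors `x`, `y`, logical `masked` (TRUE =
#'   unusable even after interpolation) and logical `interpolated`.
#' @export
clean_keypoint <- function(tracks, keypoint, conf_threshold = 0.5, max_gap = 5L) {
  kp <- tracks$keypoints[[keypoint]]
  if (is.null(kp)) stop("keypoint not present: ", keypoint)
  low <- kp$confidence < conf_threshold
  x <- kp$x
  y <- kp$y
  n <- length(x)
  masked <- logical(n)
  interpolated <- logical(n)
  if (any(low)) {
    runs <- true_runs(low)
    good_idx <- which(!low)
    for (k in seq_len(nrow(runs))) {
      s <- runs[k, "start"]; e <- runs[k, "end"]
      len <- e - s + 1L
      interior <- s > 1L && e < n
      if (interior && len <= max_gap) {
        idx <- s:e
        x[idx] <- stats::approx(good_idx, kp$x[good_idx], xout = idx)$y
        y[idx] <- stats::approx(good_idx, kp$y[good_idx], xout = idx)$y
        interpolated[idx] <- TRUE
      } else {
        masked[s:e] <- TRUE
        x[s:e] <- NA_real_
        y[s:e] <- NA_real_
      }
    }
  }
  list(x = x, y = y, masked = masked, interpolated = interpolated)
}

# Median position (x, y) of a keypoint over confident frames.
keypoint_position <- function(tracks, keypoint, conf_threshold = 0.5,
                              min_frames = 10L) {
  kp <- tracks$keypoints[[keypoint]]
  if (is.null(kp)) stop("keypoint not present: ", keypoint)
  ok <- kp$confidence >= conf_threshold
  if (sum(ok) < min_frames) {
    stop(sprintf("keypoint %s has only %d confident frames (>= %d required)",
                 keypoint, sum(ok), min_frames))
  }
  c(x = stats::median(kp$x[ok]), y = stats::median(kp$y[ok]))
}
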