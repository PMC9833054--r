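# Widefield GCaMP processing.
#
# Movies are stored internally as T x P matrices (P = H*W pixels in
# column-major image order) with image shape carried alongside; this keeps
# per-pixel operations (baseline means, SDs, thresholds) as fast column
# operations.

#' Construct a strobed two-channel widefield stack
#'
#' Raw acquisition interleaves two illumination channels frame-by-frame at
#' the combined rate: blue-excitation frames carry GCaMP fluorescence, green
#' illumination frames carry reflectance (hemodynamics, no indicator
#' signal). `channel_order` names the channel of the first frame.
#'
#' @param frames T x P numeric matrix of 12-bit intensities (P = H*W,
#'   column-major), or a T x H x W array.
#' @param h,w image dimensions (ignored for array input).
#' @param combined_rate combined frame rate in Hz (default 120).
#' @param channel_order two channel names, first frame first
#'   (default fluorescence then reflectance).
#' @param pixel_size_um pixel size in micrometers (default 68, the
#'   resolution after 8x8 camera binning).
#' @return A `strobed_stack` object.
#' @export
strobed_stack <- function(frames, h = NULL, w = NULL, combined_rate = 120,
                          channel_order = c("fluorescence", "reflectance"),
                          pixel_size_um = 68) {
  if (length(dim(frames)) == 3L) {
    d <- dim(frames)
    h <- d[2L]; w <- d[3L]
    frames <- matrix(frames, nrow = d[1L])
  }
  stopifnot(is.matrix(frames), !is.null(h), !is.null(w), h * w == ncol(frames))
  if (min(frames) < 0 || max(frames) > 4095) {
    stop("strobed stack values must lie in the 12-bit range [0, 4095]")
  }
  stopifnot(length(channel_order) == 2L, channel_order[1L] != channel_order[2L])
  structure(
    list(frames = frames, h = as.integer(h), w = as.integer(w),
         combined_rate = combined_rate, channel_order = channel_order,
         pixel_size_um = pixel_size_um),
    class = "strobed_stack"
  )
}

#' @export
print.strobed_stack <- function(x, ...) {
  cat(sprintf("<strobed_stack> %d frames %dx%d @ %g Hz combined, order: %s\n",
              nrow(x$frames), x$h, x$w, x$combined_rate,
              paste(x$channel_order, collapse = " -> ")))
  invisible(x)
}

channel_movie <- function(values, h, w, rate, channel) {
  structure(list(values = values, h = h, w = w, rate = rate, channel = channel),
            class = "channel_movie")
}

#' Demultiplex a strobed stack into its two channels
#'
#' Splits interleaved frames into per-channel movies at half the combined
#' rate. A trailing unpaired frame is dropped with a warning so both
#' channels have equal length.
#'
#' @param stack a `strobed_stack`.
#' @return named list of two `channel_movie` objects (names from
#'   `channel_order`), each with `rate = combined_rate / 2`.
#' @export
demultiplex <- function(stack) {
  stopifnot(inherits(stack, "strobed_stack"))
  n <- nrow(stack$frames)
  if (n < 2L) stop("need at least 2 frames (one per channel) to demultiplex")
  if (n %% 2L == 1L) {
    warning(sprintf("dropping trailing unpaired frame (%d of %d)", n, n))
    n <- n - 1L
  }
  rate <- stack$combined_rate / 2
  out <- list(
    channel_movie(stack$frames[seq.int(1L, n, 2L), , drop = FALSE],
                  stack$h, stack$w, rate, stack$channel_order[1L]),
    channel_movie(stack$frames[seq.int(2L, n, 2L), , drop = FALSE],
                  stack$h, stack$w, rate, stack$channel_order[2L])
  )
  names(out) <- stack$channel_order
  out
}

#' Percent dF/F relative to a per-pixel baseline
#'
#' For each pixel, F0 is the mean intensity over the baseline window
#' (default: trial start to water-reward delivery) and the output is
#' `(F - F0) / F0 * 100`. Pixels with near-zero baseline (outside the
#' preparation) are masked and carried as zeros.
#'
#' @param movie a `channel_movie`.
#' @param baseline_window_s half-open window `c(t0, t1)` in seconds used for
#'   F0 (default `c(0, 6)`, i.e. up to reward delivery).
#' @param eps baseline level at or below which a pixel is masked.
#' @return A `dff_movie`: list with `values` (percent dF/F, T x P), `h`,
#'   `w`, `rate`, `baseline_window_s`, `corrected` (FALSE), `f0`, and
#'   logical `mask` (TRUE = excluded pixel).
#' @export
compute_dff <- function(movie, baseline_window_s = c(0, 6), eps = 1e-3) {
  stopifnot(inherits(movie, "channel_movie"))
  idx <- frame_window(baseline_window_s[1L], baseline_window_s[2L],
                      movie$rate, n_frames = nrow(movie$values))
  f0 <- colMeans(movie$values[idx, , drop = FALSE])
  mask <- f0 <= eps
  if (all(mask)) stop("all pixels have (near-)zero baseline; cannot form dF/F")
  vals <- dff_percent_cpp(movie$values, f0, eps)
  structure(
    list(values = vals, h = movie$h, w = movie$w, rate = movie$rate,
         baseline_window_s = baseline_window_s, corrected = FALSE,
         f0 = f0, mask = mask),
    class = "dff_movie"
  )
}

#' Hemodynamic correction by reflectance subtraction
#'
#' Blood-volume and movement artifacts modulate both the fluorescence and
#' the reflectance channel, while the calcium signal appears only in
#' fluorescence. Subtracting the reflectance dF/F from the fluorescence
#' dF/F, pixel by pixel and frame by frame, removes the shared artifact.
#' Subtraction of percent traces is the single supported mode.
#'
#' @param fluo_dff,reflect_dff `dff_movie` objects of identical shape, rate
#'   and baseline window.
#' @return corrected `dff_movie` (`corrected = TRUE`; mask is the union of
#'   the channel masks).
#' @export
hemodynamic_correct <- function(fluo_dff, reflect_dff) {
  stopifnot(inherits(fluo_dff, "dff_movie"), inherits(reflect_dff, "dff_movie"))
  if (!identical(dim(fluo_dff$values), dim(reflect_dff$values)) ||
      fluo_dff$h != reflect_dff$h || fluo_dff$rate != reflect_dff$rate) {
    stop("fluorescence and reflectance movies differ in shape or rate")
  }
  if (!isTRUE(all.equal(fluo_dff$baseline_window_s,
                        reflect_dff$baseline_window_s))) {
    stop("channels were normalized to different baseline windows")
  }
  out <- fluo_dff
  out$values <- fluo_dff$values - reflect_dff$values
  out$mask <- fluo_dff$mask | reflect_dff$mask
  if (any(out$mask)) out$values[, out$mask] <- 0
  out$corrected <- TRUE
  out
}

#' Extract the mean dF/F trace of a 5x5-pixel ROI window
#'
#' The region is a 5 x 5 pixel square centered on the ROI centroid (rounded
#' to the nearest pixel, ties toward the smaller index). ROIs are interior
#' by construction; a window clipped by the image border is an error.
#'
#' @param dff a `dff_movie`.
#' @param roi_map an `atlas_roi_map` registered to the movie's frame.
#' @param roi ROI name (e.g. `"M1_contra"`).
#' @param half window half-width in pixels (default 2, i.e. 5x5).
#' @return An `roi_trace`: numeric vector (percent dF/F per frame) with
#'   attributes `rate`, `roi` and `center` (row, col).
#' @export
extract_trace <- function(dff, roi_map, roi, half = 2L) {
  stopifnot(inherits(dff, "dff_movie"), inherits(roi_map, "atlas_roi_map"))
  if (!identical(as.integer(c(dff$h, dff$w)), roi_map$shape)) {
    stop("ROI map shape does not match the movie")
  }
  ctr <- roi_centroid(roi_map, roi)
  rows <- (ctr[1L] - half):(ctr[1L] + half)
  cols <- (ctr[2L] - half):(ctr[2L] + half)
  if (min(rows) < 1L || min(cols) < 1L || max(rows) > dff$h || max(cols) > dff$w) {
    stop(sprintf("ROI window for %s is clipped by the image border", roi))
  }
  pix <- as.vector(outer(rows, (cols - 1L) * dff$h, `+`))
  trace <- rowMeans(dff$values[, pix, drop = FALSE])
  structure(trace, rate = dff$rate, roi = roi, center = ctr, class = "roi_trace")
}

# Category -> peak search window (seconds, half-open) within the 10-s trial.
peak_search_window <- function(category, timeline, trial_duration_s = 10) {
  if (category %in% c("success", "partial_fail")) {
    if (is.na(timeline$reward_s)) stop("rewarded category without a reward time")
    c(timeline$reward_s, timeline$reward_s + 4)
  } else if (category == "unrewarded_reach") {
    c(0, trial_duration_s)
  } else {
    stop("no peak search window is defined for category '", category, "'")
  }
}

#' Peak amplitude of an ROI trace
#'
#' Amplitude is measured from the baseline (mean over 1-5 s from trial
#' start) to the maximum of the trace inside the category-specific search
#' window: after the water drop (reward to +4 s) for success and partial
#' fail trials — where reaches are cue-locked — and the entire 10-s trial
#' for unrewarded reach trials, where reaching can occur at any time. Ties
#' are broken by the earliest peak.
#'
#' @param trace an `roi_trace` (or numeric vector with a `rate` attribute).
#' @param timeline a `trial_timeline`.
#' @param category trial category (`success`, `partial_fail` or
#'   `unrewarded_reach`).
#' @param baseline_window_s baseline window in seconds (default `c(1, 5)`).
#' @return A `peak_result` list: `roi`, `amplitude` (percent dF/F),
#'   `peak_time_s`, `baseline_mean`, `baseline_sd`, `search_window_s`.
#' @export
peak_amplitude <- function(trace, timeline, category,
                           baseline_window_s = c(1, 5)) {
  rate <- attr(trace, "rate")
  if (is.null(rate)) stop("trace must carry a 'rate' attribute")
  n <- length(trace)
  win <- peak_search_window(category, timeline)
  b_idx <- frame_window(baseline_window_s[1L], baseline_window_s[2L], rate, n)
  w_idx <- tryCatch(frame_window(win[1L], win[2L], rate, n),
                    error = function(e) stop(
                      sprintf("peak search window [%g, %g) s exceeds the trace (%.2f s)",
                              win[1L], win[2L], n / rate)))
  b_mean <- mean(trace[b_idx])
  b_sd <- stats::sd(trace[b_idx])
  k <- which.max(trace[w_idx])     # which.max returns the earliest maximum
  list(
    roi = attr(trace, "roi") %||% NA_character_,
    amplitude = unname(trace[w_idx][k] - b_mean),
    peak_time_s = unname((w_idx[k] - 1L) / rate),
    baseline_mean = b_mean,
    baseline_sd = b_sd,
    search_window_s = win
  )
}

#' Cortical area activated above 4x baseline SD
#'
#' A pixel is activated when its maximum dF/F inside the category-specific
#' peak search window exceeds `sd_factor` (default 4) times its own
#' baseline SD (1-5 s from trial start). Only pixels inside the brain mask
#' (union of atlas labels, when a map is supplied) are eligible;
#' zero-variance baseline pixels are excluded and reported.
#'
#' `sd_mode = "global"` replaces the per-pixel SD with the median baseline
#' SD over eligible pixels, for sensitivity analyses; the per-pixel rule is
#' the default.
#'
#' @param dff a `dff_movie`.
#' @param timeline a `trial_timeline`.
#' @param category trial category defining the search window
#'   (default `"success"`).
#' @param roi_map optional `atlas_roi_map`; its labels define the brain mask.
#' @param sd_factor activation threshold in baseline SDs (default 4).
#' @param sd_mode `"per_pixel"` (default) or `"global"`.
#' @param baseline_window_s baseline window in seconds (default `c(1, 5)`).
#' @return list with `n_pixels`, `area_mm2`, `n_eligible`,
#'   `n_zero_variance` and logical vector `activated` (length P).
#' @export
area_activated <- function(dff, timeline, category = "success", roi_map = NULL,
                           sd_factor = 4, sd_mode = c("per_pixel", "global"),
                           baseline_window_s = c(1, 5),
                           pixel_size_um = 68) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(inherits(dff, "dff_movie"))
  n <- nrow(dff$values)
  b_idx <- frame_window(baseline_window_s[1L], baseline_window_s[2L], dff$rate, n)
  win <- peak_search_window(category, timeline)
  w_idx <- frame_window(win[1L], win[2L], dff$rate, n)

  base <- dff$values[b_idx, , drop = FALSE]
  m <- colMeans(base)
  sds <- sqrt(pmax(0, colMeans(base^2) - m^2) * length(b_idx) / (length(b_idx) - 1L))

  peak <- do.call(pmax, asplit(dff$values[w_idx, , drop = FALSE], 1L))

  eligible <- !dff$mask
  if (!is.null(roi_map)) {
    if (!identical(as.integer(c(dff$h, dff$w)), roi_map$shape)) {
      stop("ROI map shape does not match the movie")
    }
    eligible <- eligible & (as.vector(roi_map$label_image) > 0L)
  }
  zero_var <- eligible & sds <= 0
  eligible <- eligible & sds > 0

  thr <- if (sd_mode == "per_pixel") sd_factor * sds
         else rep(sd_factor * stats::median(sds[eligible]), length(sds))
  activated <- eligible & (peak > thr)
  list(
    n_pixels = sum(activated),
    area_mm2 = sum(activated) * (pixel_size_um / 1000)^2,
    n_eligible = sum(eligible),
    n_zero_variance = sum(zero_var),
    activated = activated
  )
}
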