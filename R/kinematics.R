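#' Spout geometry from landmark tracks
#'
#' The spout distance — the vertical separation between the paw-rest
#' platform and the water spout — is the unit in which all reach path
#' lengths are expressed: 1.0 spout distances is the most efficient route
#' from platform to spout. Landmark heights are taken as medians over
#' confident frames, which makes the estimate robust to tracking jitter.
#'
#' @param tracks `pose_tracks` containing `platform` and `spout` keypoints.
#' @param conf_threshold confidence below which a frame is ignored.
#' @param min_frames minimum confident frames required per landmark.
#' @return A `spout_geometry` list: `spout_distance_px`, `platform_y`,
#'   `spout_y` (pixels; y increases downward).
#' @export
spout_distance <- function(tracks, conf_threshold = 0.5, min_frames = 10L) {
  plat <- keypoint_position(tracks, "platform", conf_threshold, min_frames)
  spt <- keypoint_position(tracks, "spout", conf_threshold, min_frames)
  d <- abs(plat["y"] - spt["y"])
  if (d <= 0) {
    stop("degenerate geometry: platform and spout heights coincide")
  }
  structure(
    list(spout_distance_px = unname(d),
         platform_y = unname(plat["y"]),
         spout_y = unname(spt["y"])),
    class = "spout_geometry"
  )
}

#' Euclidean path length of the left-paw reach, in spout-distance multiples
#'
#' Sums frame-to-frame straight-line displacements of the left paw over the
#' window from water-reward delivery to 1.1 s afterward — the time a
#' proficient mouse needs to complete a reach — and divides by the spout
#' distance. Only consecutive usable frames contribute: unreliable gaps of
#' at most `max_gap` frames are linearly interpolated (and do contribute),
#' while longer gaps are masked, excluded from the sum, and flag the trial.
#'
#' @param tracks `pose_tracks` for one rewarded trial.
#' @param timeline `trial_timeline` with a `reward_s`.
#' @param geometry `spout_geometry`.
#' @param window_s length of the measurement window in seconds (default 1.1).
#' @param conf_threshold,max_gap see [clean_keypoint()].
#' @return numeric scalar (spout-distance multiples) with attribute
#'   `flagged` = TRUE when a masked gap longer than `max_gap` fell inside
#'   the window (such trials are excluded from distribution summaries).
#' @export
path_length <- function(tracks, timeline, geometry, window_s = 1.1,
                        conf_threshold = 0.5, max_gap = 5L) {
  if (is.na(timeline$reward_s)) {
    stop("path_length is defined for rewarded trials (no reward time)")
  }
  t0 <- timeline$reward_s
  t1 <- timeline$reward_s + window_s
  idx <- frame_window(t0, t1, tracks$rate, n_frames = length(tracks$t))
  paw <- clean_keypoint(tracks, "left_paw", conf_threshold, max_gap)
  x <- paw$x[idx]
  y <- paw$y[idx]
  masked <- paw$masked[idx]
  # consecutive usable pairs only
  ok_pair <- !masked[-length(masked)] & !masked[-1L]
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  total <- sum(seg[ok_pair])
  structure(total / geometry$spout_distance_px, flagged = any(masked))
}

#' Bin reach path lengths into spout-distance multiples
#'
#' Bin `k` covers `[k, k+1)` spout distances, so a trial whose paw traveled
#' exactly 4 spout distances lands in bin 4. Frequencies are relative (%).
#'
#' @param lengths numeric vector of path lengths in spout-distance multiples.
#' @return data.frame with columns `bin` (integer lower edge) and
#'   `rel_freq_pct`; zero rows for empty input.
#' @export
bin_distances <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (!length(lengths)) {
    return(data.frame(bin = integer(0), rel_freq_pct = numeric(0)))
  }
  if (any(lengths < 0)) stop("path lengths must be non-negative")
  k <- floor(lengths)
  bins <- seq.int(0L, max(k))
  counts <- tabulate(k + 1L, nbins = length(bins))
  data.frame(bin = bins, rel_freq_pct = 100 * counts / length(lengths))
}

#' Per-mouse then per-genotype reach-distance statistics
#'
#' The hierarchy matters: the mean and (sample) SD of path length are
#' computed for each mouse across its successful trials, and genotype-level
#' values are means of the per-mouse values — never pooled across mice — so
#' mice with many trials do not dominate.
#'
#' @param lengths data.frame with columns `genotype`, `mouse`, `length`
#'   (spout-distance multiples; flagged/NA trials should be removed first).
#' @return list with `per_mouse` (genotype, mouse, n_trials, mean, sd) and
#'   `per_genotype` (genotype, n_mice, mean, sem, sd_mean, sd_sem — means
#'   and SEMs over per-mouse means and per-mouse SDs).
#' @export
trajectory_stats <- function(lengths) {
  stopifnot(all(c("genotype", "mouse", "length") %in% names(lengths)))
  lengths <- lengths[!is.na(lengths$length), , drop = FALSE]
  key <- interaction(lengths$genotype, lengths$mouse, drop = TRUE)
  per_mouse <- do.call(rbind, lapply(split(lengths, key), function(d) {
    data.frame(genotype = d$genotype[1L], mouse = d$mouse[1L],
               n_trials = nrow(d),
               mean = mean(d$length),
               sd = if (nrow(d) > 1L) stats::sd(d$length) else NA_real_)
  }))
  rownames(per_mouse) <- NULL
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
  per_genotype <- do.call(rbind, lapply(split(per_mouse, per_mouse$genotype), function(d) {
    data.frame(genotype = d$genotype[1L], n_mice = nrow(d),
               mean = mean(d$mean), sem = sem(d$mean),
               sd_mean = mean(d$sd, na.rm = TRUE),
               sd_sem = sem(d$sd[!is.na(d$sd)]))
  }))
  rownames(per_genotype) <- NULL
  list(per_mouse = per_mouse, per_genotype = per_genotype)
}

#' Left-paw lift trace
#'
#' Platform-referenced y-direction movement of the left paw over the full
#' 10-s analysis window: `platform_y - paw_y`, so positive values mean the
#' paw is lifted above the platform.
#'
#' @param tracks `pose_tracks` for one trial.
#' @param geometry `spout_geometry`.
#' @param conf_threshold,max_gap see [clean_keypoint()].
#' @return numeric vector (pixels) at the track rate; masked frames are NA.
#' @export
lift_trace <- function(tracks, geometry, conf_threshold = 0.5, max_gap = 5L) {
  tracks <- truncate_trial(tracks, duration_s = 10)
  paw <- clean_keypoint(tracks, "left_paw", conf_threshold, max_gap)
  geometry$platform_y - paw$y
}
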