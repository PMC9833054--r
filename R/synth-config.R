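#' Configuration of the synthetic-session simulator
#'
#' Defines the study conditions a simulated session emulates: ~120 trials
#' per daily session alternating rewarded and non-rewarded (always starting
#' rewarded), behavioral camera at 60 Hz, strobed widefield imaging at
#' 120 Hz combined. Default behavioral probabilities emulate a proficient
#' (day-8 wild-type-like) session: ~89% success, rare unrewarded and early
#' reaches. Reach path-length targets are drawn from a normal distribution
#' in spout-distance multiples (default mean 2.1, SD 0.6, the proficient
#' day-8 values), truncated to the interval from 1 to 4.5.
#'
#' Per-ROI transient amplitudes are percent dF/F. Published work does not
#' report per-region magnitudes numerically; the defaults (2-8%) are
#' plausible widefield GCaMP6s ranges, strongest in contralateral motor
#' cortex. Hemodynamic gains scale a shared artifact waveform (slow
#' vasomotion sinusoid plus a reach-locked dip) that enters both channels;
#' with equal gains the reflectance subtraction removes it exactly.
#'
#' @param n_trials number of trials (even; alternation starts rewarded).
#' @param frame_rate_behavior behavioral camera rate, Hz.
#' @param frame_rate_imaging_combined combined strobed imaging rate, Hz.
#' @param image_shape widefield frame shape `c(H, W)`.
#' @param spout_distance_px platform-to-spout height separation in pixels.
#' @param category_probabilities named probabilities over rewarded-trial
#'   categories (`success`, `partial_fail`, `complete_fail`, `no_reach`,
#'   `groom`); must sum to 1.
#' @param unrewarded_reach_probability probability that a non-rewarded
#'   trial contains reaching/grooming.
#' @param early_reach_probability probability that a successful trial also
#'   contains a pre-reward reach.
#' @param trajectory_length_mean,trajectory_length_sd reach path-length
#'   target distribution, in spout-distance multiples.
#' @param roi_peak_amplitudes named percent-dF/F transient amplitudes per
#'   atlas ROI.
#' @param hemodynamic_gain_fluo,hemodynamic_gain_reflect artifact amplitude
#'   in percent dF/F contributed to each channel by the unit waveform.
#' @param noise_sd imaging shot-noise SD, percent of baseline intensity.
#' @param pose_noise_px tracking jitter SD on keypoint coordinates, pixels.
#' @param dropout_fraction expected fraction of low-confidence pose frames.
#' @param baseline_counts_fluo,baseline_counts_reflect mean raw 12-bit
#'   intensity of each channel.
#' @param seed integer seed; all randomness flows from it, with per-trial
#'   substreams derived from (seed, trial index).
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_trials = 120L,
                         frame_rate_behavior = 60,
                         frame_rate_imaging_combined = 120,
                         image_shape = c(128L, 128L),
                         spout_distance_px = 40,
                         category_probabilities = c(success = 0.89,
                                                    partial_fail = 0.05,
                                                    complete_fail = 0.01,
                                                    no_reach = 0.04,
                                                    groom = 0.01),
                         unrewarded_reach_probability = 0.094,
                         early_reach_probability = 0.018,
                         trajectory_length_mean = 2.1,
                         trajectory_length_sd = 0.6,
                         roi_peak_amplitudes = c(M1_contra = 5, M2_contra = 4,
                                                 sspfl_contra = 3, rspagl_contra = 3,
                                                 M1_ipsi = 2.5, M2_ipsi = 2),
                         hemodynamic_gain_fluo = 2,
                         hemodynamic_gain_reflect = 2,
                         noise_sd = 0.2,
                         pose_noise_px = 0.05,
                         dropout_fraction = 0.02,
                         baseline_counts_fluo = 2000,
                         baseline_counts_reflect = 2500,
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

#' @rdname synth_config
#' @param config a `synth_config` to validate.
#' @export
validate_synth_config <- function(config) {
  fail <- function(field, msg) {
    stop(sprintf("invalid synth_config: field '%s' %s", field, msg), call. = FALSE)
  }
  with(config, {
    if (n_trials < 2 || n_trials %% 2 != 0) {
      fail("n_trials", "must be even and >= 2 (trials alternate, starting rewarded)")
    }
    if (frame_rate_behavior <= 0) fail("frame_rate_behavior", "must be positive")
    if (frame_rate_imaging_combined <= 0) {
      fail("frame_rate_imaging_combined", "must be positive")
    }
    if (length(image_shape) != 2 || any(image_shape < 16)) {
      fail("image_shape", "must be c(H, W) with H, W >= 16")
    }
    if (spout_distance_px <= 0) fail("spout_distance_px", "must be positive")
    need <- c("success", "partial_fail", "complete_fail", "no_reach", "groom")
    if (!all(need %in% names(category_probabilities))) {
      fail("category_probabilities",
           paste("must name all of:", paste(need, collapse = ", ")))
    }
    p <- category_probabilities[need]
    if (any(p < 0 | p > 1)) fail("category_probabilities", "must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-9) fail("category_probabilities", "must sum to 1")
    for (f in c("unrewarded_reach_probability", "early_reach_probability")) {
      v <- get(f)
      if (v < 0 || v > 1) fail(f, "must lie in [0, 1]")
    }
    if (trajectory_length_mean < 1) {
      fail("trajectory_length_mean", "must be >= 1 (spout contact requires >= 1)")
    }
    for (f in c("trajectory_length_sd", "noise_sd", "pose_noise_px")) {
      if (get(f) < 0) fail(f, "must be >= 0")
    }
    if (dropout_fraction < 0 || dropout_fraction > 0.5) {
      fail("dropout_fraction", "must lie in [0, 0.5]")
    }
    if (length(roi_peak_amplitudes) && is.null(names(roi_peak_amplitudes))) {
      fail("roi_peak_amplitudes", "must be a named vector of percent amplitudes")
    }
    if (baseline_counts_fluo <= 0 || baseline_counts_fluo > 3500 ||
        baseline_counts_reflect <= 0 || baseline_counts_reflect > 3500) {
      fail("baseline_counts_fluo/reflect",
           "must leave 12-bit headroom (0 < counts <= 3500)")
    }
    if (!is.finite(seed)) fail("seed", "must be a finite integer")
  })
  invisible(config)
}

# Keypoint layout in the behavioral camera frame, derived from the spout
# distance. Platform and spout share x so the most efficient reach is a
# straight vertical lift of exactly one spout distance.
synth_layout <- function(config) {
  D <- config$spout_distance_px
  platform <- c(x = 75, y = 60 + D)
  spout <- c(x = 75, y = 60)
  mouth <- c(x = 75 + 0.175 * D, y = 60 + 0.05 * D)
  list(platform = platform, spout = spout, mouth = mouth,
       right_paw = c(x = platform[["x"]] + 0.3 * D, y = platform[["y"]]))
}
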