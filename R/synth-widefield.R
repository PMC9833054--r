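# Synthetic strobed widefield movies with known ground truth.

#' Calcium-transient impulse kernel
#'
#' Difference-of-exponentials kernel (rise 0.1 s, decay 1.0 s) approximating
#' slow GCaMP6s kinetics, normalized to a unit peak so a transient of
#' amplitude A peaks at exactly A percent dF/F.
#'
#' @param t time in seconds relative to transient onset (vector).
#' @param rise,decay time constants in seconds.
#' @return kernel values (0 for t < 0, peak 1).
#' @export
gcamp_kernel <- function(t, rise = 0.1, decay = 1.0) {
  stopifnot(decay > rise, rise > 0)
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  kmax <- exp(-tpk / decay) - exp(-tpk / rise)
  k <- (exp(-t / decay) - exp(-t / rise)) / kmax
  k[t < 0] <- 0
  k
}

#' Shared hemodynamic artifact waveform
#'
#' Unit-scale waveform entering both imaging channels: a slow ~0.1-Hz
#' vasomotion sinusoid plus, when the trial contains a reach, a
#' reach-locked dip (functional hyperemia darkens the reflectance). The
#' channel configs scale this waveform into percent dF/F.
#'
#' @param t time in seconds from trial start.
#' @param reach_onset_s reach onset (NA for trials without a reach).
#' @param phase_shift_s per-trial phase jitter of the sinusoid, seconds.
#' @return waveform values (dimensionless, order 1).
#' @export
hemo_waveform <- function(t, reach_onset_s = NA_real_, phase_shift_s = 0) {
  w <- 0.8 * sin(2 * pi * 0.1 * (t - 5 - phase_shift_s))
  if (!is.na(reach_onset_s)) {
    w <- w - 0.5 * exp(-(t - reach_onset_s - 0.6)^2 / (2 * 0.4^2))
  }
  w
}

# Categories whose trials carry a neural transient.
transient_categories <- c("success", "partial_fail", "complete_fail",
                          "unrewarded_reach")

#' Simulate the strobed widefield movie of one trial
#'
#' Fluorescence frames carry ROI-localized calcium transients (difference-
#' of-exponentials kernel scaled by the per-ROI amplitude, onset at the
#' trial's reach onset) plus the shared hemodynamic waveform times
#' `hemodynamic_gain_fluo`, plus Gaussian shot noise. Reflectance frames
#' carry the same waveform times `hemodynamic_gain_reflect` plus
#' independent noise and no transients. Frames are interleaved
#' fluorescence-first at the combined rate and quantized to the 12-bit
#' range. Uses the current RNG state.
#'
#' @param category trial category (see [classify_trial()]).
#' @param reach_onset_s transient onset in seconds (NA for no-reach trials).
#' @param roi_map `atlas_roi_map` matching `config$image_shape`.
#' @param config a [synth_config()].
#' @param end_s trial length in seconds.
#' @param phase_shift_s hemodynamic sinusoid phase jitter, seconds.
#' @return A `strobed_stack`.
#' @export
simulate_widefield_trial <- function(category, reach_onset_s, roi_map, config,
                                     end_s, phase_shift_s = 0) {
  amps <- config$roi_peak_amplitudes
  unknown <- setdiff(names(amps), roi_map$names)
  if (length(unknown)) {
    stop("roi_peak_amplitudes names absent from the ROI map: ",
         paste(unknown, collapse = ", "))
  }
  rate <- config$frame_rate_imaging_combined / 2
  n60 <- as.integer(round(end_s * rate))
  P <- prod(config$image_shape)
  t_f <- (seq_len(n60) - 1L) / rate                       # fluorescence frames
  t_r <- t_f + 1 / config$frame_rate_imaging_combined     # reflectance frames

  has_transient <- category %in% transient_categories &&
    length(amps) > 0 && !is.na(reach_onset_s)
  onset_w <- if (has_transient) reach_onset_s else NA_real_
  w_f <- hemo_waveform(t_f, onset_w, phase_shift_s)
  w_r <- hemo_waveform(t_r, onset_w, phase_shift_s)

  f0 <- config$baseline_counts_fluo
  r0 <- config$baseline_counts_reflect
  sig_pix <- integer(0)
  sig_amp <- numeric(0)
  kern_counts <- numeric(0)
  if (has_transient) {
    kern_counts <- (f0 / 100) * gcamp_kernel(t_f - reach_onset_s)
    for (roi in names(amps)) {
      pix <- roi_pixels(roi_map, roi)
      sig_pix <- c(sig_pix, pix - 1L)
      sig_amp <- c(sig_amp, rep(amps[[roi]], length(pix)))
    }
  }
  # single fused pass: baselines + transient + noise, 12-bit quantization
  # (round half up), channels interleaved fluorescence-first
  frames <- assemble_strobed_cpp(
    base_f = f0 * (1 + config$hemodynamic_gain_fluo * w_f / 100),
    base_r = r0 * (1 + config$hemodynamic_gain_reflect * w_r / 100),
    kern_counts = kern_counts, sig_pix = sig_pix, sig_amp = sig_amp,
    P = P, noise_f = config$noise_sd / 100 * f0,
    noise_r = config$noise_sd / 100 * r0)
  strobed_stack(frames, h = config$image_shape[1L], w = config$image_shape[2L],
                combined_rate = config$frame_rate_imaging_combined)
}

#' Simulate the widefield movies of a whole session
#'
#' Thin wrapper over [simulate_widefield_trial()] iterating a session's
#' trials with per-trial derived RNG substreams; mirrors what
#' [generate_session()] does when `imaging = TRUE`.
#'
#' @param session a [generate_session()] result (imaging may be absent).
#' @param roi_map `atlas_roi_map`; defaults to the session's.
#' @param trials trial indices to simulate (default all).
#' @return list of `strobed_stack` objects indexed like `trials`.
#' @export
simulate_widefield <- function(session, roi_map = session$roi_map,
                               trials = seq_len(nrow(session$log))) {
  gt <- session$ground_truth
  lapply(trials, function(i) {
    set.seed(derive_seed(session$config$seed, i, salt = 2L))
    phase <- stats::runif(1, -0.3, 0.3)
    simulate_widefield_trial(gt$true_category[i], gt$reach_onset_s[i],
                             roi_map, session$config, gt$end_s[i],
                             phase_shift_s = phase)
  })
}
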