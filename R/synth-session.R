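#' Generate a complete synthetic session with ground truth
#'
#' Produces the three input streams of a daily water-reaching session —
#' event log, pose tracks and (optionally) strobed widefield movies — plus
#' the hidden per-trial latents (`GroundTruth`) used by the recovery tests.
#' Trial types strictly alternate starting with a rewarded trial; every
#' trial's streams share the camera-start time origin. All randomness is
#' derived from `config$seed`, with deterministic per-trial substreams, so
#' the same config yields bit-identical sessions.
#'
#' @param config a [synth_config()].
#' @param imaging also simulate the widefield movies (memory-heavy at the
#'   default 128 x 128; consider a smaller `image_shape` or the
#'   `imaging_trials` subset).
#' @param imaging_trials trial indices to image when `imaging = TRUE`
#'   (default all).
#' @return list with `log` (event-log data.frame: trial_index, type,
#'   cue_time_s, tone_time_s, reward_time_s, touch_time_s, end_time_s),
#'   `tracks` (list of `pose_tracks`), `timelines` (list of
#'   `trial_timeline`), `stacks` (list of `strobed_stack` or NULL),
#'   `ground_truth` (data.frame of hidden latents), `roi_map`, `config`.
#' @export
generate_session <- function(config, imaging = FALSE, imaging_trials = NULL) {
  validate_synth_config(config)
  n <- config$n_trials
  types <- rep(c("rewarded", "nonrewarded"), length.out = n)
  roi_map <- default_atlas(config$image_shape)

  sample_target <- function() {
    repeat {
      v <- stats::rnorm(1, config$trajectory_length_mean,
                        config$trajectory_length_sd)
      if (v >= 1 && v <= 4.5) return(v)
    }
  }

  logs <- vector("list", n)
  gts <- vector("list", n)
  tracks <- vector("list", n)
  timelines <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(config$seed, i, salt = 1L))
    type <- types[i]
    if (type == "rewarded") {
      p <- config$category_probabilities
      category <- sample(names(p), 1L, prob = p)
    } else {
      category <- if (stats::runif(1) < config$unrewarded_reach_probability)
        "unrewarded_reach" else "no_reach"
    }
    early <- category == "success" &&
      stats::runif(1) < config$early_reach_probability
    target <- NA_real_
    touch_s <- NA_real_
    style <- "reach"
    if (category %in% c("success", "partial_fail")) {
      target <- sample_target()
      touch_s <- 6 + min(1.07, max(0.9, stats::rnorm(1, 1.0, 0.03)))
    } else if (category == "unrewarded_reach") {
      style <- sample(c("reach", "groom"), 1L, prob = c(0.7, 0.3))
      if (style == "reach") target <- sample_target()
    }
    timeline <- build_timeline(type, touch_s)
    tr <- simulate_trajectory(category, config, timeline,
                              target_length = target, early_reach = early,
                              style = style)
    logs[[i]] <- data.frame(
      trial_index = i, type = type,
      cue_time_s = timeline$visual_cue_s, tone_time_s = timeline$tone_s,
      reward_time_s = timeline$reward_s, touch_time_s = timeline$touch_s,
      end_time_s = timeline$end_s
    )
    gts[[i]] <- data.frame(
      trial_index = i, type = type, true_category = category,
      early_reach = if (category == "success") early else NA,
      reach_onset_s = attr(tr, "reach_onset_s"),
      contact_s = attr(tr, "contact_s"),
      true_path_length = target,
      style = if (category == "unrewarded_reach") style else NA_character_,
      end_s = timeline$end_s
    )
    tracks[[i]] <- tr
    timelines[[i]] <- timeline
  }
  session <- list(
    log = do.call(rbind, logs),
    tracks = tracks,
    timelines = timelines,
    stacks = NULL,
    ground_truth = do.call(rbind, gts),
    roi_map = roi_map,
    config = config
  )
  if (imaging) {
    idx <- imaging_trials %||% seq_len(n)
    session$stacks <- stats::setNames(simulate_widefield(session, roi_map, idx),
                                      as.character(idx))
  }
  session
}
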