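#' Parameters of the rule-based trial classifier
#'
#' The study this pipeline reproduces scored trials manually; the classifier
#' here operationalizes the written category definitions as a deterministic
#' rule cascade over pose tracks. All spatial thresholds are expressed as
#' fractions of the spout distance so they transfer across camera zooms.
#'
#' @param lift_threshold paw elevation above platform level that counts as a
#'   lift, as a fraction of spout distance (default 0.10).
#' @param forward_threshold net displacement of the paw from its rest
#'   position toward the spout that counts as a forward reach, as a fraction
#'   of spout distance (default 0.15).
#' @param contact_radius distance from the spout (or mouth) keypoint that
#'   counts as contact, as a fraction of spout distance (default 0.10).
#' @param retrieval_window_s time after first spout contact within which the
#'   paw must come to the mouth for the trial to count as a successful
#'   grasp-to-drink (default 2 s).
#' @param groom_min_cycles minimum number of paw-to-mouth oscillation cycles,
#'   without spout contact, that counts as grooming (default 3).
#' @param conf_threshold tracking confidence below which a frame is
#'   unreliable (default 0.5).
#' @param max_gap longest unreliable gap, in frames, that is filled by
#'   linear interpolation (default 5); longer gaps are masked.
#' @param max_masked_fraction masked fraction of the analysis window above
#'   which the trial is unscorable and is assigned `disregard` (default 0.5).
#' @return A `classifier_params` list.
#' @export
classifier_params <- function(lift_threshold = 0.10,
                              forward_threshold = 0.15,
                              contact_radius = 0.10,
                              retrieval_window_s = 2,
                              groom_min_cycles = 3L,
                              conf_threshold = 0.5,
                              max_gap = 5L,
                              max_masked_fraction = 0.5) {
  p <- list(lift_threshold = lift_threshold,
            forward_threshold = forward_threshold,
            contact_radius = contact_radius,
            retrieval_window_s = retrieval_window_s,
            groom_min_cycles = as.integer(groom_min_cycles),
            conf_threshold = conf_threshold,
            max_gap = as.integer(max_gap),
            max_masked_fraction = max_masked_fraction)
  stopifnot(p$lift_threshold > 0, p$forward_threshold > 0, p$contact_radius > 0,
            p$retrieval_window_s > 0, p$groom_min_cycles >= 1)
  structure(p, class = "classifier_params")
}

# Legal categories per trial type.
rewarded_categories <- c("disregard", "no_reach", "groom", "success",
                         "partial_fail", "complete_fail")
nonrewarded_categories <- c("disregard", "no_reach", "unrewarded_reach")

#' Detect reach events in the left-paw track
#'
#' A reach event is a run of frames in which the paw is (a) lifted more than
#' `lift_threshold` above the platform level and (b) displaced from its rest
#' position toward the spout by at least `forward_threshold` (projection on
#' the rest-to-spout direction). Rest position is the median paw position
#' before the visual cue.
#'
#' @param tracks `pose_tracks` covering the analysis window.
#' @param timeline a `trial_timeline`.
#' @param geometry a `spout_geometry` (see [spout_distance()]).
#' @param params a `classifier_params`.
#' @return list with `episodes` (matrix of start/end frame indices),
#'   `onset_s` (onset times), `paw` (cleaned track), plus the spout, mouth
#'   and rest reference positions used.
#' @export
reach_events <- function(tracks, timeline, geometry,
                         params = classifier_params()) {
  D <- geometry$spout_distance_px
  paw <- clean_keypoint(tracks, "left_paw", params$conf_threshold, params$max_gap)
  spout_pos <- keypoint_position(tracks, "spout", params$conf_threshold)
  mouth_pos <- keypoint_position(tracks, "mouth", params$conf_threshold)

  pre_cue <- tracks$t < timeline$visual_cue_s & !paw$masked
  if (sum(pre_cue) < 3L) pre_cue <- !paw$masked   # fall back to whole trial
  rest <- c(stats::median(paw$x[pre_cue]), stats::median(paw$y[pre_cue]))

  lift <- (geometry$platform_y - paw$y) > params$lift_threshold * D
  u <- c(spout_pos[1L] - rest[1L], spout_pos[2L] - rest[2L])
  u <- u / sqrt(sum(u^2))
  forward <- ((paw$x - rest[1L]) * u[1L] + (paw$y - rest[2L]) * u[2L]) >
    params$forward_threshold * D
  reach_frame <- lift & forward & !paw$masked
  episodes <- true_runs(reach_frame)
  list(
    episodes = episodes,
    onset_s = if (nrow(episodes)) tracks$t[episodes[, "start"]] else numeric(0),
    paw = paw,
    spout_pos = spout_pos,
    mouth_pos = mouth_pos,
    rest = rest
  )
}

#' Classify one trial from pose tracks
#'
#' Deterministic rule cascade mirroring the behavioral scoring scheme:
#' rewarded trials are `success` (reach, spout contact, paw to mouth within
#' the retrieval window), `partial_fail` (contact but no retrieval),
#' `complete_fail` (reach without contact), `groom` (repeated paw-mouth
#' oscillations without contact) or `no_reach`; non-rewarded trials are
#' `unrewarded_reach` (any reach or groom) or `no_reach`. Trials whose
#' left-paw track is unusable for more than half of the analysis window are
#' `disregard`.
#'
#' @inheritParams reach_events
#' @param type `"rewarded"` or `"nonrewarded"`.
#' @return category label (character scalar) with attributes
#'   `reach_onset_s` (first reach onset, `NA` if none), `contact_s` (first
#'   spout-contact time, `NA` if none) and, for `disregard`, a `reason`.
#' @export
classify_trial <- function(tracks, type = c("rewarded", "nonrewarded"),
                           timeline, geometry, params = classifier_params()) {
  type <- match.arg(type)
  tracks <- truncate_trial(tracks, duration_s = 10)
  D <- geometry$spout_distance_px

  paw_raw <- clean_keypoint(tracks, "left_paw", params$conf_threshold, params$max_gap)
  if (mean(paw_raw$masked) > params$max_masked_fraction) {
    return(structure("disregard",
                     reach_onset_s = NA_real_, contact_s = NA_real_,
                     reason = sprintf("left_paw unusable for %.0f%% of frames",
                                      100 * mean(paw_raw$masked))))
  }

  ev <- reach_events(tracks, timeline, geometry, params)
  paw_xy <- cbind(ev$paw$x, ev$paw$y)
  r_contact <- params$contact_radius * D

  d_spout <- dist_to_point(paw_xy, ev$spout_pos)
  contact_idx <- which(!ev$paw$masked & d_spout <= r_contact)
  contact <- length(contact_idx) > 0L
  contact_s <- if (contact) tracks$t[contact_idx[1L]] else NA_real_

  d_mouth <- dist_to_point(paw_xy, ev$mouth_pos)
  near_mouth <- !ev$paw$masked & d_mouth <= r_contact
  mouth_cycles <- nrow(true_runs(near_mouth))

  has_reach <- nrow(ev$episodes) > 0L
  onset_s <- if (has_reach) ev$onset_s[1L] else NA_real_

  category <- if (type == "rewarded") {
    if (contact) {
      in_window <- near_mouth &
        tracks$t >= contact_s &
        tracks$t < contact_s + params$retrieval_window_s
      if (any(in_window)) "success" else "partial_fail"
    } else if (mouth_cycles >= params$groom_min_cycles) {
      "groom"
    } else if (has_reach) {
      "complete_fail"
    } else {
      "no_reach"
    }
  } else {
    if (has_reach || contact || mouth_cycles >= params$groom_min_cycles) {
      "unrewarded_reach"
    } else {
      "no_reach"
    }
  }
  structure(category, reach_onset_s = onset_s, contact_s = contact_s)
}

#' Detect an early (pre-reward) reach in a successful trial
#'
#' Early reaches — reaches initiated strictly before water delivery on a
#' rewarded trial — mark an event-sequence failure (impulsive reaching) even
#' when the trial is ultimately successful.
#'
#' @inheritParams reach_events
#' @return `TRUE` iff the first reach event onsets strictly before
#'   `timeline$reward_s`.
#' @export
detect_early_reach <- function(tracks, timeline, geometry,
                               params = classifier_params()) {
  if (is.na(timeline$reward_s)) {
    stop("early reaches are defined for rewarded trials only")
  }
  tracks <- truncate_trial(tracks, duration_s = 10)
  ev <- reach_events(tracks, timeline, geometry, params)
  length(ev$onset_s) > 0L && ev$onset_s[1L] < timeline$reward_s
}
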