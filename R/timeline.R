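#' Construct the timeline of a single water-reaching trial
#'
#' Trials start at camera onset (t = 0). A visual cue is presented at
#' `visual_cue_s` (default 2 s) and an auditory tone at `tone_s` (default
#' 6 s); on rewarded trials the water drop is delivered together with the
#' tone. Recording ends 4 s after a detected spout touch on rewarded trials,
#' otherwise 10 s after the tone, so rewarded trials span 10-16 s and
#' non-rewarded trials are always 16 s long.
#'
#' The capacitive touch sensor only shortens the recording; behavioral
#' scoring is done from pose, not from the sensor. A touch reported before
#' reward delivery is a sensor artifact and is rejected. A touch reported
#' after the no-touch timeout (`tone_s + 10`) cannot shorten a recording
#' that has already ceased and is likewise rejected; end time is capped at
#' `tone_s + 10`.
#'
#' @param type `"rewarded"` or `"nonrewarded"`.
#' @param touch_s spout-touch time in seconds, or `NA` if no touch was
#'   detected. Must be `NA` for non-rewarded trials.
#' @param visual_cue_s,tone_s,iti_s cue, tone and inter-trial-interval times
#'   in seconds.
#' @return A `trial_timeline` list with elements `type`, `visual_cue_s`,
#'   `tone_s`, `reward_s` (`NA` for non-rewarded trials), `touch_s`,
#'   `end_s` and `iti_s`.
#' @examples
#' build_timeline("nonrewarded")$end_s          # 16
#' build_timeline("rewarded", touch_s = 6)$end_s # 10
#' @export
build_timeline <- function(type = c("rewarded", "nonrewarded"), touch_s = NA_real_,
                           visual_cue_s = 2, tone_s = 6, iti_s = 4) {
  type <- match.arg(type)
  if (!(is.numeric(visual_cue_s) && is.numeric(tone_s) && visual_cue_s < tone_s)) {
    stop("invalid timeline: visual_cue_s must precede tone_s")
  }
  timeout_s <- tone_s + 10
  if (!is.na(touch_s)) {
    if (type == "nonrewarded") {
      stop("touch_s must be absent for nonrewarded trials (no water is present)")
    }
    if (touch_s < tone_s) {
      stop(sprintf(
        "touch_s = %g precedes reward delivery at %g s; a touch before reward is a sensor artifact",
        touch_s, tone_s))
    }
    if (touch_s >= timeout_s) {
      stop(sprintf("touch_s = %g is at or after the no-touch timeout (%g s)",
                   touch_s, timeout_s))
    }
    end_s <- min(touch_s + 4, timeout_s)
  } else {
    end_s <- timeout_s
  }
  structure(
    list(
      type = type,
      visual_cue_s = visual_cue_s,
      tone_s = tone_s,
      reward_s = if (type == "rewarded") tone_s else NA_real_,
      touch_s = touch_s,
      end_s = end_s,
      iti_s = iti_s
    ),
    class = "trial_timeline"
  )
}

#' Truncate a trial-aligned stream to the common analysis window
#'
#' All trials, whatever their recorded length, are analyzed over their first
#' 10 s. The stream may be a numeric vector, a matrix with time in rows, or a
#' `pose_tracks` object; it must cover at least the full window.
#'
#' @param stream trial-aligned signal sampled at `rate` Hz from t = 0.
#' @param rate sampling rate in Hz. Ignored (taken from the object) for
#'   `pose_tracks` input.
#' @param duration_s analysis window length in seconds (default 10).
#' @return The stream restricted to `[0, duration_s)`.
#' @export
truncate_trial <- function(stream, rate = 60, duration_s = 10) {
  if (inherits(stream, "pose_tracks")) {
    n_req <- as.integer(round(stream$rate * duration_s))
    n <- length(stream$t)
    if (n < n_req) {
      stop(sprintf("stream is %.3f s long; %.0f s required for truncation",
                   n / stream$rate, duration_s))
    }
    stream$t <- stream$t[seq_len(n_req)]
    stream$keypoints <- lapply(stream$keypoints, function(kp) {
      lapply(kp, function(v) v[seq_len(n_req)])
    })
    return(stream)
  }
  if (inherits(stream, "roi_trace")) {
    rate <- attr(stream, "rate")
    n_req <- as.integer(round(rate * duration_s))
    if (length(stream) < n_req) {
      stop(sprintf("stream is %.3f s long; %.0f s required for truncation",
                   length(stream) / rate, duration_s))
    }
    at <- attributes(stream)
    out <- unclass(stream)[seq_len(n_req)]
    attributes(out) <- at
    return(out)
  }
  n_req <- as.integer(round(rate * duration_s))
  n <- if (is.matrix(stream)) nrow(stream) else length(stream)
  if (n < n_req) {
    stop(sprintf("stream is %.3f s long; %.0f s required for truncation",
                 n / rate, duration_s))
  }
  if (is.matrix(stream)) stream[seq_len(n_req), , drop = FALSE]
  else stream[seq_len(n_req)]
}
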