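# Synthetic reach trajectories.
#
# Trajectories are rendered from keyframe scripts (time, position, optional
# target arc length for the segment ending at that keyframe). Segments with
# a target arc length are drawn as a straight base path plus a transverse
# sinusoid whose amplitude is solved so that the *discrete* frame-to-frame
# polyline length matches the target, which is what the kinematics module
# measures.

# Straight or zigzag polyline from `from` to `to` over n_steps frames whose
# discrete arc length equals L_target (when feasible; L_target = NA or
# <= chord gives the straight constant-speed path).
zigzag_path <- function(from, to, n_steps, L_target = NA) {
  s <- seq(0, 1, length.out = n_steps + 1L)
  base <- cbind(from[1L] + s * (to[1L] - from[1L]),
                from[2L] + s * (to[2L] - from[2L]))
  chord <- sqrt(sum((to - from)^2))
  if (is.na(L_target) || L_target <= chord * (1 + 1e-9) || n_steps < 4L) {
    return(base)
  }
  dvec <- (to - from) / chord
  nvec <- c(-dvec[2L], dvec[1L])
  # three rectified transverse lobes, all on the -normal side: for the
  # platform-to-spout reach this swings the paw away from the mouth, so the
  # extra path never fakes a grasp-to-drink (mouth-contact) event
  off <- -abs(sin(3 * pi * s))
  plen <- function(a) {
    p <- base + (a * off) %o% nvec
    sum(sqrt(rowSums(diff(p)^2)))
  }
  a_hi <- chord
  while (plen(a_hi) < L_target && a_hi < 100 * chord) a_hi <- a_hi * 2
  a <- stats::uniroot(function(a) plen(a) - L_target, c(0, a_hi),
                      tol = 1e-10)$root
  base + (a * off) %o% nvec
}

# Render a keyframe script into an n x 2 position matrix at `rate` Hz.
# script: data.frame with t (s), x, y, L (target arc length of the segment
# ending at this keyframe; NA = straight).
render_script <- function(script, n, rate) {
  stopifnot(nrow(script) >= 1L)
  f <- pmax(1L, pmin(n, as.integer(round(script$t * rate)) + 1L))
  pos <- matrix(NA_real_, n, 2L)
  pos[seq_len(f[1L]), 1L] <- script$x[1L]
  pos[seq_len(f[1L]), 2L] <- script$y[1L]
  if (nrow(script) > 1L) {
    for (k in 2:nrow(script)) {
      i0 <- f[k - 1L]; i1 <- f[k]
      if (i1 <= i0) {
        pos[i1, ] <- c(script$x[k], script$y[k])
        next
      }
      pos[i0:i1, ] <- zigzag_path(c(script$x[k - 1L], script$y[k - 1L]),
                                  c(script$x[k], script$y[k]),
                                  i1 - i0, script$L[k])
    }
  }
  last <- f[nrow(script)]
  if (last < n) {
    pos[(last + 1L):n, 1L] <- script$x[nrow(script)]
    pos[(last + 1L):n, 2L] <- script$y[nrow(script)]
  }
  pos
}

key <- function(t, pos, L = NA_real_) {
  data.frame(t = t, x = pos[[1L]], y = pos[[2L]], L = L)
}

#' Simulate the pose tracks of one trial
#'
#' Builds a left-paw trajectory realizing the requested behavioral category
#' — rest on the platform, lift, spout approach, grasp and mouth return for
#' a success; the corresponding truncated variants for the failure modes —
#' plus static landmark keypoints, tracking jitter and low-confidence
#' dropout bursts. For spout-contact categories the discrete path length
#' over the reward-to-+1.1-s window equals `target_length` spout distances
#' (up to tracking jitter): the paw is still from reward delivery until the
#' reach onset, travels a transverse-sinusoid path whose polyline length is
#' solved to the target, then holds at the spout past the window end.
#'
#' Uses the current RNG state; seed before calling for reproducibility.
#'
#' @param category behavioral category to realize (`success`,
#'   `partial_fail`, `complete_fail`, `groom`, `no_reach`,
#'   `unrewarded_reach`).
#' @param config a [synth_config()].
#' @param timeline the trial's [build_timeline()] result.
#' @param target_length path-length target in spout-distance multiples;
#'   required (>= 1) for spout-contact categories.
#' @param early_reach also insert a pre-reward lift (successful trials).
#' @param contact_s spout-contact time in seconds (defaults to the
#'   timeline's `touch_s`; required for contact categories).
#' @param style for `unrewarded_reach`: `"reach"` (spout contact) or
#'   `"groom"` (paw-mouth cycles).
#' @return A `pose_tracks` object with attributes `reach_onset_s`,
#'   `contact_s` and `category`.
#' @export
simulate_trajectory <- function(category, config, timeline,
                                target_length = NA_real_, early_reach = FALSE,
                                contact_s = NA_real_,
                                style = c("reach", "groom")) {
  style <- match.arg(style)
  layout <- synth_layout(config)
  rate <- config$frame_rate_behavior
  n <- as.integer(round(timeline$end_s * rate))
  D <- config$spout_distance_px
  rest <- unname(layout$platform)
  spout <- unname(layout$spout)
  mouth <- unname(layout$mouth)
  contact_cats <- c("success", "partial_fail")
  if (category %in% contact_cats ||
      (category == "unrewarded_reach" && style == "reach")) {
    if (is.na(target_length) || target_length < 1) {
      stop("spout-contact categories require target_length >= 1 spout distance")
    }
  }
  reward <- if (!is.na(timeline$reward_s)) timeline$reward_s else timeline$tone_s
  onset <- NA_real_
  contact <- NA_real_

  script <- switch(
    category,
    no_reach = key(0, rest),
    success = ,
    partial_fail = {
      onset <- reward + stats::runif(1, 0.03, 0.08)
      contact <- if (!is.na(contact_s)) contact_s else
        if (!is.na(timeline$touch_s)) timeline$touch_s else
          reward + min(1.07, max(0.9, stats::rnorm(1, 1.0, 0.03)))
      sc <- key(0, rest)
      if (early_reach && category == "success") {
        t_e <- stats::runif(1, 3, 5.3)
        bump <- rest + 0.45 * (spout - rest)
        sc <- rbind(sc, key(t_e, rest), key(t_e + 0.25, bump),
                    key(t_e + 0.35, bump), key(t_e + 0.6, rest))
      }
      sc <- rbind(sc, key(onset, rest),
                  key(contact, spout, L = target_length * D),
                  key(reward + 1.15, spout))
      if (category == "success") {
        rbind(sc, key(reward + 1.45, mouth), key(reward + 2.25, mouth),
              key(reward + 2.65, rest))
      } else {
        rbind(sc, key(reward + 1.55, rest))
      }
    },
    complete_fail = {
      onset <- reward + stats::runif(1, 0.05, 0.3)
      apex <- rest + 0.6 * (spout - rest)
      rbind(key(0, rest), key(onset, rest), key(onset + 0.5, apex),
            key(onset + 0.7, apex), key(onset + 1.2, rest))
    },
    groom = {
      onset <- stats::runif(1, 2.5, 4)
      groom_script(onset, rest, mouth, cycles = 4L)
    },
    unrewarded_reach = {
      if (style == "reach") {
        onset <- stats::runif(1, 1, 7)
        contact <- onset + 1.0
        rbind(key(0, rest), key(onset, rest),
              key(contact, spout, L = target_length * D),
              key(contact + 0.15, spout), key(contact + 0.55, rest))
      } else {
        onset <- stats::runif(1, 1, 5.5)
        groom_script(onset, rest, mouth, cycles = 4L)
      }
    },
    stop("unknown category: ", category)
  )

  paw <- render_script(script, n, rate)
  keypoints <- list(
    left_paw = jittered_keypoint(paw, config),
    right_paw = jittered_keypoint(layout$right_paw, config, n),
    mouth = jittered_keypoint(mouth, config, n),
    platform = jittered_keypoint(layout$platform, config, n),
    spout = jittered_keypoint(spout, config, n)
  )
  tr <- pose_tracks(keypoints, rate = rate)
  attr(tr, "reach_onset_s") <- onset
  attr(tr, "contact_s") <- contact
  attr(tr, "category") <- category
  tr
}

groom_script <- function(onset, rest, mouth, cycles = 4L,
                         up = 0.35, hold = 0.1, down = 0.35, pause = 0.1) {
  sc <- key(0, rest)
  t <- onset
  for (k in seq_len(cycles)) {
    sc <- rbind(sc, key(t, rest), key(t + up, mouth),
                key(t + up + hold, mouth), key(t + up + hold + down, rest))
    t <- t + up + hold + down + pause
  }
  sc
}

# Tracking jitter + low-confidence dropout bursts for one keypoint.
# `pos` is an n x 2 matrix or a length-2 constant position.
jittered_keypoint <- function(pos, config, n = NULL) {
  if (is.null(dim(pos))) {
    pos <- matrix(rep(unname(pos), each = n), ncol = 2L)
  }
  n <- nrow(pos)
  sd <- config$pose_noise_px
  x <- pos[, 1L] + stats::rnorm(n, 0, sd)
  y <- pos[, 2L] + stats::rnorm(n, 0, sd)
  conf <- stats::runif(n, 0.95, 1)
  if (config$dropout_fraction > 0) {
    mean_len <- 2.25
    n_bursts <- stats::rbinom(1L, n, config$dropout_fraction / mean_len)
    if (n_bursts > 0) {
      starts <- sample.int(n, n_bursts)
      lens <- sample(1:4, n_bursts, replace = TRUE,
                     prob = c(0.3, 0.3, 0.25, 0.15))
      for (k in seq_len(n_bursts)) {
        idx <- starts[k]:min(n, starts[k] + lens[k] - 1L)
        conf[idx] <- stats::runif(length(idx), 0.05, 0.45)
        x[idx] <- x[idx] + stats::rnorm(length(idx), 0, 8)
        y[idx] <- y[idx] + stats::rnorm(length(idx), 0, 8)
      }
    }
  }
  list(x = x, y = y, confidence = conf)
}
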