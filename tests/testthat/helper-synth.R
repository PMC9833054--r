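# Shared fixture builders. All fixtures are generated in code; tests that
# need randomness seed explicitly.

# Pose tracks with a scripted left paw and static landmarks (no jitter).
# paw_xy: n x 2 matrix; remaining keypoints are constants.
make_tracks <- function(paw_xy, rate = 60,
                        platform = c(75, 100), spout = c(75, 60),
                        mouth = c(82, 52), conf = NULL) {
  n <- nrow(paw_xy)
  if (is.null(conf)) conf <- rep(1, n)
  still <- function(p) list(x = rep(p[1], n), y = rep(p[2], n),
                            confidence = rep(1, n))
  pose_tracks(list(
    left_paw = list(x = paw_xy[, 1], y = paw_xy[, 2], confidence = conf),
    right_paw = still(c(87, 100)),
    mouth = still(mouth),
    platform = still(platform),
    spout = still(spout)
  ), rate = rate)
}

# A paw that rests on the platform for `secs` seconds.
resting_paw <- function(secs = 16, rate = 60, at = c(75, 100)) {
  n <- round(secs * rate)
  cbind(rep(at[1], n), rep(at[2], n))
}

# Noise-free simulator config for ground-truth recovery tests.
noise_free_config <- function(...) {
  synth_config(pose_noise_px = 0, dropout_fraction = 0, noise_sd = 0,
               hemodynamic_gain_fluo = 0, hemodynamic_gain_reflect = 0, ...)
}

# Classify every trial of a session against its ground truth; returns the
# fraction of agreement.
session_agreement <- function(session) {
  n <- nrow(session$log)
  ok <- logical(n)
  for (i in seq_len(n)) {
    geom <- spout_distance(session$tracks[[i]])
    got <- as.character(classify_trial(session$tracks[[i]], session$log$type[i],
                                       session$timelines[[i]], geom))
    ok[i] <- got == session$ground_truth$true_category[i]
  }
  mean(ok)
}
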