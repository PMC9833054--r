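# Rule-cascade classification on constructed and simulated trials.

timeline_rew <- build_timeline("rewarded", touch_s = 7)
timeline_non <- build_timeline("nonrewarded")

# Constructed success trajectory: rest, reach at 6.05-7.0 s, spout hold,
# mouth at ~7.4 s, return.
success_paw <- function(rate = 60) {
  n <- round(11 * rate)
  paw <- resting_paw(11, rate)
  reach <- round(6.05 * rate):round(7 * rate)
  s <- seq(0, 1, length.out = length(reach))
  paw[reach, 1] <- 75
  paw[reach, 2] <- 100 - 40 * s
  hold <- round(7 * rate):round(7.3 * rate)
  paw[hold, ] <- rep(c(75, 60), each = length(hold))
  tomouth <- round(7.3 * rate):round(7.6 * rate)
  s2 <- seq(0, 1, length.out = length(tomouth))
  paw[tomouth, 1] <- 75 + 7 * s2
  paw[tomouth, 2] <- 60 - 8 * s2
  back <- round(7.6 * rate):round(8.2 * rate)
  s3 <- seq(0, 1, length.out = length(back))
  paw[back, 1] <- 82 - 7 * s3
  paw[back, 2] <- 52 + 48 * s3
  paw
}

test_that("constructed trials map to the expected categories", {
  geom <- spout_distance(make_tracks(resting_paw(16)))
  expect_identical(
    as.character(classify_trial(make_tracks(resting_paw(16)), "rewarded",
                                timeline_rew, geom)),
    "no_reach")
  expect_identical(
    as.character(classify_trial(make_tracks(success_paw()), "rewarded",
                                timeline_rew, geom)),
    "success")
  # partial fail: same reach, but straight back to the platform after contact
  paw <- success_paw()
  back <- round(7.3 * 60):round(8 * 60)
  s <- seq(0, 1, length.out = length(back))
  paw[back, 1] <- 75
  paw[back, 2] <- 60 + 40 * s
  paw[round(8 * 60):nrow(paw), ] <- rep(c(75, 100), each = length(round(8 * 60):nrow(paw)))
  expect_identical(
    as.character(classify_trial(make_tracks(paw), "rewarded", timeline_rew, geom)),
    "partial_fail")
  # complete fail: lift to 60% of spout distance, never contacting
  paw <- resting_paw(16)
  lift <- round(6.2 * 60):round(7.4 * 60)
  s <- seq(0, 1, length.out = length(lift))
  paw[lift, 2] <- 100 - 24 * pmin(s, 1 - s) * 2
  expect_identical(
    as.character(classify_trial(make_tracks(paw), "rewarded",
                                build_timeline("rewarded"), geom)),
    "complete_fail")
  # nonrewarded trial with a mid-trial reach
  paw <- resting_paw(16)
  lift <- round(3 * 60):round(4 * 60)
  s <- seq(0, 1, length.out = length(lift))
  paw[lift, 2] <- 100 - 40 * pmin(s, 1 - s) * 2
  expect_identical(
    as.character(classify_trial(make_tracks(paw), "nonrewarded",
                                timeline_non, geom)),
    "unrewarded_reach")
})

test_that("unscorable trials (mostly low confidence) are disregarded", {
  n <- round(16 * 60)
  conf <- rep(0.1, n)
  conf[1:200] <- 1
  tr <- make_tracks(resting_paw(16), conf = conf)
  geom <- spout_distance(tr)
  got <- classify_trial(tr, "rewarded", timeline_rew, geom)
  expect_identical(as.character(got), "disregard")
  expect_match(attr(got, "reason"), "left_paw")
})

test_that("short low-confidence gaps are interpolated, long gaps masked", {
  n <- 300
  paw <- cbind(seq(0, 30, length.out = n), rep(100, n))
  conf <- rep(1, n)
  conf[50:53] <- 0.2      # 4-frame gap: interpolate
  conf[100:120] <- 0.2    # 21-frame gap: mask
  tr <- make_tracks(paw, conf = conf)
  cl <- clean_keypoint(tr, "left_paw")
  expect_false(any(cl$masked[50:53]))
  expect_equal(cl$x[50:53], paw[50:53, 1], tolerance = 1e-12)
  expect_true(all(cl$masked[100:120]))
  expect_true(all(is.na(cl$x[100:120])))
})

test_that("early reaches are flagged only for pre-reward onsets", {
  geom <- spout_distance(make_tracks(resting_paw(16)))
  expect_false(detect_early_reach(make_tracks(success_paw()),
                                  timeline_rew, geom))
  paw <- success_paw()
  bump <- round(4 * 60):round(4.5 * 60)
  s <- seq(0, 1, length.out = length(bump))
  paw[bump, 2] <- 100 - 18 * pmin(s, 1 - s) * 2
  expect_true(detect_early_reach(make_tracks(paw), timeline_rew, geom))
  expect_error(detect_early_reach(make_tracks(resting_paw(16)),
                                  timeline_non, geom),
               "rewarded trials only")
})

test_that("classifier recovers ground truth across all categories", {
  cfg <- noise_free_config(
    n_trials = 60, seed = 5,
    category_probabilities = c(success = 0.2, partial_fail = 0.2,
                               complete_fail = 0.2, no_reach = 0.2,
                               groom = 0.2),
    unrewarded_reach_probability = 0.7)
  s <- generate_session(cfg)
  expect_gte(session_agreement(s), 0.99)
  expect_setequal(
    unique(s$ground_truth$true_category[s$log$type == "nonrewarded"]),
    c("no_reach", "unrewarded_reach"))
})

test_that("performance fractions exclude disregards and sum to one", {
  records <- data.frame(
    day = 1,
    type = c(rep("rewarded", 10), rep("nonrewarded", 4)),
    category = c(rep("success", 9), "partial_fail",
                 "unrewarded_reach", "no_reach", "no_reach", "disregard"),
    early_reach = c(rep(FALSE, 9), rep(NA, 5)))
  out <- summarize_performance(records)
  expect_equal(out$success, 0.9)
  expect_equal(out$partial_fail, 0.1)
  expect_equal(out$unrewarded_reach, 1 / 3)
  expect_equal(out$n_nonrewarded, 3)
  expect_equal(out$success + out$partial_fail + out$complete_fail +
                 out$no_reach + out$groom, 1, tolerance = 1e-9)
  # degenerate day: everything disregarded
  rec2 <- data.frame(day = 2, type = "rewarded", category = "disregard",
                     early_reach = NA)
  out2 <- summarize_performance(rec2)
  expect_true(out2$empty)
  expect_true(is.na(out2$success))
  expect_error(summarize_performance(
    data.frame(day = 1, type = "nonrewarded", category = "groom")),
    "illegal category")
})

test_that("category fractions sum to one for every simulated day", {
  recs <- do.call(rbind, lapply(1:3, function(day) {
    s <- generate_session(synth_config(n_trials = 30, seed = 100 + day))
    data.frame(day = day, type = s$log$type,
               category = s$ground_truth$true_category,
               early_reach = s$ground_truth$early_reach)
  }))
  out <- summarize_performance(recs)
  sums <- out$success + out$partial_fail + out$complete_fail +
    out$no_reach + out$groom
  expect_true(all(abs(sums - 1) < 1e-9))
})
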