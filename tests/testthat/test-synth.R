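# Synthetic-session generator: structure, determinism, channel separation,
# path-length realization.

test_that("config invariants are enforced with the offending field named", {
  expect_error(synth_config(n_trials = 5), "n_trials")
  expect_error(synth_config(category_probabilities = c(
    success = 0.5, partial_fail = 0.5, complete_fail = 0.2,
    no_reach = 0, groom = 0)), "category_probabilities")
  expect_error(synth_config(early_reach_probability = 1.2),
               "early_reach_probability")
  expect_error(synth_config(trajectory_length_sd = -1),
               "trajectory_length_sd")
  expect_error(synth_config(trajectory_length_mean = 0.5),
               "trajectory_length_mean")
})

test_that("trial types strictly alternate starting rewarded", {
  s <- generate_session(synth_config(n_trials = 8, seed = 1))
  expect_equal(s$log$type, rep(c("rewarded", "nonrewarded"), 4))
  expect_equal(s$log$trial_index, 1:8)
})

test_that("identical config and seed give bit-identical sessions", {
  cfg <- synth_config(n_trials = 6, seed = 123, image_shape = c(32, 32))
  a <- generate_session(cfg, imaging = TRUE, imaging_trials = 1)
  b <- generate_session(cfg, imaging = TRUE, imaging_trials = 1)
  expect_identical(a$log, b$log)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$stacks, b$stacks)
})

test_that("degenerate samplers honor their probabilities", {
  cfg <- synth_config(n_trials = 40, seed = 2, category_probabilities = c(
    success = 1, partial_fail = 0, complete_fail = 0, no_reach = 0,
    groom = 0))
  s <- generate_session(cfg)
  rew <- s$ground_truth[s$ground_truth$type == "rewarded", ]
  expect_true(all(rew$true_category == "success"))
})

test_that("ground truth records latents iff the trial involves a reach", {
  s <- generate_session(synth_config(
    n_trials = 60, seed = 31,
    category_probabilities = c(success = 0.3, partial_fail = 0.2,
                               complete_fail = 0.2, no_reach = 0.2,
                               groom = 0.1),
    unrewarded_reach_probability = 0.5))
  gt <- s$ground_truth
  moving <- gt$true_category != "no_reach"
  expect_true(all(!is.na(gt$reach_onset_s[moving])))
  expect_true(all(is.na(gt$reach_onset_s[!moving])))
  contact <- gt$true_category %in% c("success", "partial_fail")
  expect_true(all(gt$true_path_length[contact] >= 1))
})

test_that("realized window path length matches the target within 2 percent", {
  lengths_checked <- 0
  for (seed in 1:3) {
    s <- generate_session(noise_free_config(
      n_trials = 140, seed = seed,
      category_probabilities = c(success = 0.7, partial_fail = 0.3,
                                 complete_fail = 0, no_reach = 0, groom = 0)))
    idx <- which(s$ground_truth$true_category %in% c("success", "partial_fail"))
    for (i in idx) {
      g <- spout_distance(s$tracks[[i]])
      got <- as.numeric(path_length(s$tracks[[i]], s$timelines[[i]], g))
      expect_lt(abs(got - s$ground_truth$true_path_length[i]) /
                  s$ground_truth$true_path_length[i], 0.02)
      lengths_checked <- lengths_checked + 1
    }
  }
  expect_gte(lengths_checked, 200)
})

test_that("trajectory rejects sub-unit targets for contact categories", {
  cfg <- synth_config(n_trials = 2, seed = 1)
  tl <- build_timeline("rewarded", touch_s = 7)
  expect_error(simulate_trajectory("success", cfg, tl, target_length = 0.8),
               "target_length")
})

test_that("a 16-s trial yields 1920 interleaved frames, 960 per channel", {
  cfg <- synth_config(n_trials = 2, seed = 6, image_shape = c(32, 32))
  tl <- build_timeline("nonrewarded")
  st <- simulate_widefield_trial("no_reach", NA, default_atlas(c(32, 32)),
                                 cfg, tl$end_s)
  expect_equal(nrow(st$frames), 1920)
  ch <- demultiplex(st)
  expect_equal(nrow(ch$fluorescence$values), 960)
  expect_equal(nrow(ch$reflectance$values), 960)
})

test_that("neural transients appear only in the fluorescence channel", {
  cfg <- noise_free_config(n_trials = 2, seed = 7, image_shape = c(64, 64),
                           roi_peak_amplitudes = c(M1_contra = 5))
  atlas <- default_atlas(c(64, 64))
  st <- simulate_widefield_trial("success", 6.05, atlas, cfg, 11)
  ch <- demultiplex(st)
  fd <- compute_dff(ch$fluorescence, c(0, 6))
  rd <- compute_dff(ch$reflectance, c(0, 6))
  # with zero gains and zero noise, reflectance dF/F is identically zero
  expect_true(all(rd$values == 0))
  tr <- extract_trace(fd, atlas, "M1_contra")
  expect_equal(max(tr), 5, tolerance = 0.1)
  # equal nonzero gains: artifact enters both, subtraction recovers neural
  cfg2 <- synth_config(n_trials = 2, seed = 8, image_shape = c(64, 64),
                       noise_sd = 0, roi_peak_amplitudes = c(M1_contra = 5))
  st2 <- simulate_widefield_trial("success", 6.05, atlas, cfg2, 11)
  ch2 <- demultiplex(st2)
  fd2 <- compute_dff(ch2$fluorescence, c(0, 6))
  rd2 <- compute_dff(ch2$reflectance, c(0, 6))
  expect_gt(max(abs(rd2$values)), 1)    # artifact is present in reflectance
  corr <- hemodynamic_correct(fd2, rd2)
  tr2 <- extract_trace(corr, atlas, "M1_contra")
  pk <- peak_amplitude(truncate_trial(tr2),
                       build_timeline("rewarded", touch_s = 7), "success")
  expect_equal(pk$amplitude, 5, tolerance = 0.15)
})

test_that("unknown ROI names in the config are rejected with their names", {
  cfg <- synth_config(n_trials = 2, seed = 9, image_shape = c(32, 32),
                      roi_peak_amplitudes = c(M1_contra = 5, bogus_roi = 2))
  expect_error(
    simulate_widefield_trial("success", 6.05, default_atlas(c(32, 32)),
                             cfg, 11),
    "bogus_roi")
})
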