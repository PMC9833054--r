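# Spout geometry, path length, binning, hierarchical statistics, lift trace.

test_that("spout distance is the platform-to-spout height difference", {
  tr <- make_tracks(resting_paw(10), platform = c(75, 100), spout = c(75, 60))
  g <- spout_distance(tr)
  expect_equal(g$spout_distance_px, 40)
  expect_equal(g$platform_y, 100)
  # jittered landmarks: median within 1 px of the clean value
  set.seed(21)
  tr2 <- make_tracks(resting_paw(10))
  n <- length(tr2$t)
  tr2$keypoints$platform$y <- 100 + runif(n, -1, 1)
  tr2$keypoints$spout$y <- 60 + runif(n, -1, 1)
  expect_lt(abs(spout_distance(tr2)$spout_distance_px - 40), 1)
  # degenerate: coincident heights
  tr3 <- make_tracks(resting_paw(10), spout = c(75, 100))
  expect_error(spout_distance(tr3), "degenerate")
  # not enough confident landmark frames
  tr4 <- make_tracks(resting_paw(10))
  tr4$keypoints$spout$confidence <- rep(0.1, n)
  expect_error(spout_distance(tr4), "confident frames")
})

test_that("path length matches brute-force segment summation", {
  timeline <- build_timeline("rewarded", touch_s = 7)
  # stationary paw
  g <- spout_distance(make_tracks(resting_paw(11)))
  expect_equal(as.numeric(path_length(make_tracks(resting_paw(11)),
                                      timeline, g)), 0)
  # straight vertical lift of exactly one spout distance inside the window
  paw <- resting_paw(11)
  idx <- frame_window(6, 7.1, 60)
  s <- seq(0, 1, length.out = length(idx))
  paw[idx, 2] <- 100 - 40 * s
  paw[max(idx):nrow(paw), 2] <- 60
  expect_equal(as.numeric(path_length(make_tracks(paw), timeline, g)), 1,
               tolerance = 1e-12)
  # random tracks against an independent per-segment oracle
  set.seed(33)
  for (k in 1:20) {
    paw <- resting_paw(11)
    idx2 <- frame_window(6, 7.1, 60, nrow(paw))
    paw[idx2, 1] <- cumsum(rnorm(length(idx2), 0, 2)) + 75
    paw[idx2, 2] <- cumsum(rnorm(length(idx2), 0, 2)) + 100
    got <- as.numeric(path_length(make_tracks(paw), timeline, g))
    oracle <- 0
    for (i in idx2[-1]) {
      oracle <- oracle + sqrt((paw[i, 1] - paw[i - 1, 1])^2 +
                                (paw[i, 2] - paw[i - 1, 2])^2)
    }
    expect_equal(got, oracle / 40, tolerance = 1e-9)
  }
})

test_that("path length is translation invariant and zoom-normalized", {
  timeline <- build_timeline("rewarded", touch_s = 7)
  set.seed(44)
  paw <- resting_paw(11)
  idx <- frame_window(6, 7.1, 60, nrow(paw))
  paw[idx, 1] <- 75 + cumsum(rnorm(length(idx)))
  paw[idx, 2] <- 100 - seq(0, 40, length.out = length(idx))
  base_tr <- make_tracks(paw)
  g <- spout_distance(base_tr)
  base <- as.numeric(path_length(base_tr, timeline, g))
  # translate everything by (+17, -9): unchanged
  tr_shift <- make_tracks(cbind(paw[, 1] + 17, paw[, 2] - 9),
                          platform = c(92, 91), spout = c(92, 51),
                          mouth = c(99, 43))
  expect_equal(as.numeric(path_length(tr_shift, timeline,
                                      spout_distance(tr_shift))),
               base, tolerance = 1e-12)
  # uniform 2x zoom: spout-distance normalization cancels
  tr_zoom <- make_tracks(paw * 2, platform = c(150, 200),
                         spout = c(150, 120), mouth = c(164, 104))
  expect_equal(as.numeric(path_length(tr_zoom, timeline,
                                      spout_distance(tr_zoom))),
               base, tolerance = 1e-12)
  # triangle inequality: path >= net displacement / spout distance
  net <- sqrt(sum((paw[max(idx), ] - paw[idx[1], ])^2)) / 40
  expect_gte(base, net - 1e-12)
})

test_that("long masked gaps inside the window flag the trial", {
  timeline <- build_timeline("rewarded", touch_s = 7)
  paw <- resting_paw(11)
  conf <- rep(1, nrow(paw))
  conf[380:400] <- 0.1     # 21-frame gap inside [6, 7.1)
  tr <- make_tracks(paw, conf = conf)
  g <- spout_distance(tr)
  res <- path_length(tr, timeline, g)
  expect_true(attr(res, "flagged"))
  # window not covered at all
  expect_error(path_length(make_tracks(resting_paw(6.5)), timeline, g),
               "window")
})

test_that("distance bins are [k, k+1) with percentages summing to 100", {
  h <- bin_distances(c(4.0, 4.2, 4.9))
  expect_equal(h$rel_freq_pct[h$bin == 4], 100)
  expect_equal(sum(h$rel_freq_pct), 100, tolerance = 1e-6)
  expect_equal(nrow(bin_distances(numeric(0))), 0)
  # exhaustive and exclusive assignment
  set.seed(55)
  x <- abs(rnorm(500, 2.1, 0.6))
  h2 <- bin_distances(x)
  expect_equal(sum(h2$rel_freq_pct), 100, tolerance = 1e-6)
  expect_true(all(unique(floor(x)) %in% h2$bin))
  expect_equal(h2$rel_freq_pct, 100 * tabulate(floor(x) + 1,
                                               max(floor(x)) + 1) / 500)
  # truncated-normal masses in bins 1-3 match the analytic CDF within 3%
  set.seed(56)
  draws <- rnorm(20000, 2.1, 0.6)
  draws <- draws[draws >= 0][1:1000]
  h3 <- bin_distances(draws)
  z <- pnorm(0, 2.1, 0.6, lower.tail = FALSE)
  for (k in 1:3) {
    analytic <- 100 * (pnorm(k + 1, 2.1, 0.6) - pnorm(k, 2.1, 0.6)) / z
    expect_lt(abs(h3$rel_freq_pct[h3$bin == k] - analytic), 3)
  }
})

test_that("statistics aggregate per mouse first, then per genotype", {
  one <- data.frame(genotype = "WT", mouse = "m1", length = c(1, 3))
  st <- trajectory_stats(one)
  expect_equal(st$per_mouse$mean, 2)
  expect_equal(st$per_mouse$sd, sqrt(2))
  # unequal trial counts cannot tilt the genotype mean
  two <- data.frame(
    genotype = "WT",
    mouse = rep(c("m1", "m2"), c(30, 2)),
    length = c(rep(2, 30), rep(4, 2)))
  expect_equal(trajectory_stats(two)$per_genotype$mean, 3)
})

test_that("simulated cohort recovers the configured trajectory mean", {
  lengths <- do.call(rbind, lapply(1:6, function(m) {
    s <- generate_session(noise_free_config(
      n_trials = 100, seed = 700 + m,
      category_probabilities = c(success = 1, partial_fail = 0,
                                 complete_fail = 0, no_reach = 0, groom = 0)))
    idx <- which(s$ground_truth$true_category == "success")
    vals <- vapply(idx, function(i) {
      g <- spout_distance(s$tracks[[i]])
      as.numeric(path_length(s$tracks[[i]], s$timelines[[i]], g))
    }, numeric(1))
    data.frame(genotype = "WT", mouse = sprintf("m%d", m), length = vals)
  }))
  st <- trajectory_stats(lengths)
  # mean of Normal(2.1, 0.6) truncated to [1, 4.5] is 2.146
  target <- 2.1 + 0.6 * (dnorm(-11 / 6) - dnorm(4)) /
    (pnorm(4) - pnorm(-11 / 6))
  expect_lt(abs(st$per_genotype$mean - target), 3 * st$per_genotype$sem + 0.02)
})

test_that("lift trace is platform-referenced and peaks in the reach window", {
  g <- spout_distance(make_tracks(resting_paw(16)))
  expect_true(all(abs(lift_trace(make_tracks(resting_paw(16)), g)) < 1e-9))
  s <- generate_session(noise_free_config(
    n_trials = 2, seed = 77,
    category_probabilities = c(success = 1, partial_fail = 0,
                               complete_fail = 0, no_reach = 0, groom = 0)))
  tr <- s$tracks[[1]]
  lt <- lift_trace(tr, spout_distance(tr))
  peak_t <- (which.max(lt) - 1) / 60
  expect_gte(peak_t, 6)
  expect_lt(peak_t, 7.1)
})
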