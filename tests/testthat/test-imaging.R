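# Demultiplexing, dF/F, hemodynamic correction, ROI traces, peaks, area.

# Small raw movie builder: T x P counts around a flat baseline.
flat_movie <- function(T, h = 8, w = 8, level = 1000, rate = 60) {
  mesoreach:::channel_movie(matrix(level, T, h * w), h, w, rate, "fluorescence")
}

test_that("demultiplexing splits channels and drops unpaired frames", {
  frames <- matrix(rep(c(1000L, 2000L), 960), ncol = 1)[, rep(1, 4)]
  st <- strobed_stack(frames, h = 2, w = 2)
  ch <- demultiplex(st)
  expect_equal(nrow(ch$fluorescence$values), 960)
  expect_equal(nrow(ch$reflectance$values), 960)
  expect_equal(ch$fluorescence$rate, 60)
  expect_true(all(ch$fluorescence$values == 1000))
  expect_true(all(ch$reflectance$values == 2000))
  st_odd <- strobed_stack(rbind(frames, frames[1, ]), h = 2, w = 2)
  expect_warning(ch2 <- demultiplex(st_odd), "unpaired")
  expect_equal(nrow(ch2$fluorescence$values), 960)
  expect_error(demultiplex(strobed_stack(frames[1, , drop = FALSE],
                                         h = 2, w = 2)),
               "at least 2 frames")
})

test_that("dF/F is zero for constant input and exact for known steps", {
  mv <- flat_movie(660)
  dff <- compute_dff(mv, c(0, 6))
  expect_true(all(dff$values == 0))
  mv$values[400, 5] <- 1050
  dff2 <- compute_dff(mv, c(0, 6))
  expect_equal(dff2$values[400, 5], 5, tolerance = 1e-9)
  # per-pixel baseline mean of dF/F is 0 over its own window
  set.seed(8)
  mv3 <- flat_movie(660)
  mv3$values <- mv3$values + matrix(rnorm(length(mv3$values), 0, 5), 660)
  dff3 <- compute_dff(mv3, c(0, 6))
  idx <- frame_window(0, 6, 60)
  expect_lt(max(abs(colMeans(dff3$values[idx, ]))), 1e-9)
  # all-dark plane errors; single dark pixels are masked
  dark <- flat_movie(660, level = 0)
  expect_error(compute_dff(dark, c(0, 6)), "zero baseline")
  mv4 <- flat_movie(660)
  mv4$values[, 3] <- 0
  dff4 <- compute_dff(mv4, c(0, 6))
  expect_true(dff4$mask[3])
  expect_true(all(dff4$values[, 3] == 0))
})

test_that("reflectance subtraction removes a shared artifact exactly", {
  T <- 660
  # artifact with full periods inside the [0, 6) s baseline window, so its
  # baseline mean is exactly zero and the cancellation is exact
  artifact <- 2 * sin(2 * pi * (0:(T - 1)) / 180)
  neural <- c(rep(0, 380), 5 * exp(-(1:280) / 60))
  f <- flat_movie(T)
  f$values <- 1000 * (1 + (neural + artifact) / 100) *
    matrix(1, T, 64)
  r <- flat_movie(T)
  r$values <- 1500 * (1 + artifact / 100) * matrix(1, T, 64)
  fd <- compute_dff(f, c(0, 6))
  rd <- compute_dff(r, c(0, 6))
  out <- hemodynamic_correct(fd, rd)
  expect_true(out$corrected)
  # identical baseline-window normalization cancels the artifact exactly
  recovered <- out$values[, 1]
  direct <- compute_dff({
    m <- flat_movie(T); m$values <- 1000 * (1 + neural / 100) * matrix(1, T, 64); m
  }, c(0, 6))$values[, 1]
  expect_equal(recovered, direct, tolerance = 1e-9)
  # reflect == 0 is the identity
  zero <- flat_movie(T)
  zd <- compute_dff(zero, c(0, 6))
  expect_equal(hemodynamic_correct(fd, zd)$values, fd$values)
  # linearity: correct(aX, aY) = a correct(X, Y)
  fa <- fd; fa$values <- 3 * fd$values
  ra <- rd; ra$values <- 3 * rd$values
  expect_equal(hemodynamic_correct(fa, ra)$values,
               3 * out$values, tolerance = 1e-12)
  # shape mismatch
  small <- compute_dff(flat_movie(T, h = 4, w = 4), c(0, 6))
  expect_error(hemodynamic_correct(fd, small), "differ in shape")
})

test_that("ROI traces average the 5x5 window at the centroid", {
  atlas <- default_atlas(c(64, 64))
  dff <- compute_dff(flat_movie(660, h = 64, w = 64), c(0, 6))
  dff$values[] <- 3
  tr <- extract_trace(dff, atlas, "M1_contra")
  expect_equal(unclass(tr)[1], 3)
  # delta at the centroid pixel only: 25% / 25 = 1%
  ctr <- mesoreach:::roi_centroid(atlas, "M1_contra")
  dff$values[] <- 0
  dff$values[100, (ctr[2] - 1) * 64 + ctr[1]] <- 25
  tr2 <- extract_trace(dff, atlas, "M1_contra")
  expect_equal(unclass(tr2)[100], 1)
  expect_error(extract_trace(dff, atlas, "nonexistent_roi"), "unknown ROI")
})

test_that("peak amplitude uses the category-specific search window", {
  tl <- build_timeline("rewarded", touch_s = 7)
  flat <- structure(rep(0, 600), rate = 60, roi = "M1_contra",
                    class = "roi_trace")
  pk <- peak_amplitude(flat, tl, "success")
  expect_equal(pk$amplitude, 0)
  expect_equal(pk$baseline_sd, 0)
  # 6% plateau during [6.5, 7) on a success trial
  tr <- flat
  tr[frame_window(6.5, 7, 60)] <- 6
  pk2 <- peak_amplitude(tr, tl, "success")
  expect_equal(pk2$amplitude, 6)
  expect_gte(pk2$peak_time_s, 6.5)
  # an early transient (before the 1-5 s baseline) is seen by the
  # full-trial window only
  tln <- build_timeline("nonrewarded")
  tr3 <- flat
  tr3[frame_window(0.2, 0.7, 60)] <- 4
  pk_full <- peak_amplitude(tr3, tln, "unrewarded_reach")
  expect_equal(pk_full$amplitude, 4)
  tl_s <- build_timeline("rewarded", touch_s = 7)
  pk_windowed <- peak_amplitude(tr3, tl_s, "success")
  expect_equal(pk_windowed$amplitude, 0)
  expect_error(peak_amplitude(flat, tl, "no_reach"), "no peak search window")
  short <- structure(rep(0, 300), rate = 60, class = "roi_trace")
  expect_error(peak_amplitude(short, tl, "success"), "exceeds the trace")
})

test_that("activated area finds a constructed blob and excludes zero variance", {
  tl <- build_timeline("rewarded", touch_s = 7)
  # zero movie with zero noise: nothing is eligible
  dffz <- compute_dff(flat_movie(600, h = 16, w = 16), c(0, 6))
  az <- area_activated(dffz, tl, "success")
  expect_equal(az$n_pixels, 0)
  expect_equal(az$n_zero_variance, 256)
  # 5x5 blob at 10 sigma on 1% Gaussian noise
  set.seed(99)
  h <- 32; P <- h * h
  mv <- flat_movie(600, h = h, w = h)
  mv$values <- mv$values + matrix(rnorm(600 * P, 0, 10), 600, P)
  blob <- as.vector(outer(10:14, (9:13) * h, `+`))
  win <- frame_window(6.5, 7.5, 60)
  mv$values[win, blob] <- mv$values[win, blob] + 100
  dff <- compute_dff(mv, c(0, 6))
  aa <- area_activated(dff, tl, "success")
  p_fp <- 1 - pnorm(4)^length(frame_window(6, 10, 60))
  allowance <- qbinom(0.9999, P - 25, p_fp * 1.5)
  expect_gte(aa$n_pixels, 25)
  expect_lte(aa$n_pixels, 25 + allowance)
  expect_equal(aa$area_mm2, aa$n_pixels * 0.068^2)
  # global-SD mode runs and stays in the same ballpark
  ag <- area_activated(dff, tl, "success", sd_mode = "global")
  expect_gte(ag$n_pixels, 25)
})
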