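test_that("frame subsampling follows the interval contract", {
  ts <- (0:199) / 20                      # 10 s at 20 Hz
  sq <- thermal_seq(ts, 4, 4, renderer = function(i) matrix(0, 4, 4))
  expect_warning(out <- sample_frames(sq, 30), "no frames")
  expect_equal(length(out), 0)
  expect_error(sample_frames(sq, 0.01), "shorter than the frame spacing")
  # nearest-frame selection with ties toward the earlier frame
  sq2 <- thermal_seq(c(0, 1, 2, 3), 2, 2,
                     frames = replicate(4, matrix(0, 2, 2), simplify = FALSE))
  out2 <- sample_frames(sq2, 1.5)         # targets 1.5, 3.0
  expect_equal(attr(out2, "source_index"), c(2, 4))
})

test_that("ROI extrema match an exhaustive pixel scan, ties row-major", {
  # constant field
  fr <- matrix(30, 20, 20)
  ex <- roi_extrema(fr, rect_roi(3, 3, 5, 5))
  expect_equal(ex$t_max, 30); expect_equal(ex$t_min, 30)
  # ties: two equal maxima, row-major first occurrence wins
  fr2 <- matrix(0, 10, 10)
  fr2[3 + 1, 7 + 1] <- 5   # (x=7, y=3): later in row-major than (2,4)? no:
  fr2[4 + 1, 2 + 1] <- 5   # (x=2, y=4) is a later row -> (7,3) first
  ex2 <- roi_extrema(fr2, rect_roi(0, 0, 10, 10))
  expect_equal(unname(ex2$argmax_px), c(7, 3))
  # clipping: ROI partly outside uses the intersection only
  fr3 <- matrix(seq_len(25), 5, 5)
  ex3 <- roi_extrema(fr3, rect_roi(-2, -2, 4, 4))
  or3 <- oracle_roi_extrema(fr3, -2, -2, 4, 4)
  expect_equal(ex3$t_max, or3$t_max)
  expect_equal(unname(ex3$argmax_px), or3$argmax_px)
  expect_error(roi_extrema(fr3, rect_roi(10, 10, 2, 2)), "intersect")
})

test_that("ROI translation preserves size and rejects off-frame moves", {
  r <- rect_roi(10, 10, 40, 40)
  expect_equal(track_roi(r, c(0, 0), 100, 100), r)
  r2 <- track_roi(r, c(5, -3), 100, 100)
  expect_equal(c(r2$x0, r2$y0, r2$w, r2$h), c(15, 7, 40, 40))
  expect_error(track_roi(r, c(200, 0), 100, 100), "leaves the frame")
})

test_that("keypoint sampling: identity at radius 0, 3x3 mean at radius 1, dropout", {
  cfg <- noiseless_cfg(duration_s = 5)
  gt <- generate_kinematics(cfg)
  th <- render_thermal(cfg, gt)
  tr <- simulate_tracker(cfg, gt)
  pr <- sample_at_keypoints(th, tr, p_cut = 0.5, radius_px = 0)
  for (z in knee_zones())
    expect_identical(pr[[z]]$temp_c, unname(gt$zone_temps[, z]))
  # radius 1: mean of the 9-pixel neighbourhood, hand-computed
  fr <- matrix(rnorm(100), 10, 10)
  sq <- thermal_seq(0, 10, 10, frames = list(fr))
  tk <- data.frame(frame = 1, time = 0, zone = "RP",
                   x = 4.2, y = 6.8, likelihood = 1)
  class(tk) <- c("keypoint_track", "data.frame")
  pr1 <- sample_at_keypoints(sq, tk, p_cut = 0.5, radius_px = 1)
  expect_equal(pr1$RP$temp_c, mean(fr[(6:8) + 1, (3:5) + 1]))
  # full dropout for a zone yields an empty, flagged profile
  tk2 <- tk; tk2$likelihood <- 0.1
  pr2 <- sample_at_keypoints(sq, tk2, p_cut = 0.5, radius_px = 0)
  expect_equal(nrow(pr2$RP), 0)
  expect_equal(attr(pr2, "n_dropped"), 1L)
  # off-frame keypoint omitted with a warning and counted
  tk3 <- tk; tk3$x <- 50
  expect_warning(pr3 <- sample_at_keypoints(sq, tk3, 0.5, 0), "outside")
  expect_equal(attr(pr3, "n_outside"), 1L)
  expect_equal(nrow(pr3$RP), 0)
})

test_that("robust lowess preserves lines and constants, suppresses spikes", {
  n <- 600
  t <- seq_len(n)
  line <- zone_profile(t, 25 + 0.004 * t, "RSM", "automatic")
  sm <- smooth_profile(line, 0.02)
  expect_lt(max(abs(sm$temp_c - line$temp_c)), 1e-6)
  const <- zone_profile(t, rep(30, n), "RP", "automatic")
  expect_lt(max(abs(smooth_profile(const, 0.02)$temp_c - 30)), 1e-9)
  # single +5 degC spike drops by >= 90%
  spiky <- line$temp_c; spiky[300] <- spiky[300] + 5
  smsp <- smooth_profile(zone_profile(t, spiky, "RSM", "automatic"), 0.02)
  expect_lt(abs(smsp$temp_c[300] - line$temp_c[300]), 0.5)
  # idempotent once the outliers are gone: re-smoothing a cleaned
  # trend-plus-spikes series changes it by < 1e-3 degC
  set.seed(3)
  spiked <- zone_profile(t, 25 + 0.004 * t + 5 * (runif(n) < 0.01),
                         "RSM", "automatic")
  s1 <- smooth_profile(spiked, 0.02)
  s2 <- smooth_profile(s1, 0.02)
  expect_lt(max(abs(s2$temp_c - s1$temp_c)), 1e-3)
  # short profiles come back unsmoothed with a warning
  short <- zone_profile(1:2, c(1, 2), "RP", "automatic")
  expect_warning(out <- smooth_profile(short, 0.02), "fewer than 3")
  expect_equal(out$temp_c, c(1, 2))
})

test_that("slope recovery and trend directions on noisy synthetic data", {
  reps <- 8
  signs_ok <- 0
  rel_err <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- fast_cfg(duration_s = 240, seed = 100 + r)
    gt <- generate_kinematics(cfg)
    th <- render_thermal(cfg, gt)
    a <- sample_frames(th, 1)
    tr <- simulate_tracker(cfg, gt, frame_index = attr(a, "source_index"))
    pr <- sample_at_keypoints(a, tr, 0.5, 1)
    slope <- function(p) unname(coef(lm(temp_c ~ I(t_s / 60), data = p))[2])
    rel_err[r] <- abs(slope(pr$RSM) - 0.08) / 0.08
    sgn <- c(slope(pr$RSM) > 0, slope(pr$LSM) > 0,
             slope(pr$RP) < 0, slope(pr$LP) < 0,
             slope(pr$RPT) < 0, slope(pr$LPT) < 0)
    signs_ok <- signs_ok + all(sgn)
  }
  expect_lt(median(rel_err), 0.10)
  expect_gte(signs_ok, reps - 1)
})

test_that("file formats round-trip: thermal CSV/TIFF, keypoints, profiles", {
  cfg <- noiseless_cfg(duration_s = 2)
  gt <- generate_kinematics(cfg)
  th <- render_thermal(cfg, gt)
  small <- sample_frames(th, 1)
  d <- file.path(tempdir(), "thcsv")
  write_thermal_csv(small, d)
  back <- read_thermal_csv(d)
  expect_equal(get_frame(back, 1), get_frame(small, 1))
  expect_equal(back$timestamps, small$timestamps)
  tf <- file.path(tempdir(), "th.tif")
  write_thermal_tiff(small, tf)
  backt <- read_thermal_tiff(tf)
  expect_equal(get_frame(backt, 2), get_frame(small, 2), tolerance = 1e-5)
  tr <- simulate_tracker(cfg, gt)
  kf <- file.path(tempdir(), "kp.csv")
  write_keypoints_csv(tr, kf)
  tr2 <- read_keypoints_csv(kf)
  expect_equal(tr2$x, tr$x, tolerance = 1e-12)
  expect_equal(tr2$zone, tr$zone)
  p <- zone_profile(1:5, 21:25, "RSM", "automatic")
  pf <- file.path(tempdir(), "prof.csv")
  write_zone_profiles(list(RSM = p), pf)
  p2 <- read_zone_profiles(pf)$RSM
  expect_equal(p2$temp_c, p$temp_c)
  expect_equal(attr(p2, "method"), "automatic")
  unlink(c(d, tf, paste0(tf, ".timestamps.csv"), kf, pf), recursive = TRUE)
})
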