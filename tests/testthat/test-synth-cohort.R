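test_that("config validation rejects impossible parameters", {
  expect_error(synth_config(left_share = 0), "left_share")
  expect_error(synth_config(left_share = 1), "left_share")
  expect_error(synth_config(rear_share = 1.2), "rear_share")
  expect_error(synth_config(frame_rate_hz = 0), "frame_rate_hz")
  expect_error(synth_config(thermal_noise_c = -1), "thermal_noise_c")
  expect_error(synth_config(cycle_period_s = c(4, 3)), "cycle_period_s")
  expect_error(generate_kinematics(synth_config(width_px = 60, height_px = 60)),
               "too small")
})

test_that("zone trend maps resolve leg prefixes, with prefixed entries winning", {
  tr <- thermoknee:::resolve_zone_map(c(SM = 0.08, LP = -0.07, P = -0.05))
  expect_equal(unname(tr["RSM"]), 0.08)
  expect_equal(unname(tr["LSM"]), 0.08)
  expect_equal(unname(tr["RP"]), -0.05)
  expect_equal(unname(tr["LP"]), -0.07)  # prefixed overrides unprefixed
  expect_equal(unname(tr["RPT"]), 0)
  expect_error(thermoknee:::resolve_zone_map(c(XX = 1)), "unknown zone")
})

test_that("kinematics: cycle counts, phase labels and degenerate motion", {
  # 600 s with periods in [3, 4] s completes between 150 and 200 cycles
  cfg <- fast_cfg(duration_s = 600, seed = 3)
  gt <- generate_kinematics(cfg)
  expect_gte(gt$n_cycles, 150)
  expect_lte(gt$n_cycles, 200)
  # cycle count agrees with an independent count from the raw excursion
  gt7 <- generate_kinematics(fast_cfg(seed = 7, duration_s = 120))
  expect_equal(gt7$n_cycles, oracle_cycle_count(gt7$u))
  # zero excursion amplitude: all standing, constant centres
  gt0 <- generate_kinematics(fast_cfg(excursion_px = 0))
  expect_true(all(gt0$phase == "standing"))
  expect_true(all(gt0$disp_px == 0))
  # centres stay inside the frame at both poses
  cfgb <- fast_cfg()
  gtb <- generate_kinematics(cfgb)
  ys <- rep(gtb$zone_y_base, each = 2) - rep(range(gtb$disp_px), 12)
  expect_true(all(ys >= 0 & ys <= cfgb$height_px - 1))
  expect_true(all(gtb$zone_x >= 0 & gtb$zone_x <= cfgb$width_px - 1))
})

test_that("identical seeds give identical outputs, on disk included", {
  cfg <- fast_cfg(duration_s = 10, seed = 42)
  p1 <- synth_participant(cfg)
  p2 <- synth_participant(cfg)
  expect_identical(get_frame(p1$thermal, 5), get_frame(p2$thermal, 5))
  expect_identical(p1$track, p2$track)
  expect_identical(as.data.frame(p1$loadcells), as.data.frame(p2$loadcells))
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  for (d in c(d1, d2)) {
    dir.create(d, showWarnings = FALSE)
    write_keypoints_csv(p1$track, file.path(d, "kp.csv"))
    write_loadcells_csv(p1$loadcells, file.path(d, "lc.csv"))
  }
  expect_identical(readLines(file.path(d1, "kp.csv")),
                   readLines(file.path(d2, "kp.csv")))
  expect_identical(readLines(file.path(d1, "lc.csv")),
                   readLines(file.path(d2, "lc.csv")))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("thermal field: noiseless static frames are identical, trends move the centre", {
  cfg <- noiseless_cfg(excursion_px = 0, zone_trends = c(SM = 0),
                       duration_s = 5)
  gt <- generate_kinematics(cfg)
  th <- render_thermal(cfg, gt)
  expect_identical(get_frame(th, 1), get_frame(th, 50))
  # +0.08 degC/min on SM: centre temperature rises slope * duration
  cfg2 <- noiseless_cfg(duration_s = 600, zone_trends = c(SM = 0.08))
  gt2 <- generate_kinematics(cfg2)
  n <- length(gt2$times)
  rise <- unname(gt2$zone_temps[n, "RSM"] - gt2$zone_temps[1, "RSM"])
  expect_equal(rise, 0.08 * gt2$times[n] / 60, tolerance = 1e-10)
})

test_that("per-pixel thermal noise matches the configured 0.04 degC std", {
  cfg <- fast_cfg(duration_s = 5, excursion_px = 0,
                  zone_trends = c(SM = 0), seed = 9)  # 100 static frames
  gt <- generate_kinematics(cfg)
  th <- render_thermal(cfg, gt)
  stack <- sapply(1:100, function(i) as.vector(get_frame(th, i)))
  px_sd <- apply(stack[seq(1, nrow(stack), by = 37), ], 1, sd)
  expect_equal(mean(px_sd), 0.04, tolerance = 0.1 * 0.04)
})

test_that("tracker error calibrates to the configured RMS and dropout rate", {
  cfg <- fast_cfg(duration_s = 45, tracker_rms_px = 9.3, dropout_prob = 0,
                  seed = 2)   # 900 frames x 12 zones > 10000 samples
  gt <- generate_kinematics(cfg)
  tr <- simulate_tracker(cfg, gt)
  xt <- rep(gt$zone_x, times = length(gt$times))
  yt <- rep(gt$zone_y_base, times = length(gt$times)) -
    rep(gt$disp_px, each = 12)
  rms <- sqrt(mean((tr$x - xt)^2 + (tr$y - yt)^2))
  expect_equal(rms, 9.3, tolerance = 0.05 * 9.3)
  # zero-noise tracker reproduces the truth exactly
  cfg0 <- noiseless_cfg(duration_s = 5)
  gt0 <- generate_kinematics(cfg0)
  tr0 <- simulate_tracker(cfg0, gt0)
  expect_equal(tr0$x, rep(gt0$zone_x, times = length(gt0$times)))
  expect_true(all(tr0$likelihood == 1))
  # dropout: fraction below 0.5 within binomial error of the target
  cfgd <- fast_cfg(duration_s = 45, dropout_prob = 0.1, seed = 4)
  gtd <- generate_kinematics(cfgd)
  trd <- simulate_tracker(cfgd, gtd)
  n <- nrow(trd)
  frac <- mean(trd$likelihood < 0.5)
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / n))
  expect_equal(mean(trd$likelihood[trd$likelihood >= 0.5]), 0.99,
               tolerance = 0.005)
})

test_that("load cells conserve the configured total and respect shares", {
  cfg <- noiseless_cfg(duration_s = 60, left_share = 0.53, rear_share = 0.65,
                       body_mass_kg = 70)
  gt <- generate_kinematics(cfg)
  lc <- simulate_loadcells(cfg, gt)
  total_true <- attr(lc, "total_true")
  expect_equal(total_weight(lc), total_true, tolerance = 1e-9)
  expect_equal(max(total_weight(lc)), 70, tolerance = 1e-6)
  standing <- gt$phase == "standing"
  expect_equal((lc$tl + lc$bl)[standing] / total_weight(lc)[standing],
               rep(0.53, sum(standing)), tolerance = 1e-12)
  expect_equal(lc$bl[standing] / (lc$tl + lc$bl)[standing],
               rep(0.65, sum(standing)), tolerance = 1e-12)
})

test_that("ground-truth files round-trip and carry the full config", {
  cfg <- noiseless_cfg(duration_s = 5)
  gt <- generate_kinematics(cfg)
  d <- file.path(tempdir(), "gtdir")
  write_ground_truth(gt, d)
  man <- read_ground_truth_manifest(d)
  expect_equal(man$left_share, cfg$left_share)
  expect_equal(man$n_cycles, gt$n_cycles)
  long <- read.csv(file.path(d, "ground_truth.csv"))
  expect_equal(nrow(long), length(gt$times) * 12)
  sel <- long$zone == "RSM"
  expect_equal(long$temp_c[sel], unname(gt$zone_temps[, "RSM"]))
  unlink(d, recursive = TRUE)
})
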