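# Thermal blob radial profile: flat core of radius r0 (so sampling is
# first-order insensitive to small keypoint error), Gaussian skirt of
# width sigma, compact support at r0 + 4*sigma (exact zero beyond, which
# keeps windowed rendering and pointwise ground-truth evaluation
# bit-identical).
blob_profile <- function(r, core_px, skirt_px) {
  rcut <- core_px + 4 * skirt_px
  out <- numeric(length(r))
  inside <- r <= core_px
  skirt <- r > core_px & r <= rcut
  out[inside] <- 1
  out[skirt] <- exp(-((r[skirt] - core_px)^2) / (2 * skirt_px^2))
  out
}

blob_support_px <- function(cfg) cfg$blob_core_px + 4 * cfg$blob_skirt_px

# Blob table for one config: the 12 knee zones plus (optionally) two cold
# metal-marker spots per knee. Columns: x (constant), y_base (sitting
# pose), amp0 (degC at t=0 over baseline), trend (degC/min), core, skirt.
# Row order is fixed; renderer and ground-truth evaluation share it.
blob_table <- function(cfg) {
  knee_y <- 0.55 * cfg$height_px
  lay <- zone_layout(cfg$width_px, cfg$height_px, knee_y)
  amps <- effective_amps(cfg)
  trends <- effective_trends(cfg)
  tab <- data.frame(
    name = knee_zones(),
    x = lay[, "x"], y_base = lay[, "y"],
    amp0 = unname(amps), trend = unname(trends),
    core = cfg$blob_core_px, skirt = cfg$blob_skirt_px,
    stringsAsFactors = FALSE
  )
  if (cfg$render_markers) {
    kx <- c(0.30, 0.70) * cfg$width_px
    mk <- expand.grid(x = kx, dy = c(-55, 75))
    tab <- rbind(tab, data.frame(
      name = paste0("marker", seq_len(nrow(mk))),
      x = mk$x, y_base = knee_y + mk$dy,
      amp0 = -4, trend = 0, core = 4, skirt = 2,
      stringsAsFactors = FALSE
    ))
  }
  rownames(tab) <- NULL
  tab
}

#' Generate ground-truth sit-to-stand kinematics
#'
#' Simulates repeated sit-to-stand cycles: each cycle's period is drawn
#' uniformly from `cfg$cycle_period_s` and the vertical knee excursion
#' follows a raised cosine (sitting at 0, standing at `excursion_px`).
#' Phase labels are `sitting` below 25% of the excursion, `standing` above
#' 75%, `transition` between. With `excursion_px = 0` the participant is
#' treated as standing throughout.
#'
#' @param cfg A [synth_config()].
#' @return A `ground_truth` object: frame times, per-frame phase labels,
#'   excursion fraction `u`, vertical displacement, the 12 zone centres
#'   (constant x, `y = y_base - disp`), per-frame per-zone true centre
#'   temperatures (degC, evaluated at the pixel nearest each centre),
#'   completed cycle count and static weight.
#' @export
generate_kinematics <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  tab <- blob_table(cfg)
  # layout must fit at both poses, with the blob core inside the frame
  m <- 2
  ylo <- min(tab$y_base) - cfg$excursion_px
  yhi <- max(tab$y_base)
  if (min(tab$x) < m || max(tab$x) > cfg$width_px - 1 - m ||
      ylo < m || yhi > cfg$height_px - 1 - m)
    stop_cfg("image %d x %d px too small for the 12-zone knee layout",
             cfg$width_px, cfg$height_px)
  # no zone's blob support may reach another zone's centre, or the two
  # knees' fields (and the operator ROIs) would bleed into each other
  ctr <- as.matrix(tab[seq_len(12), c("x", "y_base")])
  dmin <- min(stats::dist(ctr))
  if (dmin <= blob_support_px(cfg))
    stop_cfg(paste("image %d x %d px too small for the 12-zone knee layout:",
                   "zone centres %.0f px apart overlap the %.0f px blob",
                   "support"),
             cfg$width_px, cfg$height_px, dmin, blob_support_px(cfg))

  n <- round(cfg$duration_s * cfg$frame_rate_hz)
  times <- (seq_len(n) - 1) / cfg$frame_rate_hz

  set.seed(derive_seed(cfg$seed, 1))
  periods <- numeric(0)
  while (sum(periods) < cfg$duration_s)
    periods <- c(periods,
                 stats::runif(1, cfg$cycle_period_s[1], cfg$cycle_period_s[2]))
  starts <- cumsum(c(0, periods[-length(periods)]))
  ci <- findInterval(times, starts)
  phi <- (times - starts[ci]) / periods[ci]
  u <- (1 - cos(2 * pi * phi)) / 2

  if (cfg$excursion_px == 0) {
    u <- rep(1, n)
    phase <- rep("standing", n)
  } else {
    phase <- ifelse(u < 0.25, "sitting",
                    ifelse(u > 0.75, "standing", "transition"))
  }
  disp <- cfg$excursion_px * u

  # completed cycles = sitting -> standing transitions of the definite phase
  definite <- phase[phase != "transition"]
  rl <- rle(definite)$values
  n_cycles <- sum(rl[-1] == "standing" & rl[-length(rl)] == "sitting")

  zone_temps <- gt_zone_temps(cfg, tab, times, disp)

  structure(list(
    times = times, phase = phase, u = u, disp_px = disp,
    zone_names = knee_zones(),
    zone_x = tab$x[seq_len(12)], zone_y_base = tab$y_base[seq_len(12)],
    zone_temps = zone_temps, n_cycles = n_cycles, periods_s = periods,
    static_weight_kg = cfg$body_mass_kg, cfg = cfg
  ), class = "ground_truth")
}

# True centre temperature of each zone at each frame: the noiseless field
# value at the pixel nearest the zone centre, accumulated blob-by-blob in
# the same order as the renderer so the two agree bit for bit.
gt_zone_temps <- function(cfg, tab, times, disp) {
  n <- length(times)
  tmin <- times / 60
  out <- matrix(cfg$baseline_c, n, 12,
                dimnames = list(NULL, knee_zones()))
  for (z in seq_len(12)) {
    px <- round_half_up(tab$x[z])
    py <- round_half_up(tab$y_base[z] - disp)
    for (b in seq_len(nrow(tab))) {
      r <- sqrt((py - (tab$y_base[b] - disp))^2 + (px - tab$x[b])^2)
      amp <- tab$amp0[b] + tab$trend[b] * tmin
      out[, z] <- out[, z] + amp * blob_profile(r, tab$core[b], tab$skirt[b])
    }
  }
  out
}

# Deterministic per-frame noise seed.
frame_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i) %% 2147483647)
}

#' Render the synthetic thermal image sequence
#'
#' Each frame is a uniform baseline field plus one thermal blob per knee
#' zone (flat core, Gaussian skirt) centred on the true zone position for
#' that frame, with the centre amplitude following the configured linear
#' trend, plus i.i.d. Gaussian pixel noise of std `cfg$thermal_noise_c`.
#' Frames are rendered lazily: the returned [thermal_seq] carries a
#' renderer and materialises frames only when accessed, so a full 20 Hz
#' 10-min sequence never needs to exist in memory at once.
#'
#' @param cfg A [synth_config()].
#' @param gt Ground truth from [generate_kinematics()].
#' @return A [thermal_seq] of `length(gt$times)` frames.
#' @export
render_thermal <- function(cfg, gt) {
  stopifnot(inherits(gt, "ground_truth"))
  tab <- blob_table(cfg)
  w <- cfg$width_px; h <- cfg$height_px
  rcuts <- tab$core + 4 * tab$skirt
  renderer <- function(i) {
    d <- gt$disp_px[i]
    tmin <- gt$times[i] / 60
    frame <- matrix(cfg$baseline_c, h, w)
    for (b in seq_len(nrow(tab))) {
      cx <- tab$x[b]; cy <- tab$y_base[b] - d
      amp <- tab$amp0[b] + tab$trend[b] * tmin
      x0 <- max(0, floor(cx - rcuts[b])); x1 <- min(w - 1, ceiling(cx + rcuts[b]))
      y0 <- max(0, floor(cy - rcuts[b])); y1 <- min(h - 1, ceiling(cy + rcuts[b]))
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1; ys <- y0:y1
      rr <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
      frame[ys + 1, xs + 1] <- frame[ys + 1, xs + 1] +
        amp * blob_profile(rr, tab$core[b], tab$skirt[b])
    }
    if (cfg$thermal_noise_c > 0) {
      set.seed(frame_seed(cfg$seed, i))
      frame <- frame + matrix(stats::rnorm(h * w, 0, cfg$thermal_noise_c), h, w)
    }
    frame
  }
  thermal_seq(timestamps = gt$times, width = w, height = h,
              renderer = renderer)
}

#' Simulate DeepLabCut-style keypoint tracker output
#'
#' Observed keypoints are the true zone centres plus isotropic Gaussian
#' error with radial RMS `cfg$tracker_rms_px`. Likelihoods are drawn as
#' `1 - Beta(1, m/(1-m))` (mean `m = cfg$likelihood_mean`); a
#' `cfg$dropout_prob` fraction of (frame, zone) entries instead get a
#' likelihood uniform on [0, 0.5), emulating lost detections that a p-cut
#' of 0.5 removes.
#'
#' @param cfg A [synth_config()].
#' @param gt Ground truth from [generate_kinematics()].
#' @param frame_index Frames to track (default: all).
#' @return A `keypoint_track` data frame: `frame`, `time`, `zone`, `x`,
#'   `y`, `likelihood`, one row per frame x zone.
#' @export
simulate_tracker <- function(cfg, gt, frame_index = NULL) {
  stopifnot(inherits(gt, "ground_truth"))
  idx <- frame_index %||% seq_along(gt$times)
  nz <- 12L
  nf <- length(idx)
  N <- nf * nz
  zone <- rep(gt$zone_names, times = nf)
  xt <- rep(gt$zone_x, times = nf)
  yt <- rep(gt$zone_y_base, times = nf) - rep(gt$disp_px[idx], each = nz)

  set.seed(derive_seed(cfg$seed, 2))
  sd_axis <- cfg$tracker_rms_px / sqrt(2)
  x <- xt + stats::rnorm(N, 0, sd_axis)
  y <- yt + stats::rnorm(N, 0, sd_axis)
  if (cfg$likelihood_mean >= 1) {
    lik <- rep(1, N)
  } else {
    b <- cfg$likelihood_mean / (1 - cfg$likelihood_mean)
    lik <- 1 - stats::rbeta(N, 1, b)
  }
  drop <- stats::runif(N) < cfg$dropout_prob
  if (any(drop)) lik[drop] <- stats::runif(sum(drop), 0, 0.4999)

  out <- data.frame(
    frame = rep(idx, each = nz),
    time = rep(gt$times[idx], each = nz),
    zone = zone, x = x, y = y, likelihood = lik,
    stringsAsFactors = FALSE
  )
  class(out) <- c("keypoint_track", "data.frame")
  out
}

#' Simulate four-corner balance-board load-cell signals
#'
#' While standing the full body mass rests on the board, split
#' left/right by `cfg$left_share` and fore/rear by `cfg$rear_share`;
#' while sitting only `cfg$sit_level` of the mass remains on the feet.
#' The total follows the smooth sit-to-stand excursion, so transitions
#' are raised-cosine ramps. Independent Gaussian noise of std
#' `cfg$loadcell_noise_kg` is added per cell.
#'
#' @param cfg A [synth_config()].
#' @param gt Ground truth from [generate_kinematics()].
#' @return A [loadcell_series] with the pre-noise instantaneous total in
#'   attribute `"total_true"`.
#' @export
simulate_loadcells <- function(cfg, gt) {
  stopifnot(inherits(gt, "ground_truth"))
  total <- cfg$body_mass_kg * (cfg$sit_level + (1 - cfg$sit_level) * gt$u)
  l <- cfg$left_share; r <- cfg$rear_share
  tl <- total * l * (1 - r)
  bl <- total * l * r
  tr <- total * (1 - l) * (1 - r)
  br <- total * (1 - l) * r
  if (cfg$loadcell_noise_kg > 0) {
    set.seed(derive_seed(cfg$seed, 3))
    n <- length(total)
    tl <- tl + stats::rnorm(n, 0, cfg$loadcell_noise_kg)
    tr <- tr + stats::rnorm(n, 0, cfg$loadcell_noise_kg)
    bl <- bl + stats::rnorm(n, 0, cfg$loadcell_noise_kg)
    br <- br + stats::rnorm(n, 0, cfg$loadcell_noise_kg)
  }
  out <- loadcell_series(gt$times, tl, tr, bl, br,
                         rate_hz = cfg$frame_rate_hz)
  attr(out, "total_true") <- total
  out
}

#' Write / read ground truth for one synthetic participant
#'
#' `ground_truth.csv` holds one row per frame x zone (`frame`, `t_s`,
#' `phase`, `zone`, `x_px`, `y_px`, `temp_c`); `manifest.json` echoes the
#' full generator config plus cycle count and static weight, so every
#' downstream recovery test can run from the files alone.
#'
#' @param gt A `ground_truth` from [generate_kinematics()].
#' @param dir Target directory (created).
#' @return `write_ground_truth` the directory, invisibly;
#'   `read_ground_truth_manifest` the parsed manifest list.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(gt$times)
  long <- data.frame(
    frame = rep(seq_len(n), each = 12),
    t_s = rep(gt$times, each = 12),
    phase = rep(gt$phase, each = 12),
    zone = rep(gt$zone_names, times = n),
    x_px = rep(gt$zone_x, times = n),
    y_px = rep(gt$zone_y_base, times = n) - rep(gt$disp_px, each = 12),
    temp_c = as.vector(t(gt$zone_temps))
  )
  utils::write.csv(long, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  manifest <- c(unclass(gt$cfg),
                list(n_cycles = gt$n_cycles,
                     static_weight_kg = gt$static_weight_kg))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth_manifest <- function(dir) {
  jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
}

#' Generate one complete synthetic participant
#'
#' Convenience wrapper running [generate_kinematics()],
#' [render_thermal()], [simulate_tracker()] and [simulate_loadcells()].
#'
#' @param cfg A [synth_config()].
#' @return List with `gt`, `thermal`, `track`, `loadcells`, `cfg`.
#' @export
synth_participant <- function(cfg) {
  gt <- generate_kinematics(cfg)
  list(gt = gt,
       thermal = render_thermal(cfg, gt),
       track = simulate_tracker(cfg, gt),
       loadcells = simulate_loadcells(cfg, gt),
       cfg = cfg)
}
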