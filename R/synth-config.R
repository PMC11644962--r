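#' Configuration for the synthetic sit-to-stand cohort generator
#'
#' Bundles every parameter of the synthetic data model: acquisition
#' geometry and rate, thermal field (baseline, per-zone blob amplitudes and
#' warming/cooling trends), sit-to-stand kinematics, keypoint-tracker noise
#' and dropout, and balance-board load distribution.
#'
#' Defaults reproduce the acquisition conditions the pipeline targets:
#' 10 min of exercise at 20 Hz, 382 x 288 px thermal frames with 0.04 degC
#' sensor noise, one sit-to-stand cycle every 3-4 s, tracker error of
#' 9.3 px RMS with mean likelihood 0.99, and a balanced stance
#' (`left_share = 0.5`) with 65% of each leg's load on the rearfoot.
#'
#' @param duration_s Run length in seconds.
#' @param frame_rate_hz Acquisition rate for thermal, tracker and load-cell
#'   streams.
#' @param width_px,height_px Thermal frame size in pixels.
#' @param thermal_noise_c Per-pixel i.i.d. Gaussian sensor noise, degC std.
#' @param cycle_period_s Length-2 range; each sit-to-stand cycle period is
#'   drawn uniformly from it (seconds).
#' @param zone_trends Named numeric vector of linear temperature trends in
#'   degC/min. Names are zone codes with (`"RSM"`) or without (`"SM"`) a leg
#'   prefix; unprefixed names apply to both legs. Unnamed zones default to 0.
#' @param tracker_rms_px Radial RMS of the simulated keypoint error, pixels.
#' @param likelihood_mean Mean tracker likelihood for non-dropout entries.
#' @param dropout_prob Fraction of (frame, zone) entries whose likelihood is
#'   drawn below 0.5 (lost detections).
#' @param left_share Fraction of total standing load carried by the left
#'   leg; 0.5 is symmetric, the asymmetric regime of interest is 0.52-0.545.
#' @param rear_share Fraction of each leg's load on the rearfoot cell while
#'   standing.
#' @param body_mass_kg Participant mass.
#' @param coupling_gain Extra warming slope (degC/min per unit of excess
#'   load share above 0.5) added to the SM zone of the more loaded leg;
#'   models load-coupled heating of the medial collateral ligament region.
#' @param seed Integer seed; identical configs give identical outputs.
#' @param baseline_c Uniform background skin temperature, degC.
#' @param zone_amps Named per-zone blob amplitude offsets from baseline at
#'   t = 0, degC (leg-prefixed or not, like `zone_trends`). Positive SM and
#'   negative P/PT defaults put the frame maximum in the SM region and the
#'   minimum at the patella.
#' @param blob_core_px Radius of the flat core of each zone's thermal blob.
#' @param blob_skirt_px Gaussian sigma of the blob's skirt outside the core;
#'   support is truncated at `blob_core_px + 4 * blob_skirt_px`.
#' @param excursion_px Vertical knee travel between sitting and standing,
#'   pixels. Zero means the participant stands still.
#' @param sit_level Fraction of body mass left on the feet while seated.
#' @param loadcell_noise_kg Additive Gaussian noise per load cell, kg std.
#' @param render_markers If `TRUE`, two cold metal-marker spots are rendered
#'   above and below each knee (the manual method's fiducials).
#'
#' @return An object of class `synth_config` (validated list).
#' @export
synth_config <- function(duration_s = 600,
                         frame_rate_hz = 20,
                         width_px = 382,
                         height_px = 288,
                         thermal_noise_c = 0.04,
                         cycle_period_s = c(3, 4),
                         zone_trends = c(SM = 0.08, P = -0.05, PT = -0.05),
                         tracker_rms_px = 9.3,
                         likelihood_mean = 0.99,
                         dropout_prob = 0.005,
                         left_share = 0.50,
                         rear_share = 0.65,
                         body_mass_kg = 70,
                         coupling_gain = 1.0,
                         seed = 1L,
                         baseline_c = 27,
                         zone_amps = c(SL = 1.0, SM = 3.0, P = -2.5,
                                       LJLA = 0.8, MJLA = 0.8, PT = -2.0),
                         blob_core_px = 15,
                         blob_skirt_px = 5,
                         excursion_px = 40,
                         sit_level = 0.05,
                         loadcell_noise_kg = 0.1,
                         render_markers = FALSE) {
  cfg <- list(
    duration_s = duration_s, frame_rate_hz = frame_rate_hz,
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    thermal_noise_c = thermal_noise_c, cycle_period_s = cycle_period_s,
    zone_trends = zone_trends, tracker_rms_px = tracker_rms_px,
    likelihood_mean = likelihood_mean, dropout_prob = dropout_prob,
    left_share = left_share, rear_share = rear_share,
    body_mass_kg = body_mass_kg, coupling_gain = coupling_gain,
    seed = as.integer(seed), baseline_c = baseline_c,
    zone_amps = zone_amps, blob_core_px = blob_core_px,
    blob_skirt_px = blob_skirt_px, excursion_px = excursion_px,
    sit_level = sit_level, loadcell_noise_kg = loadcell_noise_kg,
    render_markers = isTRUE(render_markers)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$frame_rate_hz <= 0) stop_cfg("frame_rate_hz must be > 0")
  if (cfg$duration_s <= 0) stop_cfg("duration_s must be > 0")
  if (cfg$thermal_noise_c < 0) stop_cfg("thermal_noise_c must be >= 0")
  if (cfg$tracker_rms_px < 0) stop_cfg("tracker_rms_px must be >= 0")
  if (cfg$left_share <= 0 || cfg$left_share >= 1)
    stop_cfg("left_share must be in (0, 1)")
  if (cfg$rear_share <= 0 || cfg$rear_share >= 1)
    stop_cfg("rear_share must be in (0, 1)")
  if (cfg$dropout_prob < 0 || cfg$dropout_prob > 1)
    stop_cfg("dropout_prob must be in [0, 1]")
  if (length(cfg$cycle_period_s) != 2 || any(cfg$cycle_period_s <= 0) ||
      cfg$cycle_period_s[1] > cfg$cycle_period_s[2])
    stop_cfg("cycle_period_s must be an increasing positive range")
  if (cfg$excursion_px < 0) stop_cfg("excursion_px must be >= 0")
  invisible(cfg)
}

# Resolve a user map (leg-prefixed and/or unprefixed zone names) onto the
# 12 canonical zones. Unprefixed entries apply to both legs; prefixed
# entries win over unprefixed ones.
resolve_zone_map <- function(map, default = 0) {
  zones <- knee_zones()
  out <- rep(default, length(zones))
  names(out) <- zones
  if (is.null(map) || !length(map)) return(out)
  nm <- names(map)
  if (is.null(nm) || any(!nzchar(nm)))
    stop_cfg("zone maps must be fully named")
  for (i in seq_along(map)) {
    key <- nm[i]
    if (key %in% zones) next  # prefixed, second pass
    hits <- zones[substring(zones, 2) == key]
    if (!length(hits)) stop_cfg("unknown zone code '%s'", key)
    out[hits] <- map[[i]]
  }
  pref <- nm[nm %in% zones]
  out[pref] <- unlist(map[pref], use.names = FALSE)
  out
}

# Effective per-zone linear trend in degC/min, including the load-coupled
# extra warming of the heavier leg's SM zone.
effective_trends <- function(cfg) {
  tr <- resolve_zone_map(cfg$zone_trends)
  excess <- abs(cfg$left_share - 0.5)
  if (excess > 0 && cfg$coupling_gain != 0) {
    zone <- if (cfg$left_share > 0.5) "LSM" else "RSM"
    tr[zone] <- tr[zone] + cfg$coupling_gain * excess
  }
  tr
}

effective_amps <- function(cfg) resolve_zone_map(cfg$zone_amps)

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  %g s at %g Hz, %d x %d px, noise %g degC\n",
              x$duration_s, x$frame_rate_hz, x$width_px, x$height_px,
              x$thermal_noise_c))
  cat(sprintf("  left_share %.3f, rear_share %.2f, mass %g kg, seed %d\n",
              x$left_share, x$rear_share, x$body_mass_kg, x$seed))
  invisible(x)
}
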