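#' Synthetic cohort metadata table
#'
#' Draws a participant table for a cohort run: gender (about 65% male),
#' height, BMI-derived weight, and a per-participant standing load split.
#' `asym_fraction` of the cohort (rounded) gets an asymmetric split drawn
#' uniformly from `asym_range` (heavier side random); the rest are
#' balanced within 49-51%.
#'
#' @param n Number of participants.
#' @param seed Integer seed.
#' @param asym_fraction Fraction of asymmetric participants.
#' @param asym_range Range of the heavier leg's share for asymmetric
#'   participants.
#' @param coupling_gain Load-coupled SM warming gain passed to the
#'   generator (degC/min per unit excess share).
#' @return Data frame: `participant`, `gender`, `height_m`, `weight_kg`,
#'   `bmi`, `left_share`, `coupling_gain`, `seed`.
#' @export
make_cohort_metadata <- function(n = 20, seed = 1,
                                 asym_fraction = 0.65,
                                 asym_range = c(0.52, 0.545),
                                 coupling_gain = 1.0) {
  set.seed(derive_seed(seed, 10))
  n_m <- round(0.65 * n)
  gender <- sample(c(rep("M", n_m), rep("F", n - n_m)))
  height <- stats::runif(n, 1.58, 1.92)
  bmi <- stats::runif(n, 19, 30)
  weight <- bmi * height^2
  n_asym <- round(asym_fraction * n)
  asym <- sample(c(rep(TRUE, n_asym), rep(FALSE, n - n_asym)))
  share <- ifelse(asym,
                  stats::runif(n, asym_range[1], asym_range[2]),
                  stats::runif(n, 0.49, 0.51))
  side <- sample(c(-1, 1), n, replace = TRUE)
  left_share <- ifelse(side > 0, share, 1 - share)
  data.frame(
    participant = sprintf("P%02d", seq_len(n)),
    gender = gender, height_m = height, weight_kg = weight, bmi = bmi,
    left_share = left_share, coupling_gain = coupling_gain,
    seed = vapply(seq_len(n), function(i) derive_seed(seed, 100 + i),
                  integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Pipeline run configuration
#'
#' Gathers every stage parameter of a generate-extract-compare run.
#' Synthesis parameters not listed here (noise levels, trends, geometry)
#' can be overridden through `synth_args`.
#'
#' @param n_participants Cohort size when `metadata` is NULL.
#' @param metadata Participant table ([make_cohort_metadata()] layout);
#'   in `input = "files"` mode it must also carry `loadcell_csv`,
#'   `keypoints_csv` and `thermal_dir` path columns.
#' @param input `"synth"` (generate everything) or `"files"`.
#' @param duration_s Run length per participant, seconds.
#' @param semi_interval_s Semi-automatic sampling interval (one
#'   thermogram every 30 s in the reference protocol).
#' @param auto_interval_s Automatic sampling interval (1 s).
#' @param p_cut Keypoint likelihood cutoff.
#' @param radius_px Keypoint sampling window half-width.
#' @param span_fraction Robust-lowess span for profile smoothing.
#' @param smooth_for_match Smooth profiles before slope-based leg
#'   matching (regressions always use raw profiles).
#' @param stand_frac,sit_frac Phase segmentation thresholds.
#' @param asym_threshold Weight-asymmetry threshold.
#' @param strength_threshold `R^2` cutoff for a strong correlation.
#' @param bmi_cutoff BMI stratification boundary, kg/m^2.
#' @param span_x_mm,span_y_mm Balance-board sensor spans.
#' @param seed Master seed.
#' @param keep_example Keep the first participant's profiles and
#'   balance-board tables in the report (needed by [make_figures()]).
#' @param out_dir Optional output directory for the report files.
#' @param synth_args Named list of extra [synth_config()] arguments.
#' @return A `run_config` list.
#' @export
run_config <- function(n_participants = 2, metadata = NULL,
                       input = c("synth", "files"),
                       duration_s = 600,
                       semi_interval_s = 30, auto_interval_s = 1,
                       p_cut = 0.5, radius_px = 1, span_fraction = 0.02,
                       smooth_for_match = TRUE,
                       stand_frac = 0.8, sit_frac = 0.25,
                       asym_threshold = 0.52, strength_threshold = 0.5,
                       bmi_cutoff = 25, span_x_mm = 433, span_y_mm = 238,
                       seed = 1, keep_example = TRUE, out_dir = NULL,
                       synth_args = list()) {
  input <- match.arg(input)
  if (is.null(metadata))
    metadata <- make_cohort_metadata(n_participants, seed = seed)
  structure(list(
    metadata = metadata, input = input, duration_s = duration_s,
    semi_interval_s = semi_interval_s, auto_interval_s = auto_interval_s,
    p_cut = p_cut, radius_px = radius_px, span_fraction = span_fraction,
    smooth_for_match = smooth_for_match,
    stand_frac = stand_frac, sit_frac = sit_frac,
    asym_threshold = asym_threshold,
    strength_threshold = strength_threshold, bmi_cutoff = bmi_cutoff,
    span_x_mm = span_x_mm, span_y_mm = span_y_mm,
    seed = seed, keep_example = keep_example, out_dir = out_dir,
    synth_args = synth_args
  ), class = "run_config")
}

# The operator's rectangle: centred on the knee, wide/tall enough to
# contain every zone of that knee (so the ROI max sits in the SM region
# and the min at the patella), repositioned per frame with track_roi().
knee_rois <- function(cfg, gt, frame_index) {
  kx <- c(right = 0.30, left = 0.70) * cfg$width_px
  ky0 <- 0.55 * cfg$height_px
  hw <- 45L; up <- 50L; down <- 61L
  lapply(c(right = "right", left = "left"), function(leg) {
    x0 <- round_half_up(kx[[leg]]) - hw
    rois <- vector("list", length(frame_index))
    prev <- NULL
    for (j in seq_along(frame_index)) {
      y0 <- round_half_up(ky0 - gt$disp_px[frame_index[j]]) - up
      if (is.null(prev)) {
        prev <- rect_roi(x0, y0, 2L * hw + 1L, up + down + 1L)
      } else {
        prev <- track_roi(prev, c(0L, y0 - prev$y0),
                          cfg$width_px, cfg$height_px)
      }
      rois[[j]] <- prev
    }
    rois
  })
}

# Semi-automatic extraction: ROI extrema on each sampled frame, per leg.
extract_semi <- function(cfg, gt, thermal, interval_s) {
  sem <- sample_frames(thermal, interval_s)
  idx <- attr(sem, "source_index")
  rois <- knee_rois(cfg, gt, idx)
  out <- list()
  for (leg in c("right", "left")) {
    tmax <- numeric(length(idx)); tmin <- numeric(length(idx))
    for (j in seq_along(idx)) {
      ex <- roi_extrema(get_frame(sem, j), rois[[leg]][[j]])
      tmax[j] <- ex$t_max; tmin[j] <- ex$t_min
    }
    pre <- if (leg == "right") "R" else "L"
    out[[paste0(pre, "max")]] <- zone_profile(sem$timestamps, tmax,
      zone = paste0(pre, "max"), method = "semi_automatic_max")
    out[[paste0(pre, "min")]] <- zone_profile(sem$timestamps, tmin,
      zone = paste0(pre, "min"), method = "semi_automatic_min")
  }
  out
}

# Region table: the four inter-method comparisons.
comparison_regions <- function() {
  data.frame(
    region = c("R_ligament", "L_ligament", "R_patella", "L_patella"),
    auto_zone = c("RSM", "LSM", "RP", "LP"),
    semi_profile = c("Rmax", "Lmax", "Rmin", "Lmin"),
    stringsAsFactors = FALSE
  )
}

process_participant <- function(rc, row) {
  pid <- row$participant
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage '%s': %s", pid, name, conditionMessage(e)),
           call. = FALSE))
  }
  if (rc$input == "files") {
    for (col in c("loadcell_csv", "keypoints_csv", "thermal_dir")) {
      if (is.null(row[[col]]) || is.na(row[[col]]) || !file.exists(row[[col]]))
        stop(sprintf("participant %s: missing input '%s'", pid, col),
             call. = FALSE)
    }
  }

  if (rc$input == "synth") {
    sargs <- c(list(duration_s = rc$duration_s, seed = row$seed,
                    left_share = row$left_share,
                    coupling_gain = row$coupling_gain,
                    body_mass_kg = row$weight_kg),
               rc$synth_args)
    cfg <- stage("synthesis", do.call(synth_config, sargs))
    gt <- stage("synthesis", generate_kinematics(cfg))
    thermal <- stage("synthesis", render_thermal(cfg, gt))
    lc <- stage("synthesis", simulate_loadcells(cfg, gt))
    auto_seq <- stage("extract_auto", sample_frames(thermal, rc$auto_interval_s))
    track <- stage("extract_auto",
                   simulate_tracker(cfg, gt,
                                    frame_index = attr(auto_seq, "source_index")))
  } else {
    thermal <- stage("read_inputs", read_thermal_csv(row$thermal_dir))
    track <- stage("read_inputs", read_keypoints_csv(row$keypoints_csv))
    lc <- stage("read_inputs", read_loadcells_csv(row$loadcell_csv))
    cfg <- NULL; gt <- NULL
    auto_seq <- stage("extract_auto", sample_frames(thermal, rc$auto_interval_s))
  }

  auto_prof <- stage("extract_auto",
                     sample_at_keypoints(auto_seq, track, p_cut = rc$p_cut,
                                         radius_px = rc$radius_px))
  if (rc$input == "synth") {
    semi_prof <- stage("extract_semi",
                       extract_semi(cfg, gt, thermal, rc$semi_interval_s))
  } else {
    stop("file-based semi-automatic extraction needs a ROI annotation file; ",
         "not configured", call. = FALSE)
  }
  ws <- stage("wbb", weight_summary(lc, rc$stand_frac, rc$sit_frac,
                                    rc$asym_threshold,
                                    rc$span_x_mm, rc$span_y_mm))

  heavier <- if (ws$left_share_mean > 0.5) "left" else "right"
  maybe_smooth <- function(p)
    if (rc$smooth_for_match && nrow(p) >= 3)
      smooth_profile(p, rc$span_fraction) else p

  regions <- comparison_regions()
  regs <- list(); bas <- list(); rmse <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions$region[i]
    au <- auto_prof[[regions$auto_zone[i]]]
    se <- semi_prof[[regions$semi_profile[i]]]
    pair <- stage("compare", align_profiles(au, se))
    regs[[rg]] <- fit_linear(pair, rc$strength_threshold)
    bas[[rg]] <- bland_altman(pair)
    rmse[[rg]] <- list(auto = rmse_vs_trend(au), semi = rmse_vs_trend(se))
  }

  match_flag <- function(pl, pr, mode)
    leg_thermal_match(maybe_smooth(pl), maybe_smooth(pr), heavier, mode)$match
  heat_auto <- stage("compare",
    match_flag(auto_prof$LSM, auto_prof$RSM, "heating_SM"))
  heat_semi <- stage("compare",
    match_flag(semi_prof$Lmax, semi_prof$Rmax, "heating_SM"))
  cool_auto <- stage("compare",
    match_flag(auto_prof$LP, auto_prof$RP, "cooling_P"))
  cool_semi <- stage("compare",
    match_flag(semi_prof$Lmin, semi_prof$Rmin, "cooling_P"))

  list(
    participant = pid, gender = row$gender, bmi = row$bmi,
    weight = list(static_weight_kg = ws$static_weight_kg,
                  n_cycles = ws$n_cycles,
                  left_share_mean = ws$left_share_mean,
                  left_share_max = ws$left_share_max,
                  rear_share = ws$rear_share,
                  corner_pct = as.list(ws$corner_pct),
                  asymmetric = ws$asymmetric,
                  heavier_leg = ws$heavier_leg),
    regressions = regs,
    bland_altman = lapply(bas, function(b) b[c("bias", "sd_diff",
                                               "loa_low", "loa_high",
                                               "n_outside")]),
    rmse = rmse,
    labels = list(heating = classify_agreement(heat_semi, heat_auto),
                  cooling = classify_agreement(cool_semi, cool_auto),
                  heating_match = list(semi = heat_semi, auto = heat_auto),
                  cooling_match = list(semi = cool_semi, auto = cool_auto)),
    qc = list(dropped_keypoints = attr(auto_prof, "n_dropped"),
              keypoints_outside = attr(auto_prof, "n_outside"),
              invalid_wbb = ws$n_invalid),
    example = if (rc$keep_example) list(
      semi_profiles = semi_prof, auto_profiles = auto_prof,
      ba_points = lapply(bas, `[[`, "points"),
      wbb = list(t = lc$t, total = total_weight(lc), phase = ws$phase,
                 leg_shares = ws$leg_shares, foot_shares = ws$foot_shares,
                 cop = ws$cop, corner_pct = ws$corner_pct)
    )
  )
}

#' Run the full generate-extract-compare pipeline
#'
#' For each participant: synthesize (or read) thermal video, keypoint
#' track and load-cell record; extract semi-automatic ROI-extrema and
#' automatic keypoint profiles; summarise the balance-board recording;
#' compute the four regional regressions, Bland-Altman analyses, RMSE
#' values and agreement labels; then stratify the cohort. Fully
#' deterministic given the config (including seed).
#'
#' @param rc A [run_config()].
#' @return An `agreement_report`: `participants` (per-participant
#'   records), `measurements` (one row per region x participant),
#'   `cohort` (stratified tables), `config` echo. Written to
#'   `rc$out_dir` as JSON + CSV when set.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  md <- rc$metadata
  participants <- lapply(seq_len(nrow(md)), function(i) {
    res <- process_participant(rc, md[i, ])
    if (rc$keep_example && i > 1) res$example <- NULL
    res
  })
  names(participants) <- md$participant

  regions <- comparison_regions()$region
  measurements <- do.call(rbind, lapply(participants, function(p) {
    asym <- isTRUE(p$weight$asymmetric)
    do.call(rbind, lapply(regions, function(rg)
      data.frame(participant = p$participant, gender = p$gender,
                 bmi = p$bmi, asymmetric = asym, region = rg,
                 r2 = p$regressions[[rg]]$r2,
                 strong = p$regressions[[rg]]$strong,
                 stringsAsFactors = FALSE)))
  }))
  rownames(measurements) <- NULL
  labels <- do.call(rbind, lapply(participants, function(p)
    data.frame(participant = p$participant, gender = p$gender,
               label_heating = p$labels$heating %||% NA_character_,
               label_cooling = p$labels$cooling %||% NA_character_,
               stringsAsFactors = FALSE)))
  rownames(labels) <- NULL
  cohort <- stratify_results(measurements, labels, rc$bmi_cutoff)

  example <- participants[[1]]$example
  participants[[1]]$example <- NULL
  report <- structure(list(
    participants = participants, measurements = measurements,
    labels = labels, cohort = cohort, example = example,
    config = unclass(rc[setdiff(names(rc), c("metadata", "out_dir"))]),
    metadata = md
  ), class = "agreement_report")
  if (!is.null(rc$out_dir)) write_report(report, rc$out_dir)
  report
}

#' Write an agreement report to disk
#'
#' `report.json` (everything scalar), `measurements.csv`,
#' `r2_table.csv`, `label_counts_heating.csv`,
#' `label_counts_cooling.csv`.
#'
#' @param report An `agreement_report`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slim <- report
  slim$example <- NULL
  jsonlite::write_json(slim, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  utils::write.csv(report$measurements,
                   file.path(dir, "measurements.csv"), row.names = FALSE)
  utils::write.csv(report$cohort$r2_table,
                   file.path(dir, "r2_table.csv"), row.names = FALSE)
  if (!is.null(report$cohort$label_counts)) {
    utils::write.csv(report$cohort$label_counts$heating,
                     file.path(dir, "label_counts_heating.csv"),
                     row.names = FALSE)
    utils::write.csv(report$cohort$label_counts$cooling,
                     file.path(dir, "label_counts_cooling.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.agreement_report <- function(x, ...) {
  n <- length(x$participants)
  cat(sprintf("<agreement_report> %d participants, %d measurements\n",
              n, nrow(x$measurements)))
  cat(sprintf("  strong correlations: %d/%d (mean R2 %.2f)\n",
              sum(x$measurements$strong), nrow(x$measurements),
              mean(x$measurements$r2[x$measurements$strong])))
  asym <- vapply(x$participants, function(p)
    isTRUE(p$weight$asymmetric), logical(1))
  cat(sprintf("  asymmetric participants: %d/%d\n", sum(asym), n))
  invisible(x)
}
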