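#' Four-corner load-cell series
#'
#' Per-sample corner loads in kg from a balance board with four load
#' cells, two under each foot. Corners are named from the participant's
#' perspective: `tl`/`tr` top (forefoot) left/right, `bl`/`br` bottom
#' (rearfoot) left/right. Small negative readings from sensor noise are
#' tolerated (clipped to zero wherever shares are formed).
#'
#' @param times Sample times, seconds, strictly increasing.
#' @param tl,tr,bl,br Corner loads, kg.
#' @param rate_hz Nominal acquisition rate.
#' @return A `loadcell_series` data frame (`t`, `tl`, `tr`, `bl`, `br`).
#' @export
loadcell_series <- function(times, tl, tr, bl, br, rate_hz = 20) {
  n <- length(times)
  stopifnot(length(tl) == n, length(tr) == n,
            length(bl) == n, length(br) == n)
  if (n > 1 && any(diff(times) <= 0))
    stop_cfg("times must be strictly increasing")
  out <- data.frame(t = times, tl = tl, tr = tr, bl = bl, br = br)
  attr(out, "rate_hz") <- rate_hz
  class(out) <- c("loadcell_series", "data.frame")
  out
}

#' Total load on the board
#'
#' @param s A [loadcell_series()].
#' @return Numeric vector, `tl + tr + bl + br` per sample, kg.
#' @export
total_weight <- function(s) {
  stopifnot(inherits(s, "loadcell_series"))
  s$tl + s$tr + s$bl + s$br
}

#' Segment sitting / standing / transition phases
#'
#' The static (standing) weight is estimated as the median of the total
#' load over samples above its 75th percentile. Samples with total at or
#' above `stand_frac` of the static weight are `standing`, at or below
#' `sit_frac` are `sitting`, the rest `transition`. A cycle is counted at
#' every sitting-to-standing transition of the definite phase sequence.
#'
#' @param s A [loadcell_series()].
#' @param stand_frac,sit_frac Phase thresholds as fractions of the static
#'   weight; `0 < sit_frac < stand_frac < 1`.
#' @return List: `phase` (character per sample), `static_weight_kg`,
#'   `n_cycles`.
#' @export
segment_phases <- function(s, stand_frac = 0.8, sit_frac = 0.25) {
  stopifnot(inherits(s, "loadcell_series"))
  if (!(0 < sit_frac && sit_frac < stand_frac && stand_frac < 1))
    stop_cfg("need 0 < sit_frac < stand_frac < 1")
  total <- total_weight(s)
  q75 <- stats::quantile(total, 0.75, names = FALSE)
  static <- stats::median(total[total >= q75])
  if (!is.finite(static) || static < 1)
    stop_cfg("no standing phase detected")
  phase <- ifelse(total >= stand_frac * static, "standing",
                  ifelse(total <= sit_frac * static, "sitting",
                         "transition"))
  if (!any(phase == "standing")) stop_cfg("no standing phase detected")
  definite <- phase[phase != "transition"]
  rl <- rle(definite)$values
  n_cycles <- if (length(rl) > 1)
    sum(rl[-1] == "standing" & rl[-length(rl)] == "sitting") else 0L
  list(phase = phase, static_weight_kg = static, n_cycles = n_cycles)
}

#' Per-leg load shares over standing samples
#'
#' Left share is `(tl + bl) / total` with negative corner readings
#' clipped to zero first; computed only where the phase is `standing`.
#' Standing samples with total below 1 kg are marked invalid.
#'
#' @param s A [loadcell_series()].
#' @param phases Output of [segment_phases()].
#' @return Data frame over standing samples: `t`, `left`, `right`,
#'   `valid`.
#' @export
leg_shares <- function(s, phases) {
  stopifnot(inherits(s, "loadcell_series"))
  sel <- phases$phase == "standing"
  tl <- pmax(s$tl[sel], 0); tr <- pmax(s$tr[sel], 0)
  bl <- pmax(s$bl[sel], 0); br <- pmax(s$br[sel], 0)
  total <- tl + tr + bl + br
  valid <- total >= 1
  left <- ifelse(valid, (tl + bl) / total, NA_real_)
  data.frame(t = s$t[sel], left = left, right = 1 - left, valid = valid)
}

#' Fore/rearfoot load shares per leg over standing samples
#'
#' Per leg, the rearfoot share is `rear_cell / (fore_cell + rear_cell)`.
#' Samples where a leg carries less than 0.5 kg are invalid for that leg.
#'
#' @param s A [loadcell_series()].
#' @param phases Output of [segment_phases()].
#' @return Data frame over standing samples: `t`, `rear_left`,
#'   `rear_right`, `valid_left`, `valid_right`.
#' @export
foot_region_shares <- function(s, phases) {
  stopifnot(inherits(s, "loadcell_series"))
  sel <- phases$phase == "standing"
  tl <- pmax(s$tl[sel], 0); tr <- pmax(s$tr[sel], 0)
  bl <- pmax(s$bl[sel], 0); br <- pmax(s$br[sel], 0)
  lt <- tl + bl; rt <- tr + br
  vl <- lt >= 0.5; vr <- rt >= 0.5
  data.frame(t = s$t[sel],
             rear_left = ifelse(vl, bl / lt, NA_real_),
             rear_right = ifelse(vr, br / rt, NA_real_),
             valid_left = vl, valid_right = vr)
}

#' Centre-of-pressure trajectory and corner load percentages
#'
#' Standard corner-moment formula on a rectangular four-cell board:
#' `x = (span_x / 2) * ((tr + br) - (tl + bl)) / total` (medio-lateral,
#' positive right), `y = (span_y / 2) * ((tl + tr) - (bl + br)) / total`
#' (antero-posterior, positive forward); (0, 0) is the board centre.
#' Samples with total below 1 kg are flagged invalid. Default spans are
#' the published balance-board sensor spacing, 433 x 238 mm.
#'
#' @param s A [loadcell_series()].
#' @param span_x_mm,span_y_mm Distances between cell centres, mm.
#' @param phases Optional [segment_phases()] output; if supplied,
#'   `corner_pct` integrates standing samples only (otherwise all valid
#'   samples).
#' @return List: `cop` data frame (`t`, `x_mm`, `y_mm`, `valid`) and
#'   `corner_pct` (named fractions `tl`, `tr`, `bl`, `br` summing to 1).
#' @export
cop <- function(s, span_x_mm = 433, span_y_mm = 238, phases = NULL) {
  stopifnot(inherits(s, "loadcell_series"))
  if (span_x_mm <= 0 || span_y_mm <= 0) stop_cfg("spans must be > 0")
  total <- total_weight(s)
  valid <- total >= 1
  x <- ifelse(valid, (span_x_mm / 2) * ((s$tr + s$br) - (s$tl + s$bl)) / total,
              NA_real_)
  y <- ifelse(valid, (span_y_mm / 2) * ((s$tl + s$tr) - (s$bl + s$br)) / total,
              NA_real_)
  sel <- if (is.null(phases)) valid else (phases$phase == "standing" & valid)
  corners <- c(tl = sum(pmax(s$tl[sel], 0)), tr = sum(pmax(s$tr[sel], 0)),
               bl = sum(pmax(s$bl[sel], 0)), br = sum(pmax(s$br[sel], 0)))
  corner_pct <- corners / sum(corners)
  list(cop = data.frame(t = s$t, x_mm = x, y_mm = y, valid = valid),
       corner_pct = corner_pct)
}

#' Weight-bearing asymmetry flag
#'
#' A participant is asymmetric when either leg's mean standing share
#' strictly exceeds `threshold` (default 52%).
#'
#' @param left_share Mean standing left-leg share in [0, 1].
#' @param threshold Asymmetry threshold, fraction.
#' @return List: `asymmetric` (logical), `heavier_leg` (`"left"`,
#'   `"right"` or `"none"`), `share` (the heavier leg's share).
#' @export
asymmetry_flag <- function(left_share, threshold = 0.52) {
  share <- max(left_share, 1 - left_share)
  asym <- share > threshold
  heavier <- if (!asym) "none" else if (left_share > 0.5) "left" else "right"
  list(asymmetric = asym, heavier_leg = heavier, share = share)
}

#' Summarise a balance-board recording
#'
#' Runs phase segmentation, leg and foot-region shares, CoP and the
#' asymmetry flag, and gathers participant-level summaries.
#'
#' @param s A [loadcell_series()].
#' @param stand_frac,sit_frac Passed to [segment_phases()].
#' @param asym_threshold Passed to [asymmetry_flag()].
#' @param span_x_mm,span_y_mm Passed to [cop()].
#' @return A `weight_summary` list: `static_weight_kg`, `n_cycles`,
#'   `left_share_mean`, `left_share_max` (max per-leg fraction over
#'   standing samples), `rear_share` (mean over both legs), `corner_pct`,
#'   `asymmetric`, `heavier_leg`, `n_invalid` plus the per-sample tables.
#' @export
weight_summary <- function(s, stand_frac = 0.8, sit_frac = 0.25,
                           asym_threshold = 0.52,
                           span_x_mm = 433, span_y_mm = 238) {
  ph <- segment_phases(s, stand_frac, sit_frac)
  ls <- leg_shares(s, ph)
  fs <- foot_region_shares(s, ph)
  cp <- cop(s, span_x_mm, span_y_mm, phases = ph)
  left_mean <- mean(ls$left[ls$valid], na.rm = TRUE)
  per_leg_max <- max(c(ls$left[ls$valid], ls$right[ls$valid]), na.rm = TRUE)
  rear <- mean(c(fs$rear_left[fs$valid_left], fs$rear_right[fs$valid_right]),
               na.rm = TRUE)
  flag <- asymmetry_flag(left_mean, asym_threshold)
  structure(list(
    static_weight_kg = ph$static_weight_kg,
    n_cycles = ph$n_cycles,
    left_share_mean = left_mean,
    left_share_max = per_leg_max,
    rear_share = rear,
    corner_pct = cp$corner_pct,
    asymmetric = flag$asymmetric,
    heavier_leg = flag$heavier_leg,
    n_invalid = sum(!ls$valid),
    phase = ph$phase,
    leg_shares = ls,
    foot_shares = fs,
    cop = cp$cop
  ), class = "weight_summary")
}

#' @export
print.weight_summary <- function(x, ...) {
  cat("<weight_summary>\n")
  cat(sprintf("  static weight %.1f kg, %d cycles\n",
              x$static_weight_kg, x$n_cycles))
  cat(sprintf("  mean left share %.3f (max per-leg %.3f), rear share %.3f\n",
              x$left_share_mean, x$left_share_max, x$rear_share))
  cat(sprintf("  asymmetric: %s (heavier leg: %s)\n",
              x$asymmetric, x$heavier_leg))
  invisible(x)
}

# ---- on-disk formats -------------------------------------------------------

#' Write / read a load-cell series CSV
#'
#' Columns `t_s`, `TL_kg`, `TR_kg`, `BL_kg`, `BR_kg`.
#'
#' @param s A [loadcell_series()].
#' @param path Output CSV path.
#' @param rate_hz Acquisition rate recorded on read.
#' @return `write_loadcells_csv` the path, invisibly;
#'   `read_loadcells_csv` a [loadcell_series()].
#' @export
write_loadcells_csv <- function(s, path) {
  utils::write.csv(data.frame(t_s = s$t, TL_kg = s$tl, TR_kg = s$tr,
                              BL_kg = s$bl, BR_kg = s$br),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_loadcells_csv
#' @export
read_loadcells_csv <- function(path, rate_hz = NULL) {
  d <- utils::read.csv(path)
  rate <- rate_hz %||% (1 / stats::median(diff(d$t_s)))
  loadcell_series(d$t_s, d$TL_kg, d$TR_kg, d$BL_kg, d$BR_kg, rate_hz = rate)
}
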