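#' Align an automatic profile onto a semi-automatic time grid
#'
#' The automatic method yields a dense (about 1 Hz) series while the
#' semi-automatic method yields sparse discrete readings; the automatic
#' series is linearly interpolated onto the semi-automatic timestamps.
#' Semi-automatic points outside the automatic coverage are dropped (no
#' edge extrapolation) and counted.
#'
#' @param auto,semi [zone_profile()]s; `auto` should cover `semi`'s range.
#' @return A `paired_series` data frame: `t_s`, `a` (semi-automatic),
#'   `b` (interpolated automatic); attribute `n_dropped` counts grid
#'   points outside coverage. Errors if fewer than 3 points overlap.
#' @export
align_profiles <- function(auto, semi) {
  stopifnot(inherits(auto, "zone_profile"), inherits(semi, "zone_profile"))
  inside <- semi$t_s >= min(auto$t_s) & semi$t_s <= max(auto$t_s)
  n_dropped <- sum(!inside)
  if (sum(inside) < 3)
    stop_cfg("fewer than 3 overlapping points between the two profiles")
  b <- stats::approx(auto$t_s, auto$temp_c, xout = semi$t_s[inside],
                     method = "linear", rule = 1)$y
  out <- data.frame(t_s = semi$t_s[inside], a = semi$temp_c[inside], b = b)
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("paired_series", "data.frame")
  out
}

#' Ordinary least squares fit between two methods
#'
#' Fits `b ~ a` by OLS and reports the coefficient of determination
#' `R^2 = 1 - SSres / SStot`. A comparison is labelled "strong" when
#' `R^2` reaches `strength_threshold`.
#'
#' @param p A `paired_series` from [align_profiles()] (or any data frame
#'   with columns `a`, `b`), at least 3 points.
#' @param strength_threshold `R^2` cutoff for a strong correlation.
#' @return List: `slope`, `intercept`, `r2`, `strong`, `n`.
#' @export
fit_linear <- function(p, strength_threshold = 0.5) {
  if (nrow(p) < 3) stop_cfg("need at least 3 paired points")
  if (stats::var(p$a) <= 0)
    stop_cfg("zero variance in the reference series; R^2 undefined")
  fit <- stats::lm(b ~ a, data = p)
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((p$b - mean(p$b))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, strong = r2 >= strength_threshold, n = nrow(p))
}

#' RMSE of a profile about its own linear trend
#'
#' Root-mean-square residual of the temperature series about the OLS line
#' in time: near 0 for a clean linear drift, larger for noisy or
#' non-monotone series.
#'
#' @param p A [zone_profile()] with at least 3 points.
#' @return RMSE in degC.
#' @export
rmse_vs_trend <- function(p) {
  stopifnot(inherits(p, "zone_profile"))
  if (nrow(p) < 3) stop_cfg("need at least 3 points")
  if (stats::var(p$t_s) == 0) return(0)
  res <- stats::residuals(stats::lm(temp_c ~ t_s, data = p))
  sqrt(mean(res^2))
}

#' Bland-Altman agreement analysis
#'
#' Differences `b - a`: bias is their mean, limits of agreement are
#' `bias +/- 1.96 * sd` (sample sd, n - 1 denominator). Per-point
#' (mean, difference) coordinates are returned for plotting.
#'
#' @param p A `paired_series` (or data frame with `a`, `b`), >= 3 points.
#' @return List: `bias`, `sd_diff`, `loa_low`, `loa_high`, `n_outside`,
#'   `points` (data frame `mean`, `diff`).
#' @export
bland_altman <- function(p) {
  if (nrow(p) < 3) stop_cfg("need at least 3 paired points")
  d <- p$b - p$a
  m <- (p$a + p$b) / 2
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * sdd
  list(bias = bias, sd_diff = sdd, loa_low = loa[1], loa_high = loa[2],
       n_outside = sum(d < loa[1] | d > loa[2]),
       points = data.frame(mean = m, diff = d))
}

#' Classify inter-method agreement
#'
#' Each method either does or does not match the heavier-loaded leg to
#' the most thermally responsive leg. Both matching gives `AG`
#' (agreement), neither gives `NAG` (disagreement, alias `DAG`), exactly
#' one gives `PAG` (partial agreement). Symmetric in its arguments.
#'
#' @param method1_match,method2_match Logical flags (NA propagates).
#' @return `"AG"`, `"NAG"` or `"PAG"` (NA if either flag is NA).
#' @export
classify_agreement <- function(method1_match, method2_match) {
  if (is.na(method1_match) || is.na(method2_match)) return(NA_character_)
  if (method1_match && method2_match) "AG"
  else if (!method1_match && !method2_match) "NAG"
  else "PAG"
}

# OLS slope of a profile in degC per minute.
profile_slope <- function(p) {
  if (nrow(p) < 2 || stats::var(p$t_s) == 0) return(NA_real_)
  unname(stats::coef(stats::lm(temp_c ~ I(t_s / 60), data = p))[2])
}

#' Does the most thermally responsive leg match the heavier leg?
#'
#' Heating mode compares the SM (medial-ligament region) warming slopes
#' of the two legs and picks the larger; cooling mode compares the
#' patella slopes and picks the more negative. The flag is whether that
#' leg equals the heavier-loaded leg. Slopes within 1e-6 degC/min are an
#' indeterminate tie (NA with a warning).
#'
#' @param profile_left,profile_right [zone_profile()]s for the comparison
#'   zone of each leg (typically smoothed).
#' @param heavier_leg `"left"` or `"right"`.
#' @param mode `"heating_SM"` or `"cooling_P"`.
#' @return List: `match` (logical or NA), `responsive_leg`,
#'   `slope_left`, `slope_right` (degC/min).
#' @export
leg_thermal_match <- function(profile_left, profile_right, heavier_leg,
                              mode = c("heating_SM", "cooling_P")) {
  mode <- match.arg(mode)
  stopifnot(heavier_leg %in% c("left", "right"))
  if (nrow(profile_left) == 0 || nrow(profile_right) == 0)
    stop_cfg("both legs need a nonempty profile")
  sl <- profile_slope(profile_left)
  sr <- profile_slope(profile_right)
  if (abs(sl - sr) < 1e-6) {
    warning("slope tie within 1e-6 degC/min; match indeterminate")
    return(list(match = NA, responsive_leg = NA_character_,
                slope_left = sl, slope_right = sr))
  }
  responsive <- if (mode == "heating_SM") {
    if (sl > sr) "left" else "right"
  } else {
    if (sl < sr) "left" else "right"   # larger-magnitude cooling
  }
  list(match = responsive == heavier_leg, responsive_leg = responsive,
       slope_left = sl, slope_right = sr)
}

#' Stratified cohort summary of inter-method correlation
#'
#' Groups per-measurement regression results by gender, BMI group and
#' weight-bearing asymmetry, reporting mean and sd of `R^2` among the
#' strongly correlated measurements in each group, plus agreement-label
#' counts per gender.
#'
#' @param measurements Data frame with one row per measurement:
#'   `participant`, `gender` (`"M"`/`"F"`), `bmi`, `asymmetric`
#'   (logical), `r2`, `strong` (logical).
#' @param labels Optional data frame with one row per participant:
#'   `participant`, `gender`, `label_heating`, `label_cooling`.
#' @param bmi_cutoff BMI group boundary, kg/m^2.
#' @return List: `r2_table` (one row per group: n, mean, sd of strong
#'   `R^2`; single-member groups get `NA` sd; empty groups are absent)
#'   and `label_counts` (per gender x mode AG/NAG/PAG counts, or NULL).
#' @export
stratify_results <- function(measurements, labels = NULL, bmi_cutoff = 25) {
  m <- measurements
  groups <- list(
    all = rep(TRUE, nrow(m)),
    W = m$gender == "F",
    M = m$gender == "M",
    bmi_high = m$bmi >= bmi_cutoff,
    bmi_low = m$bmi < bmi_cutoff,
    balanced = !m$asymmetric,
    not_balanced = m$asymmetric
  )
  rows <- lapply(names(groups), function(g) {
    sel <- groups[[g]] & m$strong
    if (!any(sel)) return(NULL)
    r2 <- m$r2[sel]
    data.frame(group = g, n = length(r2), r2_mean = mean(r2),
               r2_sd = if (length(r2) > 1) stats::sd(r2) else NA_real_)
  })
  r2_table <- do.call(rbind, rows)
  label_counts <- NULL
  if (!is.null(labels)) {
    tab <- lapply(c("label_heating", "label_cooling"), function(col) {
      lv <- factor(labels[[col]], levels = c("AG", "NAG", "PAG"))
      as.data.frame(table(gender = labels$gender, label = lv,
                          dnn = c("gender", "label")),
                    responseName = "count")
    })
    names(tab) <- c("heating", "cooling")
    label_counts <- tab
  }
  list(r2_table = r2_table, label_counts = label_counts)
}
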