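# Small-frame configs keep rendering cheap; the zone layout still fits.
fast_cfg <- function(...) {
  args <- list(...)
  base <- list(duration_s = 60, width_px = 288, height_px = 160, seed = 1L)
  do.call(synth_config, utils::modifyList(base, args))
}

# Fully deterministic variant: no thermal, tracker or load-cell noise.
noiseless_cfg <- function(...) {
  args <- list(...)
  base <- list(thermal_noise_c = 0, tracker_rms_px = 0, dropout_prob = 0,
               likelihood_mean = 1, loadcell_noise_kg = 0)
  do.call(fast_cfg, utils::modifyList(base, args))
}

# ---- independent oracles ---------------------------------------------------

# Exhaustive pixel scan over an ROI clipped to the frame (row-major ties).
oracle_roi_extrema <- function(frame, x0, y0, w, h) {
  hh <- nrow(frame); ww <- ncol(frame)
  best_max <- -Inf; best_min <- Inf
  arg_max <- arg_min <- NULL
  for (y in max(0, y0):min(hh - 1, y0 + h - 1)) {
    for (x in max(0, x0):min(ww - 1, x0 + w - 1)) {
      v <- frame[y + 1, x + 1]
      if (v > best_max) { best_max <- v; arg_max <- c(x, y) }
      if (v < best_min) { best_min <- v; arg_min <- c(x, y) }
    }
  }
  list(t_max = best_max, t_min = best_min,
       argmax_px = arg_max, argmin_px = arg_min)
}

# Closed-form simple OLS of b on a.
oracle_ols <- function(a, b) {
  am <- mean(a); bm <- mean(b)
  slope <- sum((a - am) * (b - bm)) / sum((a - am)^2)
  intercept <- bm - slope * am
  res <- b - (intercept + slope * a)
  r2 <- 1 - sum(res^2) / sum((b - bm)^2)
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Direct Bland-Altman arithmetic.
oracle_bland_altman <- function(a, b) {
  d <- b - a
  bias <- sum(d) / length(d)
  sdd <- sqrt(sum((d - bias)^2) / (length(d) - 1))
  list(bias = bias, loa_low = bias - 1.96 * sdd, loa_high = bias + 1.96 * sdd)
}

# Cycle count as standing plateaus (u > 0.75) that follow a sitting dwell
# (u < 0.25), counted from the raw excursion signal via run-length
# encoding of a three-level quantisation.
oracle_cycle_count <- function(u) {
  lev <- ifelse(u > 0.75, "hi", ifelse(u < 0.25, "lo", "mid"))
  r <- rle(lev)$values
  r <- r[r != "mid"]
  if (length(r) < 2) return(0L)
  sum(r[-1] == "hi" & r[-length(r)] == "lo")
}
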