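#' Rectangular region of interest
#'
#' 0-based, inclusive top-left corner and size in pixels, mirroring the
#' rectangle an operator draws on each thermogram.
#'
#' @param x0,y0 Top-left pixel (0-based).
#' @param w,h Width and height in pixels (>= 1).
#' @return A `rect_roi` object.
#' @export
rect_roi <- function(x0, y0, w, h) {
  if (w < 1 || h < 1) stop_cfg("ROI must be at least 1 x 1 px")
  structure(list(x0 = x0, y0 = y0, w = w, h = h), class = "rect_roi")
}

#' Maximum and minimum temperature inside an ROI
#'
#' Scans the pixels of `roi` clipped to the frame and reports the extreme
#' temperatures with their positions in full-frame 0-based coordinates.
#' Ties are broken by row-major (top-to-bottom, left-to-right within a
#' row) first occurrence.
#'
#' @param frame Temperature matrix (`height x width`), degC.
#' @param roi A [rect_roi()]; must intersect the frame.
#' @return List `t_max`, `t_min` (degC), `argmax_px`, `argmin_px`
#'   (each `c(x, y)`).
#' @export
roi_extrema <- function(frame, roi) {
  stopifnot(inherits(roi, "rect_roi"))
  h <- nrow(frame); w <- ncol(frame)
  xs <- max(0, roi$x0):min(w - 1, roi$x0 + roi$w - 1)
  ys <- max(0, roi$y0):min(h - 1, roi$y0 + roi$h - 1)
  if (roi$x0 + roi$w - 1 < 0 || roi$x0 > w - 1 ||
      roi$y0 + roi$h - 1 < 0 || roi$y0 > h - 1)
    stop_cfg("ROI does not intersect the frame")
  sub <- frame[ys + 1, xs + 1, drop = FALSE]
  tsub <- t(sub)                       # row-major scan order
  locate <- function(p) {
    nc <- nrow(tsub)                   # = ncol(sub)
    sub_col <- (p - 1) %% nc + 1
    sub_row <- (p - 1) %/% nc + 1
    c(x = xs[sub_col], y = ys[sub_row])
  }
  pmax <- which.max(tsub); pmin <- which.min(tsub)
  list(t_max = tsub[pmax], t_min = tsub[pmin],
       argmax_px = locate(pmax), argmin_px = locate(pmin))
}

#' Translate an ROI, emulating per-frame operator repositioning
#'
#' @param roi A [rect_roi()].
#' @param displacement_px `c(dx, dy)` in pixels (externally supplied, e.g.
#'   from ground-truth knee motion or a manual annotation file).
#' @param frame_width,frame_height Frame size, to reject a displacement
#'   that pushes the ROI fully off-image.
#' @return The translated [rect_roi()], same size.
#' @export
track_roi <- function(roi, displacement_px, frame_width, frame_height) {
  stopifnot(inherits(roi, "rect_roi"), length(displacement_px) == 2)
  out <- rect_roi(roi$x0 + displacement_px[1], roi$y0 + displacement_px[2],
                  roi$w, roi$h)
  if (out$x0 + out$w - 1 < 0 || out$x0 > frame_width - 1 ||
      out$y0 + out$h - 1 < 0 || out$y0 > frame_height - 1)
    stop_cfg("displaced ROI leaves the frame entirely")
  out
}

#' Per-zone temperature time series
#'
#' @param times Sample times, seconds, increasing.
#' @param temps_c Temperatures, degC.
#' @param zone Zone code (see [knee_zones()]) or a method-specific label
#'   such as `"Rmax"`.
#' @param method One of `"semi_automatic_max"`, `"semi_automatic_min"`,
#'   `"automatic"`.
#' @param smoothed Whether the series has been smoothed.
#' @return A `zone_profile` data frame (`t_s`, `temp_c`) with metadata
#'   attributes.
#' @export
zone_profile <- function(times, temps_c, zone, method, smoothed = FALSE) {
  stopifnot(length(times) == length(temps_c))
  if (length(times) > 1 && any(diff(times) <= 0))
    stop_cfg("profile times must be strictly increasing")
  structure(data.frame(t_s = times, temp_c = temps_c),
            zone = zone, method = method, smoothed = smoothed,
            class = c("zone_profile", "data.frame"))
}

#' Sample zone temperatures at tracked keypoints
#'
#' For every frame of `seq` and every zone whose likelihood clears
#' `p_cut`, the temperature is the mean over the
#' `(2 * radius_px + 1)^2` pixel window centred at the keypoint rounded
#' to the nearest pixel, the window clipped to the frame. `radius_px = 0`
#' samples the single nearest pixel. Entries below `p_cut` are omitted
#' from that zone's profile (not interpolated); keypoints that round to a
#' position outside the frame are omitted and counted.
#'
#' @param seq A [thermal_seq].
#' @param track A `keypoint_track` (see [simulate_tracker()] or
#'   [read_keypoints_csv()]) aligned to `seq` by timestamp.
#' @param p_cut Likelihood cutoff in [0, 1].
#' @param radius_px Half-width of the sampling window, pixels.
#' @return Named list of [zone_profile()]s (method `"automatic"`), with
#'   attributes `n_dropped` (likelihood below `p_cut`) and `n_outside`
#'   (rounded keypoint off-frame).
#' @export
sample_at_keypoints <- function(seq, track, p_cut = 0.5, radius_px = 1L) {
  stopifnot(inherits(seq, "thermal_seq"))
  if (p_cut < 0 || p_cut > 1) stop_cfg("p_cut must be in [0, 1]")
  if (radius_px < 0) stop_cfg("radius_px must be >= 0")
  ts <- seq$timestamps
  tol <- if (length(ts) > 1) min(diff(ts)) / 2 else 0.5
  # assign each track row to the nearest sequence frame, if close enough
  pos <- findInterval(track$time, ts)
  lo <- pmax(pos, 1)
  hi <- pmin(pos + 1, length(ts))
  near <- ifelse(abs(track$time - ts[lo]) <= abs(ts[hi] - track$time), lo, hi)
  ok <- abs(track$time - ts[near]) <= tol
  zones <- unique(track$zone)
  acc <- lapply(zones, function(z) list(t = numeric(0), v = numeric(0)))
  names(acc) <- zones
  n_dropped <- 0L; n_outside <- 0L
  w <- seq$width; h <- seq$height
  for (fi in sort(unique(near[ok]))) {
    rows <- which(ok & near == fi)
    keep <- track$likelihood[rows] >= p_cut
    n_dropped <- n_dropped + sum(!keep)
    rows <- rows[keep]
    if (!length(rows)) next
    frame <- get_frame(seq, fi)
    for (ri in rows) {
      px <- round_half_up(track$x[ri]); py <- round_half_up(track$y[ri])
      if (px < 0 || px > w - 1 || py < 0 || py > h - 1) {
        n_outside <- n_outside + 1L
        next
      }
      xs <- max(0, px - radius_px):min(w - 1, px + radius_px)
      ys <- max(0, py - radius_px):min(h - 1, py + radius_px)
      val <- mean(frame[ys + 1, xs + 1])
      z <- track$zone[ri]
      acc[[z]]$t <- c(acc[[z]]$t, ts[fi])
      acc[[z]]$v <- c(acc[[z]]$v, val)
    }
  }
  if (n_outside > 0)
    warning(sprintf("%d keypoint(s) rounded outside the frame were omitted",
                    n_outside))
  out <- lapply(zones, function(z)
    zone_profile(acc[[z]]$t, acc[[z]]$v, zone = z, method = "automatic"))
  names(out) <- zones
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_outside") <- n_outside
  out
}

# Robust locally weighted linear regression (MATLAB-style 'rlowess'):
# for each point, a weighted linear fit over its k nearest neighbours
# (tricube distance weights), then `iters` reweighting passes with
# bisquare robustness weights computed from r / (6 * median|r|). When the
# residuals are already negligible the robustness pass is skipped, so an
# exact line is reproduced exactly.
robust_lowess <- function(x, y, k, iters = 5) {
  n <- length(y)
  k <- max(2L, min(as.integer(k), n))
  fit <- numeric(n)
  rw <- rep(1, n)
  # contiguous k-windows on sorted x, two-pointer
  win_lo <- integer(n)
  l <- 1L
  for (i in seq_len(n)) {
    while (l + k - 1L < n && (x[i] - x[l]) > (x[l + k] - x[i])) l <- l + 1L
    win_lo[i] <- l
  }
  for (it in 0:iters) {
    for (i in seq_len(n)) {
      o <- win_lo[i]:(win_lo[i] + k - 1L)
      d <- abs(x[o] - x[i])
      dmax <- max(d)
      wt <- if (dmax > 0) (1 - pmin(d / dmax, 1)^3)^3 else rep(1, k)
      w <- wt * rw[o]
      if (sum(w) <= 0) {
        # every neighbour was flagged as an outlier (a spike's own window
        # after reweighting): refit from the k nearest clean points
        clean <- which(rw > 0)
        if (length(clean)) {
          o <- clean[order(abs(x[clean] - x[i]))]
          o <- o[seq_len(min(k, length(o)))]
          d <- abs(x[o] - x[i]); dmax <- max(d)
          w <- if (dmax > 0) (1 - pmin(d / dmax, 1)^3)^3 else rep(1, length(o))
        } else {
          w <- wt
        }
      }
      sw <- sum(w)
      xm <- sum(w * x[o]) / sw
      ym <- sum(w * y[o]) / sw
      dx <- x[o] - xm
      sxx <- sum(w * dx * dx)
      slope <- if (sxx > 0) sum(w * dx * (y[o] - ym)) / sxx else 0
      fit[i] <- ym + slope * (x[i] - xm)
    }
    if (it == iters) break
    res <- y - fit
    scale_y <- max(abs(y), 1)
    if (max(abs(res)) <= 1e-9 * scale_y) break   # tight everywhere
    s6 <- 6 * stats::median(abs(res))
    if (s6 <= 0) s6 <- 1e-12 * scale_y
    rw <- (1 - pmin(abs(res) / s6, 1)^2)^2
  }
  fit
}

#' Robust lowess smoothing of a temperature profile
#'
#' Locally weighted linear regression over a window of
#' `max(2, ceiling(span_fraction * n))` nearest points with tricube
#' distance weights and bisquare robustness reweighting, evaluated on the
#' profile's own time grid. The default 2% span suppresses single-frame
#' outlier spikes while leaving the overall trend intact; an exactly
#' linear profile passes through unchanged.
#'
#' @param p A [zone_profile()] with at least 3 points (shorter profiles
#'   are returned unsmoothed with a warning).
#' @param span_fraction Window size as a fraction of the series length,
#'   in (0, 1].
#' @return A smoothed [zone_profile()] (`smoothed = TRUE`).
#' @export
smooth_profile <- function(p, span_fraction = 0.02) {
  stopifnot(inherits(p, "zone_profile"))
  if (span_fraction <= 0 || span_fraction > 1)
    stop_cfg("span_fraction must be in (0, 1]")
  n <- nrow(p)
  if (n < 3) {
    warning("fewer than 3 points; profile returned unsmoothed")
    return(p)
  }
  k <- max(2L, ceiling(span_fraction * n))
  sm <- robust_lowess(p$t_s, p$temp_c, k)
  zone_profile(p$t_s, sm, zone = attr(p, "zone"),
               method = attr(p, "method"), smoothed = TRUE)
}

# ---- on-disk formats -------------------------------------------------------

#' Write / read keypoint tracks in a DeepLabCut-style CSV layout
#'
#' Wide CSV with three header rows -- zone names, coordinate labels
#' (`x`, `y`, `likelihood`), units -- and one data row per frame.
#'
#' @param track A `keypoint_track` data frame.
#' @param path Output CSV path.
#' @return `write_keypoints_csv` the path, invisibly;
#'   `read_keypoints_csv` a `keypoint_track` data frame.
#' @export
write_keypoints_csv <- function(track, path) {
  zones <- unique(track$zone)
  frames <- sort(unique(track$frame))
  header1 <- c("frame", "time", rep(zones, each = 3))
  header2 <- c("", "", rep(c("x", "y", "likelihood"), length(zones)))
  header3 <- c("index", "s", rep(c("px", "px", "fraction"), length(zones)))
  wide <- matrix(NA_real_, length(frames), 3 * length(zones))
  tsec <- numeric(length(frames))
  fmap <- match(track$frame, frames)
  zmap <- match(track$zone, zones)
  for (r in seq_len(nrow(track))) {
    j <- (zmap[r] - 1) * 3
    wide[fmap[r], j + 1] <- track$x[r]
    wide[fmap[r], j + 2] <- track$y[r]
    wide[fmap[r], j + 3] <- track$likelihood[r]
    tsec[fmap[r]] <- track$time[r]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(header1, collapse = ","),
               paste(header2, collapse = ","),
               paste(header3, collapse = ",")), con)
  utils::write.table(cbind(frames, tsec, wide), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_keypoints_csv
#' @export
read_keypoints_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  h1 <- strsplit(hdr[1], ",")[[1]]
  zones <- unique(h1[-(1:2)])
  dat <- utils::read.csv(path, skip = 3, header = FALSE)
  nf <- nrow(dat)
  out <- do.call(rbind, lapply(seq_along(zones), function(zi) {
    j <- 2 + (zi - 1) * 3
    data.frame(frame = dat[[1]], time = dat[[2]], zone = zones[zi],
               x = dat[[j + 1]], y = dat[[j + 2]],
               likelihood = dat[[j + 3]], stringsAsFactors = FALSE)
  }))
  out <- out[order(out$frame, match(out$zone, zones)), ]
  rownames(out) <- NULL
  class(out) <- c("keypoint_track", "data.frame")
  out
}

#' Write / read zone profiles as a long CSV
#'
#' Columns `t_s`, `temp_c`, `zone`, `method`, `smoothed`.
#'
#' @param profiles A [zone_profile()] or named list of them.
#' @param path Output CSV path.
#' @return `write_zone_profiles` the path, invisibly;
#'   `read_zone_profiles` a named list of [zone_profile()]s.
#' @export
write_zone_profiles <- function(profiles, path) {
  if (inherits(profiles, "zone_profile")) profiles <- list(profiles)
  long <- do.call(rbind, lapply(profiles, function(p)
    data.frame(t_s = p$t_s, temp_c = p$temp_c,
               zone = attr(p, "zone"), method = attr(p, "method"),
               smoothed = attr(p, "smoothed"))))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_zone_profiles
#' @export
read_zone_profiles <- function(path) {
  long <- utils::read.csv(path)
  keys <- unique(long[, c("zone", "method")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- long$zone == keys$zone[i] & long$method == keys$method[i]
    zone_profile(long$t_s[sel], long$temp_c[sel], zone = keys$zone[i],
                 method = keys$method[i], smoothed = long$smoothed[sel][1])
  })
  names(out) <- keys$zone
  out
}
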