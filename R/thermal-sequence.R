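#' Thermal image sequence
#'
#' An ordered stack of 2-D temperature grids (degC) with per-frame
#' timestamps. Frames are `height x width` matrices indexed
#' `frame[y + 1, x + 1]` with 0-based pixel coordinates, origin top-left,
#' y increasing downward. A sequence is backed either by a list of
#' materialised matrices or by a renderer function (lazy), so long
#' high-rate acquisitions need not be held in memory.
#'
#' @param timestamps Strictly increasing frame times, seconds from start.
#' @param width,height Frame size in pixels.
#' @param frames Optional list of frame matrices (`height x width`).
#' @param renderer Optional `function(i)` returning frame `i`.
#' @return A `thermal_seq` object.
#' @export
thermal_seq <- function(timestamps, width, height,
                        frames = NULL, renderer = NULL) {
  if (is.null(frames) && is.null(renderer))
    stop_cfg("thermal_seq needs frames or a renderer")
  if (any(diff(timestamps) <= 0))
    stop_cfg("timestamps must be strictly increasing")
  if (!is.null(frames)) {
    stopifnot(length(frames) == length(timestamps))
    dims <- vapply(frames, dim, integer(2))
    if (any(dims[1, ] != height) || any(dims[2, ] != width))
      stop_cfg("all frames must be %d x %d", height, width)
  }
  structure(list(timestamps = timestamps,
                 width = as.integer(width), height = as.integer(height),
                 frames = frames, renderer = renderer),
            class = "thermal_seq")
}

#' @export
length.thermal_seq <- function(x) length(x$timestamps)

#' Fetch one frame of a thermal sequence
#'
#' @param seq A [thermal_seq].
#' @param i Frame index (1-based).
#' @return `height x width` temperature matrix, degC.
#' @export
get_frame <- function(seq, i) {
  stopifnot(inherits(seq, "thermal_seq"), i >= 1, i <= length(seq))
  if (!is.null(seq$frames) && !is.null(seq$frames[[i]]))
    return(seq$frames[[i]])
  seq$renderer(i)
}

#' @export
print.thermal_seq <- function(x, ...) {
  cat(sprintf("<thermal_seq> %d frames, %d x %d px, %.2f-%.2f s%s\n",
              length(x), x$width, x$height,
              x$timestamps[1], x$timestamps[length(x)],
              if (is.null(x$frames)) " (lazy)" else ""))
  invisible(x)
}

# Nominal total span of a regularly acquired sequence: n * dt, so a 600 s
# run sampled at 20 Hz (last timestamp 599.95) still spans 600 s.
seq_span <- function(seq) {
  n <- length(seq)
  if (n < 2) return(if (n == 1) seq$timestamps[1] else 0)
  dt <- stats::median(diff(seq$timestamps))
  seq$timestamps[1] + n * dt
}

#' Subsample a thermal sequence at a fixed interval
#'
#' Picks the acquired frame nearest each target time `interval_s`,
#' `2*interval_s`, ... up to the nominal span of the sequence. The t = 0
#' frame is not a target, so a 600 s run subsampled every 30 s yields
#' exactly 20 frames, and every 1 s yields 600. Ties between two equally
#' near frames go to the earlier one.
#'
#' @param seq A [thermal_seq].
#' @param interval_s Sampling interval, seconds; must be no shorter than
#'   the acquisition spacing.
#' @return A [thermal_seq] holding the selected frames (still lazy if the
#'   input was); the original frame indices are kept in attribute
#'   `"source_index"`.
#' @export
sample_frames <- function(seq, interval_s) {
  stopifnot(inherits(seq, "thermal_seq"))
  if (interval_s <= 0) stop_cfg("interval_s must be > 0")
  dt <- if (length(seq) > 1) stats::median(diff(seq$timestamps)) else Inf
  if (interval_s < dt - 1e-9)
    stop_cfg("interval_s (%g s) is shorter than the frame spacing (%g s)",
             interval_s, dt)
  span <- seq_span(seq)
  targets <- seq(interval_s, by = interval_s,
                 length.out = max(0, floor(span / interval_s + 1e-9)))
  if (!length(targets)) {
    warning("interval exceeds sequence duration; no frames sampled")
    idx <- integer(0)
  } else {
    idx <- vapply(targets, function(tt)
      which.min(abs(seq$timestamps - tt)), integer(1))
  }
  out <- thermal_seq(
    timestamps = seq$timestamps[idx],
    width = seq$width, height = seq$height,
    frames = if (!is.null(seq$frames)) seq$frames[idx],
    renderer = if (!is.null(seq$renderer)) {
      parent <- seq$renderer
      function(j) parent(idx[j])
    }
  )
  attr(out, "source_index") <- idx
  out
}

# ---- on-disk formats -------------------------------------------------------

#' Write / read a thermal sequence as a one-CSV-per-frame directory
#'
#' `frame_000001.csv` ... hold the raw temperature grids (no header);
#' `timestamps.csv` holds frame index and time.
#'
#' @param seq A [thermal_seq].
#' @param dir Target directory (created).
#' @return `write_thermal_csv` the directory, invisibly;
#'   `read_thermal_csv` a materialised [thermal_seq].
#' @export
write_thermal_csv <- function(seq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(length(seq))) {
    utils::write.table(get_frame(seq, i),
                       file.path(dir, sprintf("frame_%06d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(data.frame(frame = seq_len(length(seq)),
                              t_s = seq$timestamps),
                   file.path(dir, "timestamps.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_thermal_csv
#' @export
read_thermal_csv <- function(dir) {
  ts <- utils::read.csv(file.path(dir, "timestamps.csv"))
  frames <- lapply(ts$frame, function(i)
    as.matrix(utils::read.csv(file.path(dir, sprintf("frame_%06d.csv", i)),
                              header = FALSE)))
  frames <- lapply(frames, unname)
  thermal_seq(ts$t_s, width = ncol(frames[[1]]), height = nrow(frames[[1]]),
              frames = frames)
}

#' Write / read a thermal sequence as a multi-page 32-bit TIFF
#'
#' TIFF pages store `(T - offset) / scale` in [0, 1]; `offset` (degC) and
#' `scale` (degC) are recorded in the sidecar timestamps CSV so the reader
#' can invert the mapping. Default window -20..80 degC.
#'
#' @param seq A [thermal_seq].
#' @param path Output `.tif` path; the sidecar is written next to it as
#'   `<path>.timestamps.csv`.
#' @param offset,scale Affine storage mapping, degC.
#' @return `write_thermal_tiff` the path, invisibly; `read_thermal_tiff`
#'   a materialised [thermal_seq].
#' @export
write_thermal_tiff <- function(seq, path, offset = -20, scale = 100) {
  frames <- lapply(seq_len(length(seq)), function(i)
    (get_frame(seq, i) - offset) / scale)
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stop_cfg("temperatures outside the storage window [%g, %g] degC",
             offset, offset + scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32, compression = "none")
  utils::write.csv(data.frame(frame = seq_len(length(seq)),
                              t_s = seq$timestamps,
                              offset_c = offset, scale_c = scale),
                   paste0(path, ".timestamps.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_thermal_tiff
#' @export
read_thermal_tiff <- function(path) {
  side <- utils::read.csv(paste0(path, ".timestamps.csv"))
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(seq_along(pages), function(i)
    pages[[i]] * side$scale_c[i] + side$offset_c[i])
  thermal_seq(side$t_s, width = ncol(frames[[1]]),
              height = nrow(frames[[1]]), frames = frames)
}
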