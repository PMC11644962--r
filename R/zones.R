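#' Knee zone codes
#'
#' The twelve knee zones tracked by the automatic method: six per knee --
#' superior lateral (SL), superior medial (SM), patella (P), lateral and
#' medial joint line areas (LJLA, MJLA) and patellar tendon (PT) -- each
#' prefixed by `R` or `L` for the right or left leg.
#'
#' @return Character vector of the 12 zone codes, right leg first.
#' @export
knee_zones <- function() {
  base <- c("SL", "SM", "P", "LJLA", "MJLA", "PT")
  c(paste0("R", base), paste0("L", base))
}

# Per-zone layout offsets (px) relative to the knee centre (the patella).
# `medial` is the direction toward the body midline: +x for the right knee
# (which appears on the image left when the camera faces the participant),
# -x for the left knee. y grows downward.
zone_offsets <- function(medial_sign) {
  rbind(
    SL   = c(-30 * medial_sign, -35),
    SM   = c( 30 * medial_sign, -35),
    P    = c(  0,                 0),
    LJLA = c(-32 * medial_sign,  18),
    MJLA = c( 32 * medial_sign,  18),
    PT   = c(  0,                55)
  )
}

# 12 x 2 matrix of zone centres (x, y) in pixels for one body pose.
# knee_y is the current patella height; the right knee sits at
# x = 0.30 * width, the left at 0.70 * width.
zone_layout <- function(width_px, height_px, knee_y) {
  rx <- 0.30 * width_px
  lx <- 0.70 * width_px
  right <- sweep(zone_offsets(+1), 2, c(rx, knee_y), "+")
  left  <- sweep(zone_offsets(-1), 2, c(lx, knee_y), "+")
  out <- rbind(right, left)
  rownames(out) <- knee_zones()
  colnames(out) <- c("x", "y")
  out
}

# Zones belonging to one leg, in canonical order.
leg_zones <- function(leg = c("right", "left")) {
  leg <- match.arg(leg)
  pre <- if (leg == "right") "R" else "L"
  paste0(pre, c("SL", "SM", "P", "LJLA", "MJLA", "PT"))
}
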