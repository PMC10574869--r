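#' Landmark coordinate from a patch start
#'
#' A template's landmark sits at its exact center, so the landmark of a
#' selected 100 x 100 patch is the 0-based start plus 50 pixels on each
#' axis.
#'
#' @param start Length-2 numeric `(Sx, Sy)`.
#' @return Numeric `(x, y)`.
#' @export
poi_center <- function(start) {
  c(start[1] + 50, start[2] + 50)
}

#' Slope of the line through two landmarks
#'
#' `m = (y2 - y1) / (x2 - x1)` in raster coordinates (y down).  Vertical
#' lines return `Inf` as a distinguished marker handled by [acute_angle].
#'
#' @param p1,p2 Length-2 numeric points `(x, y)`.
#' @return Slope, possibly `Inf`.
#' @export
line_slope <- function(p1, p2) {
  if (isTRUE(all(p1 == p2))) {
    abort("Cannot take the slope through two identical points.",
          class = "flatfootr_error_degenerate")
  }
  if (p2[1] == p1[1]) return(Inf)
  (p2[2] - p1[2]) / (p2[1] - p1[1])
}

#' Acute angle between two lines given by slopes
#'
#' `theta = atan(|m2 - m1| / |1 + m1 m2|)` in degrees; perpendicular lines
#' (`1 + m1 m2 == 0`) give 90.  An infinite slope is handled through the
#' perpendicular complement: the angle between a vertical line and a line
#' of slope `m` is `90 - atan(|m|)`.
#'
#' @param m1,m2 Slopes (finite or `Inf`).
#' @return Degrees in `[0, 90]`.
#' @export
acute_angle <- function(m1, m2) {
  inf1 <- is.infinite(m1); inf2 <- is.infinite(m2)
  if (inf1 && inf2) return(0)
  if (inf1 || inf2) {
    m <- if (inf1) m2 else m1
    return(90 - atan(abs(m)) * 180 / pi)
  }
  den <- 1 + m1 * m2
  if (den == 0) return(90)
  atan(abs(m2 - m1) / abs(den)) * 180 / pi
}

#' Signed angle from one direction vector to another
#'
#' Two-argument arctangent of (cross, dot).  Under the raster convention
#' (y down) a positive angle is a clockwise turn on screen:
#' `directed_angle(c(1, 0), c(0, 1)) == 90`.
#'
#' @param u,v Nonzero length-2 numeric vectors.
#' @return Signed degrees in `(-180, 180]`.
#' @export
directed_angle <- function(u, v) {
  if (all(u == 0) || all(v == 0)) {
    abort("Direction vectors must be nonzero.",
          class = "flatfootr_error_degenerate")
  }
  atan2(u[1] * v[2] - u[2] * v[1], sum(u * v)) * 180 / pi
}

# landmark lookup: landmarks tibble (poi_id, x, y) -> c(x, y)
lm_pt <- function(landmarks, id) {
  r <- landmarks[landmarks$poi_id == id, ]
  if (nrow(r) != 1L) {
    abort(paste0("Landmark missing or duplicated: PoI ", id),
          class = "flatfootr_error_missing_landmark", poi_id = id)
  }
  c(r$x[1], r$y[1])
}

# Line definitions for the three clinical angles.  Frozen here as the one
# configuration table: alternative landmark pairings are a config change.
angle_lines <- list(
  cia = list(a = c(5L, 6L), b = c(5L, 9L)),   # calcaneal inferior vs base
  ma  = list(a = c(7L, 8L), b = c(1L, 2L)),   # talar axis vs 1st metatarsal
  aa  = list(a = c(5L, 6L), b = c(3L, 4L))    # calcaneal vs 5th metatarsal
)

#' Calcaneal inclination angle (degrees)
#'
#' Acute angle between the calcaneal inferior line (PoI 5 to 6) and the
#' base line from the posterior calcaneus to the sesamoid (PoI 5 to 9).
#' Normal feet incline 20-30 degrees; flattening lowers the angle.
#'
#' @param landmarks Tibble `poi_id, x, y` (0-based raster coordinates).
#' @return Degrees in `[0, 90]`.
#' @export
measure_cia <- function(landmarks) {
  p5 <- lm_pt(landmarks, 5L); p6 <- lm_pt(landmarks, 6L)
  p9 <- lm_pt(landmarks, 9L)
  acute_angle(line_slope(p5, p6), line_slope(p5, p9))
}

#' Meary's angle (degrees)
#'
#' Acute angle between the talar axis (PoI 7 to 8) and the first
#' metatarsal axis (PoI 1 to 2); near 0 in a normal foot, growing as the
#' medial arch breaks.
#'
#' @inheritParams measure_cia
#' @return Degrees in `[0, 90]`.
#' @export
measure_ma <- function(landmarks) {
  p7 <- lm_pt(landmarks, 7L); p8 <- lm_pt(landmarks, 8L)
  p1 <- lm_pt(landmarks, 1L); p2 <- lm_pt(landmarks, 2L)
  acute_angle(line_slope(p7, p8), line_slope(p1, p2))
}

#' Arch angle (degrees)
#'
#' `AA = 180 - delta` with `delta` the signed [directed_angle] from the
#' posterior-to-anterior calcaneal inferior direction (PoI 5 to 6) to the
#' posterior-to-anterior fifth-metatarsal inferior direction (PoI 3 to 4).
#' The sign convention is frozen so a raised arch (apex above the heel-toe
#' chord; smaller raster y) yields AA below 180 and a collapsed arch a
#' reflex AA of 180 or more — the clinically meaningful moderate range
#' that an unsigned two-line angle cannot express.  The phantom generator
#' realizes ground truth with this same constant.
#'
#' @inheritParams measure_cia
#' @return Degrees in (0, 360).
#' @export
measure_aa <- function(landmarks) {
  p5 <- lm_pt(landmarks, 5L); p6 <- lm_pt(landmarks, 6L)
  p3 <- lm_pt(landmarks, 3L); p4 <- lm_pt(landmarks, 4L)
  u <- p6 - p5; v <- p4 - p3
  if (all(u == 0) || all(v == 0)) {
    abort("Coincident landmarks defining the arch angle.",
          class = "flatfootr_error_degenerate")
  }
  180 - directed_angle(u, v)
}

#' Measure all three clinical angles from a landmark set
#'
#' @inheritParams measure_cia
#' @param image_id Identifier copied into the result.
#' @return One-row tibble `image_id, cia_deg, aa_deg, ma_deg`.
#' @export
measure_foot_angles <- function(landmarks, image_id = "img") {
  tibble(image_id = image_id,
         cia_deg = measure_cia(landmarks),
         aa_deg = measure_aa(landmarks),
         ma_deg = measure_ma(landmarks))
}
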