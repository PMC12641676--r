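#' Screen geometry for pixel / visual-angle conversion
#'
#' Describes the monitor the gaze data was recorded on. The default matches a
#' 24-inch full-HD desktop display viewed at 650 mm, a typical operating
#' distance for remote desktop eye trackers.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param diagonal_inch Physical diagonal of the display in inches.
#' @param viewing_distance_mm Eye-to-screen distance in millimetres.
#' @return A `screen_geometry` list with the inputs plus `pitch_mm`, the
#'   physical size of one pixel (square pixels assumed).
#' @examples
#' geom <- screen_geometry()
#' geom$pitch_mm
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080,
                            diagonal_inch = 24, viewing_distance_mm = 650) {
  stopifnot(width_px > 0, height_px > 0, diagonal_inch > 0,
            viewing_distance_mm > 0)
  diag_mm <- diagonal_inch * 25.4
  pitch_mm <- diag_mm / sqrt(width_px^2 + height_px^2)
  structure(
    list(width_px = width_px, height_px = height_px,
         diagonal_inch = diagonal_inch,
         viewing_distance_mm = viewing_distance_mm,
         pitch_mm = pitch_mm),
    class = "screen_geometry"
  )
}

#' Convert an on-screen pixel distance to visual angle
#'
#' Uses the exact subtended-angle formula
#' `2 * atan(d_px * pitch / (2 * viewing_distance))`, in degrees. Monotone in
#' the pixel distance and (for fixed distance) strictly decreasing in viewing
#' distance.
#'
#' @param d_px Pixel distance(s), non-negative.
#' @param geometry A [screen_geometry()].
#' @return Visual angle(s) in degrees.
#' @export
px_to_degrees <- function(d_px, geometry = screen_geometry()) {
  if (any(d_px < 0, na.rm = TRUE)) {
    stop("px_to_degrees: pixel distances must be non-negative")
  }
  2 * atan((d_px * geometry$pitch_mm) / (2 * geometry$viewing_distance_mm)) *
    180 / pi
}
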