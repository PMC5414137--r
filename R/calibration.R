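#' Pixel/millimetre calibration at the table plane
#'
#' Every geometric threshold in the MJT detection pipeline is stated in
#' millimetres, while the detectors operate on images. With the sensor
#' mounted perpendicularly ~1200 mm above the table, a single planar scale
#' at the table plane is an adequate mapping; this object holds it.
#'
#' @param mm_per_px Scale of one pixel at the table plane, mm/pixel. Must be
#'   positive.
#' @param sensor_height_mm Nominal sensor-to-table distance in mm (default
#'   1200); informational only.
#' @return An object of class `mjt_calibration`.
#' @examples
#' cal <- calibration(2.0)
#' px_to_mm(63.5, cal)  # 127 mm
#' @export
calibration <- function(mm_per_px, sensor_height_mm = 1200) {
  stopifnot(is.numeric(mm_per_px), length(mm_per_px) == 1L, mm_per_px > 0)
  structure(list(mm_per_px = as.numeric(mm_per_px),
                 sensor_height_mm = as.numeric(sensor_height_mm)),
            class = "mjt_calibration")
}

#' @export
print.mjt_calibration <- function(x, ...) {
  cat(sprintf("<mjt_calibration> %.4g mm/px, sensor height %.0f mm\n",
              x$mm_per_px, x$sensor_height_mm))
  invisible(x)
}

#' Convert a pixel distance to millimetres
#'
#' Linear in `d_px`: `d_px * mm_per_px`.
#'
#' @param d_px Non-negative pixel distance (vectorised).
#' @param cal An [calibration()] object.
#' @return Distance(s) in mm.
#' @export
px_to_mm <- function(d_px, cal) {
  stopifnot(inherits(cal, "mjt_calibration"), all(d_px >= 0))
  d_px * cal$mm_per_px
}

#' Convert a millimetre distance to integer pixels
#'
#' Inverse of [px_to_mm()]; rounds half-up to an integer pixel count, which
#' is the convention used whenever a mm threshold must become a pixel count.
#'
#' @param d_mm Non-negative distance in mm (vectorised).
#' @param cal An [calibration()] object.
#' @return Integer pixel count(s).
#' @export
mm_to_px <- function(d_mm, cal) {
  stopifnot(inherits(cal, "mjt_calibration"), all(d_mm >= 0))
  as.integer(floor(d_mm / cal$mm_per_px + 0.5))
}

#' Derive the calibration from a detected known-size object
#'
#' The board ridge has a known physical length (508 mm); dividing it by the
#' detected pixel extent of the ridge yields the scale at the table plane.
#'
#' @param ridge_extent_px Detected ridge extent in pixels (footprint
#'   convention, see [component_extent_px()]).
#' @param ridge_length_mm Physical ridge length in mm (default 508).
#' @inheritParams calibration
#' @return An `mjt_calibration`.
#' @export
calibration_from_ridge <- function(ridge_extent_px, ridge_length_mm = 508,
                                   sensor_height_mm = 1200) {
  stopifnot(ridge_extent_px > 0)
  calibration(ridge_length_mm / ridge_extent_px, sensor_height_mm)
}
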