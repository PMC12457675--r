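#' Physical calibration of a time-lapse movie
#'
#' Couples the spatial sampling (micrometres per pixel) and the temporal
#' sampling (seconds per frame) of an acquisition. Defaults correspond to a
#' 40x confocal objective sampling at 0.36 um/pixel with one frame every 2 s.
#'
#' @param pixel_size Micrometres per pixel; must be > 0.
#' @param frame_interval Seconds per frame; must be > 0.
#' @return An object of class `aw_calibration`.
#' @examples
#' cal <- calibration()
#' convert_speed(0.5, cal)   # 5.4 um/min
#' convert_length(15, cal)   # 5.4 um
#' @export
calibration <- function(pixel_size = 0.36, frame_interval = 2) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, is.finite(pixel_size),
            pixel_size > 0,
            is.numeric(frame_interval), length(frame_interval) == 1L,
            is.finite(frame_interval), frame_interval > 0)
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval),
            class = "aw_calibration")
}

#' @export
print.aw_calibration <- function(x, ...) {
  cat(sprintf("calibration: %.4g um/px, %.4g s/frame\n",
              x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Convert a speed from pixels/frame to micrometres/minute
#'
#' @param value Speed in pixels per frame (vectorised).
#' @param calibration An [calibration()] object.
#' @return Speed in um/min: `value * pixel_size / frame_interval * 60`.
#' @export
convert_speed <- function(value, calibration) {
  stopifnot(inherits(calibration, "aw_calibration"))
  value * calibration$pixel_size / calibration$frame_interval * 60
}

#' Convert a length from pixels to micrometres
#'
#' @param value Length in pixels (vectorised).
#' @param calibration An [calibration()] object.
#' @return Length in um: `value * pixel_size`.
#' @export
convert_length <- function(value, calibration) {
  stopifnot(inherits(calibration, "aw_calibration"))
  value * calibration$pixel_size
}
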