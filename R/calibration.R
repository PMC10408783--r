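#' Spatial calibration
#'
#' Maps sensor pixels to on-sample distances. The on-sample size of a raw
#' pixel is `sensor_pixel_pitch_um / (objective_mag * tube_mag)`; the
#' analysis grid produced by the pipeline's spatial downsample is
#' `downsample_factor` times coarser.
#'
#' @param sensor_pixel_pitch_um physical pixel pitch of the sensor, in
#'   micrometres (e.g. 5.5 for a typical CCD).
#' @param objective_mag objective magnification (e.g. 4).
#' @param tube_mag camera tube magnification (e.g. 1 or 0.5).
#' @param downsample_factor integer spatial downsampling factor of the
#'   analysis pipeline (default 4).
#' @return An object of class `iosi_calibration`.
#' @examples
#' cal <- spatial_calibration(5.5, 4, 1)
#' raw_pixel_size_um(cal)       # 1.375
#' analysis_pixel_size_um(cal)  # 5.5
#' @export
spatial_calibration <- function(sensor_pixel_pitch_um,
                                objective_mag,
                                tube_mag = 1,
                                downsample_factor = 4L) {
  vals <- c(sensor_pixel_pitch_um, objective_mag, tube_mag, downsample_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("spatial_calibration: all fields must be positive and finite")
  if (abs(downsample_factor - round(downsample_factor)) > 0)
    stop("spatial_calibration: downsample_factor must be an integer")
  structure(list(
    sensor_pixel_pitch_um = sensor_pixel_pitch_um,
    objective_mag = objective_mag,
    tube_mag = tube_mag,
    downsample_factor = as.integer(downsample_factor)
  ), class = "iosi_calibration")
}

#' On-sample size of one raw pixel, micrometres
#' @param calibration a [spatial_calibration()].
#' @export
raw_pixel_size_um <- function(calibration) {
  calibration$sensor_pixel_pitch_um /
    (calibration$objective_mag * calibration$tube_mag)
}

#' On-sample size of one analysis pixel, micrometres
#' @param calibration a [spatial_calibration()].
#' @export
analysis_pixel_size_um <- function(calibration) {
  raw_pixel_size_um(calibration) * calibration$downsample_factor
}

#' Field of view of a sensor
#'
#' FOV along each sensor dimension in millimetres:
#' `pixels * pitch_um * 1e-3 / (objective_mag * tube_mag)`.
#'
#' @param pixels integer vector of sensor pixel counts, e.g. `c(3296, 2472)`.
#' @param calibration a [spatial_calibration()].
#' @return Numeric vector of FOV sizes in mm, same length as `pixels`.
#' @examples
#' # 8 MP CCD behind a 4x objective and 1x tube lens
#' compute_fov(c(3296, 2472), spatial_calibration(5.5, 4, 1))  # 4.53 3.40 mm
#' @export
compute_fov <- function(pixels, calibration) {
  if (any(pixels <= 0)) stop("compute_fov: pixel counts must be positive")
  pixels * raw_pixel_size_um(calibration) * 1e-3
}

#' @export
print.iosi_calibration <- function(x, ...) {
  cat(sprintf(
    "Spatial calibration: %g um pitch / (%gx x %gx) -> %g um raw, %g um analysis (ds x%d)\n",
    x$sensor_pixel_pitch_um, x$objective_mag, x$tube_mag,
    raw_pixel_size_um(x), analysis_pixel_size_um(x), x$downsample_factor))
  invisible(x)
}
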