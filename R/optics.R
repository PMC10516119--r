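#' Optical configuration of the lensfree device
#'
#' Bundles the optical and sampling parameters of the sensing geometry: a
#' partially coherent source (center wavelength and FWHM bandwidth), the
#' monochrome sensor pitch and shape, and the sample-to-sensor distance.
#' Defaults match the physical device: 528 +/- 15 nm LED, 1.67 um pixels,
#' ~1 mm gap.
#'
#' @param wavelength_nm Center wavelength of the source in nm.
#' @param bandwidth_nm Full width at half maximum of the source spectrum in nm
#'   (30 means +/- 15 nm about the center).
#' @param pixel_pitch_um Sensor pixel pitch in um.
#' @param sensor_shape Integer vector `c(rows, cols)` of sensor pixels; each
#'   entry must be at least 32.
#' @param z_um Sample-to-sensor distance in um.
#' @param medium_index Refractive index of the medium between sample and
#'   sensor.
#' @return An object of class `optics_config`.
#' @examples
#' opt <- optics_config(sensor_shape = c(128, 128))
#' opt
#' @export
optics_config <- function(wavelength_nm = 528, bandwidth_nm = 30,
                          pixel_pitch_um = 1.67, sensor_shape = c(192L, 192L),
                          z_um = 1000, medium_index = 1.0) {
  if (!(is.numeric(wavelength_nm) && wavelength_nm > 0))
    stopf("wavelength_nm must be > 0")
  if (!(is.numeric(bandwidth_nm) && bandwidth_nm >= 0))
    stopf("bandwidth_nm must be >= 0")
  if (!(is.numeric(pixel_pitch_um) && pixel_pitch_um > 0))
    stopf("pixel_pitch_um must be > 0")
  if (!(is.numeric(z_um) && z_um > 0)) stopf("z_um must be > 0")
  if (length(sensor_shape) != 2L || any(sensor_shape < 32))
    stopf("sensor_shape must be two entries, each >= 32")
  if (!(is.numeric(medium_index) && medium_index >= 1))
    stopf("medium_index must be >= 1")
  structure(list(
    wavelength_nm = wavelength_nm, bandwidth_nm = bandwidth_nm,
    pixel_pitch_um = pixel_pitch_um,
    sensor_shape = as.integer(round(sensor_shape)),
    z_um = z_um, medium_index = medium_index
  ), class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat(sprintf(
    "<optics_config> %d x %d px @ %.2f um, lambda %g +/- %g nm, z = %g um\n",
    x$sensor_shape[1], x$sensor_shape[2], x$pixel_pitch_um,
    x$wavelength_nm, x$bandwidth_nm / 2, x$z_um))
  invisible(x)
}

# Discrete wavelengths (nm) used for the partial-coherence intensity average:
# n points uniformly spanning the FWHM about the center.
coherence_wavelengths <- function(optics, n = 5L) {
  if (optics$bandwidth_nm <= 0 || n <= 1L) return(optics$wavelength_nm)
  seq(optics$wavelength_nm - optics$bandwidth_nm / 2,
      optics$wavelength_nm + optics$bandwidth_nm / 2, length.out = n)
}
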