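#' Sampled complex optical field
#'
#' A scalar optical field sampled on the sensor grid: a complex-valued matrix
#' together with its pixel pitch and carrier wavelength.
#'
#' @param values Complex (or numeric) matrix of field amplitudes.
#' @param pitch_um Sampling pitch in um.
#' @param wavelength_nm Carrier wavelength in nm.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, pitch_um, wavelength_nm) {
  if (!is.matrix(values)) stopf("values must be a matrix")
  if (!is.complex(values)) values <- values + 0i
  assert_finite(c(Re(values), Im(values)), "complex_field values")
  if (!(pitch_um > 0)) stopf("pitch_um must be > 0")
  if (!(wavelength_nm > 0)) stopf("wavelength_nm must be > 0")
  structure(list(values = values, pitch_um = pitch_um,
                 wavelength_nm = wavelength_nm),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d @ %.2f um, lambda %g nm\n",
              nrow(x$values), ncol(x$values), x$pitch_um, x$wavelength_nm))
  invisible(x)
}

#' Recorded hologram frame
#'
#' A nonnegative intensity image (detector counts) with acquisition metadata.
#'
#' @param intensity Nonnegative numeric matrix of detector counts.
#' @param pitch_um Pixel pitch in um.
#' @param timestamp_s Acquisition time in seconds from the start of the run.
#' @param epoch_id Integer id of the 10-min acquisition epoch.
#' @return An object of class `hologram_frame`.
#' @export
hologram_frame <- function(intensity, pitch_um = 1.67, timestamp_s = 0,
                           epoch_id = 0L) {
  if (!is.matrix(intensity)) stopf("intensity must be a matrix")
  assert_finite(intensity, "hologram intensity")
  if (any(intensity < 0)) stopf("hologram intensity must be >= 0")
  structure(list(intensity = intensity, pitch_um = pitch_um,
                 timestamp_s = timestamp_s, epoch_id = as.integer(epoch_id)),
            class = "hologram_frame")
}

#' @export
print.hologram_frame <- function(x, ...) {
  cat(sprintf(
    "<hologram_frame> %d x %d @ %.2f um, t = %.1f s, epoch %d, mean %.3g\n",
    nrow(x$intensity), ncol(x$intensity), x$pitch_um, x$timestamp_s,
    x$epoch_id, mean(x$intensity)))
  invisible(x)
}

#' Phase image of a reconstruction, referenced to the background
#'
#' Returns the argument of the field measured relative to the global
#' background phase (the phase of the spatial mean), so that the unscattered
#' background sits near zero and particle signals appear as positive bumps.
#'
#' @param field A [complex_field].
#' @return Numeric matrix of phase values in radians.
#' @export
phase_image <- function(field) {
  v <- field$values
  bg <- mean(v)
  if (Mod(bg) == 0) return(Arg(v))
  Arg(v * Conj(bg / Mod(bg)))
}

#' Display a frame or phase image
#'
#' Quick-look rendering with sensible orientation for inspecting holograms and
#' reconstructions.
#'
#' @param x Matrix, [hologram_frame] or [complex_field] (phase is shown).
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot_field <- function(x, main = "", ...) {
  m <- if (inherits(x, "hologram_frame")) x$intensity
       else if (inherits(x, "complex_field")) phase_image(x)
       else x
  image(t(m)[, nrow(m):1], col = gray(seq(0, 1, length.out = 256)),
        axes = FALSE, main = main, useRaster = TRUE, ...)
  invisible(NULL)
}
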