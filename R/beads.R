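#' Calibrate the sizing curve from simulated beads of known size
#'
#' Reproduces the device's calibration procedure: monodisperse spherical
#' beads of known diameters are deposited on a fresh film, imaged, and the
#' peak phase of each bead in the focused reconstruction is measured; the
#' (diameter, measured peak phase) pairs are then fitted with
#' [fit_calibration()]. Because the measured phase passes through the full
#' render/reconstruct chain (partial coherence, twin image, noise), the
#' fitted curve absorbs the systematic scale between object-plane and
#' measured phase, exactly as a bench calibration does.
#'
#' @param diameters_nm Bead set in nm (defaults to the 100/200/300/500/1000
#'   bead ladder).
#' @param optics An [optics_config].
#' @param film A [film_model] (beads imaged on a fresh film, t = 0).
#' @param noise A [noise_model].
#' @param reps Independent bead placements per diameter.
#' @param seed Master seed.
#' @param form_id Calibration form passed to [fit_calibration()].
#' @param margin_px Keep-out border for bead placement; defaults to a quarter
#'   of the sensor's smaller dimension so the bead's fringe pattern stays on
#'   the sensor (as it does on the full-size device).
#' @return A `calibration_curve`; the measured pairs are attached as
#'   attribute `pairs`.
#' @export
calibrate_from_beads <- function(diameters_nm = c(100, 200, 300, 500, 1000),
                                 optics = optics_config(sensor_shape = c(128, 128)),
                                 film = film_model(), noise = noise_model(),
                                 reps = 2L, seed = 7L, form_id = "power",
                                 margin_px = NULL) {
  if (is.null(margin_px)) margin_px <- min(optics$sensor_shape) %/% 4
  pairs <- NULL
  j <- 0L
  for (d in diameters_nm) for (r in seq_len(reps)) {
    j <- j + 1L
    sc <- simulate_scene(d, optics, film, noise, seed = derive_seed(seed, j),
                         margin_px = margin_px)
    phi <- measure_peak_phase(sc$frame, sc$manifest, optics)
    pairs <- rbind(pairs, data.frame(diameter_nm = d, peak_phase_rad = phi))
  }
  curve <- fit_calibration(pairs, form_id)
  attr(curve, "pairs") <- pairs
  curve
}

# Measured peak phase of known particles: normalize, autofocus, back-propagate
# and take the maximum phase within a small window around each true center.
measure_peak_phase <- function(frame, manifest, optics, window_px = 4L) {
  fr <- normalize_background(frame)
  z <- autofocus(fr, optics$z_um * c(0.94, 1.06), optics)
  ph <- phase_image(backpropagate(fr, z, optics))
  pitch <- optics$pixel_pitch_um
  vapply(seq_len(nrow(manifest)), function(i) {
    r0 <- round(manifest$y_um[i] / pitch) + 1L
    c0 <- round(manifest$x_um[i] / pitch) + 1L
    rr <- max(1L, r0 - window_px):min(nrow(ph), r0 + window_px)
    cc <- max(1L, c0 - window_px):min(ncol(ph), c0 + window_px)
    max(ph[rr, cc])
  }, numeric(1))
}
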