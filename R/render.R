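#' Sensor noise and digitization model
#'
#' @param read_noise_sigma Additive Gaussian read noise, in detector counts.
#' @param shot_noise Apply Poisson shot noise to the counts.
#' @param bit_depth Quantization depth, 8 or 16.
#' @param seed RNG seed; rendering is bit-reproducible given the seed.
#' @param background_level Fraction of full scale at which a unit-intensity
#'   background is recorded (leaves headroom for interference fringes).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(read_noise_sigma = 1.0, shot_noise = FALSE,
                        bit_depth = 8L, seed = 1L, background_level = 0.45) {
  if (!(read_noise_sigma >= 0)) stopf("read_noise_sigma must be >= 0")
  if (!bit_depth %in% c(8L, 16L)) stopf("bit_depth must be 8 or 16")
  if (!(background_level > 0 && background_level < 1))
    stopf("background_level must be in (0, 1)")
  structure(list(read_noise_sigma = read_noise_sigma,
                 shot_noise = isTRUE(shot_noise),
                 bit_depth = as.integer(bit_depth), seed = as.integer(seed),
                 background_level = background_level),
            class = "noise_model")
}

# Noiseless detector counts (float) for an object field: intensity of the
# field propagated to the sensor, incoherently averaged over wavelengths
# spanning the source bandwidth, scaled to detector counts.
clean_intensity_counts <- function(object_field, optics, noise,
                                   n_wavelengths = 5L) {
  if (!inherits(object_field, "complex_field"))
    stopf("object_field must be a complex_field")
  if (abs(object_field$pitch_um - optics$pixel_pitch_um) > 1e-9)
    stopf("object field is not sampled at the optics pixel pitch")
  lams <- coherence_wavelengths(optics, n_wavelengths)
  lam0 <- optics$wavelength_nm
  amp <- Mod(object_field$values)
  phi <- Arg(object_field$values)
  acc <- 0
  for (lam in lams) {
    # Dispersion of the thin phase object: phase scales as lambda0 / lambda.
    v <- amp * exp(1i * phi * lam0 / lam)
    s <- propagate_padded(v, optics$pixel_pitch_um, lam, optics$z_um,
                          fill = 1 + 0i)
    acc <- acc + Mod(s)^2
  }
  acc / length(lams) * noise$background_level * (2^noise$bit_depth - 1)
}

apply_sensor_noise <- function(counts, noise, seed) {
  full <- 2^noise$bit_depth - 1
  with_seed(seed, {
    if (noise$shot_noise)
      counts <- matrix(rpois(length(counts), pmax(counts, 0)), nrow(counts))
    if (noise$read_noise_sigma > 0)
      counts <- counts + rnorm(length(counts), 0, noise$read_noise_sigma)
    matrix(pmin(pmax(round(counts), 0), full), nrow(counts))
  })
}

#' Render a hologram frame from an object field
#'
#' Forward-propagates the object field to the sensor plane over a small set of
#' wavelengths spanning the source bandwidth (partial temporal coherence as an
#' incoherent intensity average), converts the intensity to detector counts,
#' applies read/shot noise, and quantizes to the sensor bit depth. The field
#' is zero-padded 2x (background fill) around the propagation. Rendering is
#' deterministic given the noise seed.
#'
#' @param object_field A [complex_field] at the object plane, sampled at the
#'   optics pixel pitch.
#' @param optics An [optics_config].
#' @param noise A [noise_model].
#' @param timestamp_s,epoch_id Frame metadata.
#' @param n_wavelengths Number of wavelengths in the coherence average.
#' @param seed Frame seed; defaults to the noise model's seed.
#' @return A [hologram_frame] of quantized counts (intensity >= 0).
#' @export
render_hologram <- function(object_field, optics, noise, timestamp_s = 0,
                            epoch_id = 0L, n_wavelengths = 5L, seed = NULL) {
  counts <- clean_intensity_counts(object_field, optics, noise, n_wavelengths)
  counts <- apply_sensor_noise(counts, noise,
                               if (is.null(seed)) noise$seed else seed)
  hologram_frame(counts, optics$pixel_pitch_um, timestamp_s, epoch_id)
}

#' Simulate one imaging epoch of a static particle scene
#'
#' Convenience wrapper used for calibration beads and detection test scenes:
#' builds the object transmittance at `time_s`, renders `n_frames` noisy
#' frames of the same scene (as the device does within a 10-min epoch), and
#' returns their average together with the ground-truth manifest.
#'
#' @param particles Manifest from [ground_truth_particles()], or a numeric
#'   vector of diameters (nm) to be placed uniformly at random with one
#'   footprint of minimum separation.
#' @param optics An [optics_config].
#' @param film A [film_model].
#' @param noise A [noise_model].
#' @param time_s Scene time (drives film decay).
#' @param n_frames Frames averaged per epoch.
#' @param seed Seed for placement and per-frame noise.
#' @param margin_px,min_sep_px Placement constraints when diameters are given.
#' @return List with `frame` (averaged [hologram_frame]), `manifest`, and
#'   `object_field`.
#' @export
simulate_scene <- function(particles, optics, film = film_model(),
                           noise = noise_model(), time_s = 0, n_frames = 20L,
                           seed = 1L, margin_px = 16L, min_sep_px = 12L) {
  if (is.numeric(particles)) {
    pos <- with_seed(derive_seed(seed, 1L),
                     place_particles(length(particles), optics, margin_px,
                                     min_sep_px))
    particles <- ground_truth_particles(pos$x_um, pos$y_um, particles)
  }
  field <- object_transmittance(particles, film, optics, time_s)
  counts <- clean_intensity_counts(field, optics, noise)
  frames <- lapply(seq_len(n_frames), function(i) {
    hologram_frame(apply_sensor_noise(counts, noise, derive_seed(seed, i + 1L)),
                   optics$pixel_pitch_um, time_s + (i - 1), 0L)
  })
  list(frame = average_frames(frames), manifest = particles,
       object_field = field)
}
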