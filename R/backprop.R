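#' Back-propagate a hologram to the object plane
#'
#' Treats the square root of the (normalized) intensity as the field amplitude
#' with zero sensor-plane phase — the standard single-shot in-line assumption —
#' and propagates it by `-z_um` at the carrier wavelength. The phase channel
#' of the returned reconstruction feeds particle detection. The field is
#' zero-padded to twice its linear size around the propagation (with the
#' median amplitude as fill) to suppress wrap-around fringes, then cropped.
#'
#' @param frame A normalized [hologram_frame] (background ~ 1).
#' @param z_um Object-to-sensor distance in um (positive).
#' @param optics An [optics_config].
#' @return A [complex_field] reconstruction at the object plane.
#' @export
backpropagate <- function(frame, z_um, optics) {
  if (!inherits(frame, "hologram_frame")) stopf("frame must be a hologram_frame")
  amp <- sqrt(frame$intensity)
  v <- propagate_padded(amp + 0i, optics$pixel_pitch_um, optics$wavelength_nm,
                        -z_um, fill = median(amp) + 0i)
  complex_field(v, optics$pixel_pitch_um, optics$wavelength_nm)
}

# Focus metric evaluator: FFT the padded amplitude once, then score any z by a
# single inverse FFT. The metric is the mean of the 9 largest relative-phase
# pixels — concentrated enough to peak sharply at focus for compact particle
# signals, yet robust to isolated hot pixels.
focus_scorer <- function(frame, optics) {
  amp <- sqrt(frame$intensity)
  p <- pad_matrix(amp + 0i, median(amp) + 0i)
  crop <- attr(p, "crop")
  A <- fft2(p)
  g <- spectral_grid(nrow(p), ncol(p), optics$pixel_pitch_um,
                     optics$wavelength_nm, optics$medium_index)
  zmax <- max_safe_distance(min(dim(p)), optics$pixel_pitch_um,
                            optics$wavelength_nm, optics$medium_index)
  phase_at <- function(z) {
    H <- exp(-1i * z * g$kz)
    H[!g$propagating] <- 0
    v <- crop_matrix(ifft2(A * H), crop)
    bg <- mean(v)
    Arg(v * Conj(bg / Mod(bg)))
  }
  list(
    metric = function(z) top_k_mean(phase_at(z), 9L),
    phase_at = phase_at,
    zmax = zmax
  )
}

#' Find the in-focus propagation distance
#'
#' Back-propagates the hologram over a search range and returns the distance
#' that maximizes the reconstructed particle phase, mirroring the device's
#' procedure of back-propagating until the phase of a particle is maximized.
#' A coarse grid search (default 25 steps) brackets the optimum, which is then
#' refined by golden-section search to sub-2-um tolerance. The search is
#' deterministic: equal inputs give identical results.
#'
#' @param frame A normalized [hologram_frame] containing at least one particle
#'   signal above the noise.
#' @param z_range Numeric `c(z_min, z_max)` bracketing the true focus, in um.
#' @param optics An [optics_config].
#' @param coarse_steps Number of coarse grid evaluations.
#' @param tol_um Refinement tolerance in um.
#' @return The focused distance `z*` in um.
#' @export
autofocus <- function(frame, z_range, optics, coarse_steps = 25L,
                      tol_um = 0.5) {
  if (length(z_range) != 2L || z_range[1] >= z_range[2])
    stopf("z_range must be c(z_min, z_max) with z_min < z_max")
  sc <- focus_scorer(frame, optics)
  if (z_range[2] > sc$zmax)
    stopf("z_range exceeds the aliasing-safe bound %.1f um", sc$zmax)
  zs <- seq(z_range[1], z_range[2], length.out = coarse_steps)
  m <- vapply(zs, sc$metric, numeric(1))
  # Flat metric means nothing to focus on: compare the best score with the
  # robust phase noise at the worst coarse distance.
  noise <- mad(sc$phase_at(zs[which.min(m)]))
  if (max(m) <= 5 * noise + 1e-9)
    stopf("no focusable signal in frame")
  i <- which.max(m)
  lo <- zs[max(1L, i - 1L)]
  hi <- zs[min(length(zs), i + 1L)]
  opt <- optimize(sc$metric, lower = lo, upper = hi, maximum = TRUE,
                  tol = tol_um)
  opt$maximum
}
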