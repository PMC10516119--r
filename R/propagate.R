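# Angular spectrum propagation: the workhorse of lensfree reconstruction.
# A field is decomposed into plane waves by FFT, each component advanced by the
# free-space transfer function exp(i * z * sqrt(k^2 - kx^2 - ky^2)), and the
# sum re-assembled by inverse FFT. Evanescent components (kx^2 + ky^2 > k^2)
# are hard-zeroed: at z hundreds of wavelengths they are numerically
# negligible, and zeroing keeps the operator exactly unitary on the
# propagating band so back-and-forth propagation is an identity there.

# Cache of transfer-function ingredients keyed by grid/pitch/wavelength.
.kz_cache <- new.env(parent = emptyenv())

fft_angular_freq <- function(n, pitch_um) {
  # FFT-ordered angular spatial frequencies (rad/um).
  f <- c(0:(floor((n - 1) / 2)), -(n - floor((n - 1) / 2) - 1):-1) / (n * pitch_um)
  2 * pi * f
}

spectral_grid <- function(nr, nc, pitch_um, wavelength_nm, medium_index = 1) {
  key <- paste(nr, nc, pitch_um, wavelength_nm, medium_index, sep = "|")
  hit <- .kz_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- 2 * pi * medium_index / (wavelength_nm * 1e-3)  # rad/um
  kx <- fft_angular_freq(nc, pitch_um)
  ky <- fft_angular_freq(nr, pitch_um)
  arg <- k^2 - outer(ky^2, rep(1, nc)) - outer(rep(1, nr), kx^2)
  grid <- list(kz = sqrt(pmax(arg, 0)), propagating = arg > 0, k = k)
  .kz_cache[[key]] <- grid
  grid
}

#' Maximum aliasing-safe propagation distance
#'
#' The transfer-function phase must remain adequately sampled on the FFT grid;
#' beyond this bound the highest spatial frequencies alias and the
#' reconstruction wraps around. The bound is
#' `N * dx^2 / lambda * sqrt(1 - (lambda / (2 dx))^2)` for an `N`-pixel grid of
#' pitch `dx`.
#'
#' @param n Linear grid size in pixels (use the smaller dimension).
#' @param pitch_um Sampling pitch in um.
#' @param wavelength_nm Wavelength in nm.
#' @param medium_index Refractive index of the propagation medium.
#' @return Maximum safe |distance| in um.
#' @export
max_safe_distance <- function(n, pitch_um, wavelength_nm, medium_index = 1) {
  lam <- wavelength_nm * 1e-3 / medium_index
  s <- lam / (2 * pitch_um)
  if (s >= 1) return(0)
  n * pitch_um^2 / lam * sqrt(1 - s^2)
}

#' Propagate a field by the angular spectrum method
#'
#' Exact spectral free-space propagation over a signed distance. Propagation
#' by zero returns the input unchanged; propagating by `+z` then `-z` restores
#' the field on the propagating band to machine precision. This operator works
#' on the field's own (periodic) grid; the hologram rendering and
#' reconstruction wrappers apply 2x zero-padding around it to suppress
#' wrap-around fringes from edge particles.
#'
#' @param field A [complex_field].
#' @param distance_um Signed propagation distance in um (positive moves away
#'   from the source).
#' @return The propagated [complex_field].
#' @examples
#' f <- complex_field(matrix(1 + 0i, 64, 64), 1.67, 528)
#' g <- propagate_asm(f, 200)
#' max(Mod(propagate_asm(g, -200)$values - f$values))  # ~1e-15
#' @export
propagate_asm <- function(field, distance_um) {
  if (!inherits(field, "complex_field")) stopf("field must be a complex_field")
  assert_finite(c(Re(field$values), Im(field$values)), "field values")
  if (distance_um == 0) return(field)
  n <- min(dim(field$values))
  zmax <- max_safe_distance(n, field$pitch_um, field$wavelength_nm)
  if (abs(distance_um) > zmax)
    stopf(paste0("propagation distance %.1f um exceeds the aliasing-safe ",
                 "bound %.1f um for this grid; enlarge or pad the grid"),
          abs(distance_um), zmax)
  g <- spectral_grid(nrow(field$values), ncol(field$values), field$pitch_um,
                     field$wavelength_nm)
  H <- exp(1i * distance_um * g$kz)
  H[!g$propagating] <- 0
  field$values <- ifft2(fft2(field$values) * H)
  field
}

# Padded propagation of a raw matrix: pad 2x with a constant background,
# propagate at the given wavelength, crop back. Used by rendering,
# back-propagation and twin removal, where the finite sensor window makes
# padding the physically faithful choice.
propagate_padded <- function(values, pitch_um, wavelength_nm, distance_um,
                             fill = NULL) {
  if (is.null(fill)) fill <- mean(values)
  p <- pad_matrix(values, fill)
  crop <- attr(p, "crop")
  f <- complex_field(p, pitch_um, wavelength_nm)
  f <- propagate_asm(f, distance_um)
  crop_matrix(f$values, crop)
}
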