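#' Threshold schedule for iterative detection
#'
#' Exactly five strictly decreasing phase thresholds. The detection loop works
#' from the largest down, removing detected particles between passes so that
#' fringe artifacts from big particles do not obscure smaller ones.
#'
#' @param values Numeric vector of five strictly decreasing positive phase
#'   thresholds (rad).
#' @return An object of class `threshold_schedule`.
#' @export
threshold_schedule <- function(values) {
  values <- as.numeric(values)
  if (length(values) != 5L) stopf("a threshold schedule has exactly 5 values")
  if (any(diff(values) >= 0)) stopf("thresholds must be strictly decreasing")
  if (any(values <= 0)) stopf("thresholds must be positive")
  structure(values, class = "threshold_schedule")
}

#' Default five-threshold schedule from a phase image
#'
#' Five geometrically spaced thresholds from 0.9x the maximum phase down to
#' 3x the robust (MAD-based) noise standard deviation of the background
#' phase. With sparse particles the image-wide MAD is dominated by
#' background pixels. An image whose maximum does not clear 5x the noise MAD
#' (about the expected extreme of pure Gaussian noise on these grids) has no
#' detectable signal and is rejected.
#'
#' @param phase Numeric phase matrix (or a [complex_field], whose
#'   [phase_image()] is used).
#' @return A [threshold_schedule()].
#' @export
default_thresholds <- function(phase) {
  if (inherits(phase, "complex_field")) phase <- phase_image(phase)
  assert_finite(phase, "phase image")
  noise <- mad(phase)
  if (max(phase) <= 5 * noise)
    stopf("no signal: maximum phase %.4g does not clear the noise (MAD %.4g)",
          max(phase), noise)
  top <- 0.9 * max(phase)
  floor_ <- 3 * noise
  threshold_schedule(exp(seq(log(top), log(floor_), length.out = 5L)))
}

#' Detect particles above a phase threshold
#'
#' Connected components of `phase > threshold` in the focused reconstruction,
#' one detection per component. The centroid is the phase-weighted center of
#' mass (subpixel, 0-based pixel units and um from the top-left pixel
#' center); the peak phase is the component maximum. Components touching the
#' image border are discarded.
#'
#' @param recon A [complex_field] reconstruction (in focus), or a phase
#'   matrix plus `pitch_um`.
#' @param threshold Phase threshold in rad.
#' @param pitch_um Pixel pitch, required when `recon` is a bare matrix.
#' @return Data frame with columns `x_px`, `y_px`, `x_um`, `y_um`,
#'   `peak_phase_rad`, `area_px`, `eq_radius_px`. Empty when nothing exceeds
#'   the threshold.
#' @export
detect_at_threshold <- function(recon, threshold, pitch_um = NULL) {
  if (inherits(recon, "complex_field")) {
    pitch_um <- recon$pitch_um
    ph <- phase_image(recon)
  } else {
    ph <- recon
    if (is.null(pitch_um)) stopf("pitch_um required for a bare phase matrix")
  }
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      peak_phase_rad = numeric(0), area_px = integer(0),
                      eq_radius_px = numeric(0))
  mask <- ph > threshold
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(ph), ncol(ph))
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  idx <- which(lab > 0L)
  labs <- lab[idx]
  keep <- !(labs %in% border_labels)
  idx <- idx[keep]; labs <- labs[keep]
  if (length(idx) == 0L) return(empty)
  rows <- (idx - 1L) %% nrow(ph)      # 0-based
  cols <- (idx - 1L) %/% nrow(ph)
  w <- ph[idx]
  wsum <- tapply(w, labs, sum)
  ids <- as.integer(names(wsum))
  x_px <- as.numeric(tapply(w * cols, labs, sum) / wsum)
  y_px <- as.numeric(tapply(w * rows, labs, sum) / wsum)
  peak <- as.numeric(tapply(w, labs, max))
  area <- as.integer(table(labs))
  out <- data.frame(x_px = x_px, y_px = y_px,
                    x_um = x_px * pitch_um, y_um = y_px * pitch_um,
                    peak_phase_rad = peak, area_px = area,
                    eq_radius_px = sqrt(area / pi))
  out[order(-out$peak_phase_rad), , drop = FALSE]
}

# Feathered complex inpainting of a disk: full replacement by the local
# background (annulus mean) inside radius R, cos^2 taper to 1.6R. A
# hard-edged patch would ring through the re-propagation.
inpaint_disk <- function(m, r0, c0, R) {
  rr <- seq(max(1L, r0 - ceiling(2.6 * R)), min(nrow(m), r0 + ceiling(2.6 * R)))
  cc <- seq(max(1L, c0 - ceiling(2.6 * R)), min(ncol(m), c0 + ceiling(2.6 * R)))
  d <- sqrt(outer((rr - r0)^2, rep(1, length(cc))) +
            outer(rep(1, length(rr)), (cc - c0)^2))
  w <- ifelse(d <= R, 1,
              ifelse(d <= 1.6 * R, cos(pi * (d - R) / (2 * 0.6 * R))^2, 0))
  annulus <- d > 1.6 * R & d <= 2.6 * R
  bg <- if (any(annulus)) mean(m[rr, cc][annulus]) else mean(m)
  m[rr, cc] <- w * bg + (1 - w) * m[rr, cc]
  m
}

#' Remove a detected particle and its twin image from a raw hologram
#'
#' Field-domain inpainting at both conjugate planes. The hologram amplitude
#' carries the particle term (which focuses at the object plane) and its
#' conjugate twin (which focuses at the mirror plane on the other side of
#' the sensor); each is compact only in its own plane. The amplitude is
#' back-propagated to the object plane, where the particle's region of
#' interest is replaced by the local background field (feathered complex
#' mean over a surrounding annulus); the field is then propagated to the
#' twin's focal plane, where the conjugate image is inpainted the same way;
#' finally it returns to the sensor plane, whose intensity becomes the new
#' hologram. Both the focused particle and its defocused twin fringes
#' disappear; pixels far from the detection pass through exact propagation
#' round trips and change only through the localized diffraction of the
#' inpainted patches.
#'
#' @param raw_hologram The (normalized) [hologram_frame] the detection came
#'   from.
#' @param detection One-row data frame from [detect_at_threshold()].
#' @param z_um Focus distance in um.
#' @param optics An [optics_config].
#' @param roi_factor ROI radius as a multiple of the component's equivalent
#'   radius.
#' @param min_roi_px Minimum ROI radius in pixels.
#' @param iterations Fixed-point sweeps of the two-plane inpainting; the
#'   intensity projection at the sensor leaves a small residue after one
#'   sweep, and a second drives the operation to idempotence.
#' @return The cleaned [hologram_frame].
#' @export
remove_particle_and_twin <- function(raw_hologram, detection, z_um, optics,
                                     roi_factor = 3, min_roi_px = 5L,
                                     iterations = 2L) {
  amp <- sqrt(raw_hologram$intensity)
  p <- pad_matrix(amp + 0i, median(amp) + 0i)
  crop <- attr(p, "crop")
  pitch <- optics$pixel_pitch_um
  lam <- optics$wavelength_nm
  # Detection coordinates in the padded grid (1-based).
  r0 <- crop[1] + round(detection$y_px) + 1L
  c0 <- crop[2] + round(detection$x_px) + 1L
  R <- max(roi_factor * detection$eq_radius_px, min_roi_px)
  if (r0 - ceiling(R) < crop[1] + 1L || r0 + ceiling(R) > crop[1] + crop[3] ||
      c0 - ceiling(R) < crop[2] + 1L || c0 + ceiling(R) > crop[2] + crop[4])
    warnf("removal ROI clipped at the frame edge")
  sens <- p
  for (it in seq_len(iterations)) {
    # real image plane: the particle term is compact here
    obj <- propagate_asm(complex_field(sens, pitch, lam), -z_um)$values
    obj <- inpaint_disk(obj, r0, c0, R)
    sens <- propagate_asm(complex_field(obj, pitch, lam), z_um)$values
    # twin (virtual image) plane: the conjugate term is compact here
    virt <- propagate_asm(complex_field(sens, pitch, lam), z_um)$values
    virt <- inpaint_disk(virt, r0, c0, R)
    sens <- propagate_asm(complex_field(virt, pitch, lam), -z_um)$values
    if (it < iterations) sens <- Mod(sens) + 0i  # sensor records intensity
  }
  cleaned <- Mod(crop_matrix(sens, crop))^2
  hologram_frame(cleaned, raw_hologram$pitch_um, raw_hologram$timestamp_s,
                 raw_hologram$epoch_id)
}

#' Iterative multi-threshold particle detection
#'
#' The device's detection loop: for each of five decreasing phase thresholds,
#' the hologram is autofocused near `z_hint`, particles above the current
#' threshold are detected and recorded (with the pass index at which they
#' first appeared), and each detected particle together with its twin image
#' is removed from the raw hologram before the next, lower-threshold pass, so
#' that fringe artifacts of large particles no longer obscure smaller ones.
#' A particle is reported exactly once, at the first threshold it exceeds.
#'
#' @param raw_hologram A normalized [hologram_frame].
#' @param optics An [optics_config].
#' @param schedule A [threshold_schedule()], or `NULL` to derive
#'   [default_thresholds()] from the first focused reconstruction.
#' @param z_hint Approximate focus distance in um.
#' @param z_window Relative half-width of the autofocus search about
#'   `z_hint`.
#' @param min_separation_px Detections closer than this to an already
#'   accepted one are treated as residuals of the same particle and dropped.
#' @param verbose Log per-pass detection counts.
#' @return Data frame of detections sorted by descending peak phase, with a
#'   `pass_index` column; attribute `z_focus` carries the final focus
#'   distance.
#' @export
iterative_detect <- function(raw_hologram, optics, schedule = NULL, z_hint,
                             z_window = 0.08, min_separation_px = 6,
                             verbose = FALSE) {
  z_range <- z_hint * c(1 - z_window, 1 + z_window)
  z <- tryCatch(autofocus(raw_hologram, z_range, optics),
                error = function(e) z_hint)
  if (is.null(schedule)) {
    rec0 <- backpropagate(raw_hologram, z, optics)
    schedule <- default_thresholds(rec0)
  }
  current <- raw_hologram
  found <- NULL
  for (pass in seq_along(schedule)) {
    z <- tryCatch(autofocus(current, z_range, optics),
                  error = function(e) z)
    rec <- backpropagate(current, z, optics)
    cand <- detect_at_threshold(rec, schedule[pass])
    if (nrow(cand) > 0 && !is.null(found) && nrow(found) > 0) {
      sep_um <- min_separation_px * optics$pixel_pitch_um
      keep <- vapply(seq_len(nrow(cand)), function(i) {
        min(sqrt((found$x_um - cand$x_um[i])^2 +
                 (found$y_um - cand$y_um[i])^2)) >= sep_um
      }, logical(1))
      cand <- cand[keep, , drop = FALSE]
    }
    if (verbose)
      message(sprintf("pass %d (threshold %.4g): %d new detection(s), z = %.1f um",
                      pass, schedule[pass], nrow(cand), z))
    if (nrow(cand) > 0) {
      cand$pass_index <- pass
      cand$z_um <- z
      for (i in seq_len(nrow(cand)))
        current <- remove_particle_and_twin(current, cand[i, ], z, optics)
      found <- rbind(found, cand)
    }
  }
  if (is.null(found))
    found <- cbind(detect_at_threshold(matrix(0, 2, 2), 1, 1),
                   pass_index = integer(0), z_um = numeric(0))
  found <- found[order(-found$peak_phase_rad), , drop = FALSE]
  rownames(found) <- NULL
  attr(found, "z_focus") <- z
  found
}
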