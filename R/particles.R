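#' Ground-truth particle manifest
#'
#' Builds the simulator's particle table: in-plane centers (um, measured from
#' the top-left pixel center), true diameters, deposit times and the peak
#' object-plane phase each particle imprints. When `peak_phase_rad` is not
#' supplied it is generated from the invertible ground-truth curve, keeping
#' calibration recovery exactly testable.
#'
#' @param x_um,y_um Particle centers in um (x along columns, y along rows).
#' @param diameter_nm True diameters in nm (50 to 10000).
#' @param deposit_time_s Landing times in seconds (>= 0).
#' @param peak_phase_rad Optional peak phases in (0, pi); derived from `curve`
#'   when `NULL`.
#' @param curve Ground-truth phase curve used when `peak_phase_rad` is `NULL`.
#' @return Data frame with columns `id`, `x_um`, `y_um`, `diameter_nm`,
#'   `deposit_time_s`, `peak_phase_rad`.
#' @export
ground_truth_particles <- function(x_um, y_um, diameter_nm,
                                   deposit_time_s = 0,
                                   peak_phase_rad = NULL,
                                   curve = true_phase_curve()) {
  n <- length(x_um)
  if (length(y_um) != n || length(diameter_nm) != n)
    stopf("x_um, y_um, diameter_nm must have equal length")
  deposit_time_s <- rep_len(deposit_time_s, n)
  if (any(diameter_nm < 50 | diameter_nm > 10000))
    stopf("diameter_nm must lie in [50, 10000]")
  if (any(deposit_time_s < 0)) stopf("deposit_time_s must be >= 0")
  if (is.null(peak_phase_rad))
    peak_phase_rad <- phase_for_diameter(curve, diameter_nm)
  peak_phase_rad <- rep_len(peak_phase_rad, n)
  if (any(peak_phase_rad <= 0 | peak_phase_rad >= pi))
    stopf("peak_phase_rad must lie in (0, pi)")
  data.frame(id = seq_len(n), x_um = x_um, y_um = y_um,
             diameter_nm = diameter_nm, deposit_time_s = deposit_time_s,
             peak_phase_rad = peak_phase_rad)
}

# Draw n particle centers (pixel-center positions, um) uniformly over the
# sensor interior, at least `margin_px` from the border and `min_sep_px`
# apart (one particle footprint), avoiding ambiguous ground truth. Existing
# positions (data frame with x_um/y_um) are respected. Errors when the sensor
# cannot host the requested particles (saturation).
#
# method "rejection" draws uniformly with rejection (used when frames are
# rendered); "grid" samples distinct footprint cells and returns their
# centers, which guarantees the separation in O(n) and is used for
# manifest-only runs at full-device particle counts.
place_particles <- function(n, optics, margin_px = 16L, min_sep_px = 12L,
                            existing = NULL, max_tries = 2000L,
                            method = c("rejection", "grid")) {
  method <- match.arg(method)
  if (method == "grid") return(place_particles_grid(n, optics, margin_px,
                                                    min_sep_px, existing))
  pitch <- optics$pixel_pitch_um
  rows <- optics$sensor_shape[1]; cols <- optics$sensor_shape[2]
  xs <- if (!is.null(existing)) existing$x_um else numeric(0)
  ys <- if (!is.null(existing)) existing$y_um else numeric(0)
  out_x <- numeric(0); out_y <- numeric(0)
  min_sep_um <- min_sep_px * pitch
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      px <- sample.int(cols - 2L * margin_px, 1L) + margin_px - 1L  # 0-based
      py <- sample.int(rows - 2L * margin_px, 1L) + margin_px - 1L
      x <- px * pitch; y <- py * pitch
      if (length(xs) == 0 ||
          min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_sep_um) {
        xs <- c(xs, x); ys <- c(ys, y)
        out_x <- c(out_x, x); out_y <- c(out_y, y)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf(paste0("could not place particle %d with %.0f um separation; ",
                   "sensor area is saturated"), i, min_sep_um)
  }
  data.frame(x_um = out_x, y_um = out_y)
}

place_particles_grid <- function(n, optics, margin_px, min_sep_px, existing) {
  pitch <- optics$pixel_pitch_um
  rows <- optics$sensor_shape[1]; cols <- optics$sensor_shape[2]
  nr <- (rows - 2L * margin_px) %/% min_sep_px
  nc <- (cols - 2L * margin_px) %/% min_sep_px
  used <- attr(existing, "grid_cells")
  free <- setdiff(seq_len(nr * nc), used)
  if (length(free) < n)
    stopf("only %d free footprint cells for %d particles: sensor saturated",
          length(free), n)
  cells <- if (length(free) == 1L) free else sample(free, n)
  ci <- (cells - 1L) %/% nr; ri <- (cells - 1L) %% nr
  out <- data.frame(
    x_um = (margin_px + ci * min_sep_px + min_sep_px %/% 2) * pitch,
    y_um = (margin_px + ri * min_sep_px + min_sep_px %/% 2) * pitch)
  attr(out, "grid_cells") <- c(used, cells)
  out
}

#' Object-plane transmittance of deposited particles
#'
#' Returns the unit-amplitude complex transmittance `exp(i * phi(x, y))` where
#' `phi` is a sum of localized, radially symmetric phase bumps, one per
#' particle already deposited by `time_s`. Each bump peaks at the particle's
#' (film-decayed) peak phase and has lateral radius
#' `meniscus_width_factor * particle radius`, floored at two pixels (the
#' nanolens halo never collapses below the sensor sampling). Film evaporation
#' shrinks the peak phase of small particles first; see [phase_retention()].
#' Overlapping bumps add, with a warning.
#'
#' @param particles Manifest from [ground_truth_particles()].
#' @param film A [film_model].
#' @param optics An [optics_config].
#' @param time_s Scene time in seconds; only particles with
#'   `deposit_time_s <= time_s` contribute.
#' @return A [complex_field] at the object plane.
#' @export
object_transmittance <- function(particles, film, optics, time_s = 0) {
  rows <- optics$sensor_shape[1]; cols <- optics$sensor_shape[2]
  pitch <- optics$pixel_pitch_um
  phi <- matrix(0, rows, cols)
  if (!is.null(particles) && nrow(particles) > 0) {
    active <- particles[particles$deposit_time_s <= time_s, , drop = FALSE]
    if (nrow(active) > 0) {
      max_x <- (cols - 1) * pitch; max_y <- (rows - 1) * pitch
      bad <- active$x_um < 0 | active$x_um > max_x |
             active$y_um < 0 | active$y_um > max_y
      if (any(bad))
        stopf("particle(s) %s outside the field of view",
              paste(active$id[bad], collapse = ", "))
      R_um <- pmax(film$meniscus_width_factor * active$diameter_nm / 2 * 1e-3,
                   2 * pitch)
      # Overlap audit: bumps add coherently but blur ground truth.
      if (nrow(active) > 1) {
        dmat <- as.matrix(dist(cbind(active$x_um, active$y_um)))
        diag(dmat) <- Inf
        rsum <- outer(R_um, R_um, `+`)
        if (any(dmat < rsum))
          warnf("overlapping phase bumps: %d particle pair(s); phases add",
                sum(dmat < rsum) / 2)
      }
      age_h <- pmax(time_s - active$deposit_time_s, 0) / 3600
      peak <- active$peak_phase_rad *
        phase_retention(film, active$diameter_nm, age_h)
      xg <- (seq_len(cols) - 1) * pitch
      yg <- (seq_len(rows) - 1) * pitch
      for (i in seq_len(nrow(active))) {
        R <- R_um[i]
        ci <- which(abs(xg - active$x_um[i]) <= R)
        ri <- which(abs(yg - active$y_um[i]) <= R)
        rr <- sqrt(outer((yg[ri] - active$y_um[i])^2, rep(1, length(ci))) +
                   outer(rep(1, length(ri)), (xg[ci] - active$x_um[i])^2))
        bump <- peak[i] * cos(pi * pmin(rr / R, 1) / 2)^2
        phi[ri, ci] <- phi[ri, ci] + bump
      }
    }
  }
  complex_field(exp(1i * phi), pitch, optics$wavelength_nm)
}
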