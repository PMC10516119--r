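# Shared fixtures: small optics geometries and detection-vs-manifest scoring.

test_optics <- function(shape = c(128L, 128L), z_um = 1000) {
  optics_config(sensor_shape = shape, z_um = z_um)
}

# Fringe-containing geometry for quantitative phase work (see the methods
# vignette): frame side >= ~2.5x the fringe extent, particles kept central.
sizing_optics <- function() optics_config(sensor_shape = c(256L, 256L))

# Precision/recall/localization of a detection table against a manifest.
score_detections <- function(det, manifest, tol_px = 1, pitch_um = 1.67) {
  if (nrow(det) == 0L)
    return(list(precision = NA_real_, recall = 0, max_loc_px = NA_real_))
  d2 <- outer(det$x_um, manifest$x_um, "-")^2 +
        outer(det$y_um, manifest$y_um, "-")^2
  dmin_px <- sqrt(apply(d2, 1, min)) / pitch_um
  nearest <- apply(d2, 1, which.min)
  tp <- dmin_px <= tol_px
  list(precision = sum(tp) / nrow(det),
       recall = length(unique(nearest[tp])) / nrow(manifest),
       max_loc_px = if (any(tp)) max(dmin_px[tp]) else NA_real_)
}

# Synthetic phase image: cos^2 bumps at given (row, col) centers (1-based px).
phase_with_bumps <- function(nr, nc, centers, peaks, radius_px = 3) {
  ph <- matrix(0, nr, nc)
  for (i in seq_along(peaks)) {
    rr <- outer(seq_len(nr) - centers[[i]][1], rep(1, nc))
    cc <- outer(rep(1, nr), seq_len(nc) - centers[[i]][2])
    r <- sqrt(rr^2 + cc^2)
    ph <- ph + ifelse(r <= radius_px,
                      peaks[i] * cos(pi * r / (2 * radius_px))^2, 0)
  }
  ph
}

# Accumulation-mode diameter sampler used for field-day simulations.
field_sampler <- function(n) {
  pmin(pmax(exp(rnorm(n, log(600), log(1.6))), 50), 10000)
}
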