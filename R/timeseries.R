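#' Mean particle mass of a size distribution
#'
#' Monte-Carlo estimate of the mean single-particle mass under a diameter
#' sampler, used to convert a mass concentration into an expected deposition
#' rate.
#'
#' @param size_sampler Function `n -> diameters (nm)`.
#' @param rho_kgm3 Particle density (default polystyrene).
#' @param n Number of draws.
#' @param seed Seed for the draws.
#' @return Mean mass in ug.
#' @export
mean_particle_mass_ug <- function(size_sampler, rho_kgm3 = 1050, n = 20000L,
                                  seed = 1L) {
  d <- with_seed(seed, size_sampler(n))
  mean(pi / 6 * (d * 1e-9)^3 * rho_kgm3 * 1e9)
}

#' Simulate an integrative field deployment
#'
#' Emulates an outdoor run of the device: air at a time-varying PM mass
#' concentration is drawn through at `Q_Lpm`; a fraction `eta` of the drawn
#' particles lands in the imaged film area (Poisson deposition, uniform
#' placement with one footprint of minimum separation); the sensor is
#' integrative, so particles accumulate and never leave. Twenty frames are
#' recorded per 10-min epoch. Deposits occur at epoch boundaries; the
#' ground-truth manifest records every particle with its deposit time.
#'
#' The expected number of deposits per epoch is
#' `concentration / mean_mass * Q * t_epoch * eta`, linear in concentration —
#' the assumption underlying the ambient-concentration conversion.
#'
#' @param concentration_profile Ambient PM mass concentration: a numeric
#'   vector of hourly values (ug/m^3) or a function `hour -> ug/m^3`
#'   evaluated at hour indices 1..duration_h.
#' @param size_sampler Function `n -> diameters (nm)`; the field size
#'   distribution is study-specific, so the sampler is user-supplied.
#' @param optics An [optics_config].
#' @param film A [film_model].
#' @param noise A [noise_model].
#' @param duration_h Run length in hours (> 0).
#' @param seed Master seed; every random draw derives from it.
#' @param eta Collection efficiency in (0, 1].
#' @param Q_Lpm Air flow in L/min.
#' @param rho_kgm3 Particle density in kg/m^3.
#' @param frames_per_epoch Frames recorded per 10-min epoch.
#' @param render Render hologram frames (`FALSE` returns the manifest only,
#'   for deposition statistics).
#' @param keep `"epoch_mean"` stores the averaged frame per epoch (the
#'   processing input), `"all"` every raw frame, `"none"` no frames.
#' @param footprint_px Particle footprint (pixels) used for the capacity
#'   guard and minimum placement separation.
#' @param margin_px Keep-out border for placement, in pixels.
#' @return List with `manifest` (ground-truth particles), `epochs`
#'   (epoch table with start/end times and cumulative counts), `frames`
#'   (per `keep`), and `params`.
#' @export
simulate_time_series <- function(concentration_profile, size_sampler,
                                 optics = optics_config(),
                                 film = film_model(),
                                 noise = noise_model(),
                                 duration_h, seed = 1L,
                                 eta = 1.91e-4, Q_Lpm = 4.5,
                                 rho_kgm3 = 1050, frames_per_epoch = 20L,
                                 render = TRUE,
                                 keep = c("epoch_mean", "all", "none"),
                                 footprint_px = 10L, margin_px = 16L) {
  keep <- match.arg(keep)
  if (!(duration_h > 0)) stopf("duration_h must be > 0")
  if (!(eta > 0 && eta <= 1)) stopf("eta must be in (0, 1]")
  conc_at <- if (is.function(concentration_profile)) concentration_profile
             else function(h) concentration_profile[[min(h, length(concentration_profile))]]
  n_epochs <- as.integer(round(duration_h * 6))
  epoch_s <- 600
  mbar <- mean_particle_mass_ug(size_sampler, rho_kgm3,
                                seed = derive_seed(seed, 0L))
  vol_epoch_m3 <- Q_Lpm * 1e-3 * 60 * (epoch_s / 3600)  # m^3 per epoch
  capacity <- sensor_capacity(optics, footprint_px)
  manifest <- NULL
  placement <- if (render) "rejection" else "grid"
  used_cells <- NULL
  frames <- if (keep == "none" || !render) NULL else vector("list", n_epochs)
  epochs <- data.frame(epoch_id = seq_len(n_epochs),
                       t_start_s = (seq_len(n_epochs) - 1) * epoch_s,
                       t_end_s = seq_len(n_epochs) * epoch_s,
                       new_particles = 0L, cumulative_particles = 0L)
  for (e in seq_len(n_epochs)) {
    hour <- ceiling(e / 6)
    conc <- conc_at(hour)
    lambda <- conc / mbar * vol_epoch_m3 * eta
    n_have <- if (is.null(manifest)) 0L else nrow(manifest)
    if (lambda > capacity || n_have + lambda > capacity)
      stopf(paste0("expected deposition (%.0f by epoch %d) exceeds sensor ",
                   "capacity %d: sensor saturated"),
            n_have + lambda, e, capacity)
    n_new <- with_seed(derive_seed(seed, 3L * e), rpois(1L, lambda))
    if (n_new > 0) {
      ex <- manifest
      attr(ex, "grid_cells") <- used_cells
      pos <- with_seed(derive_seed(seed, 3L * e + 1L),
                       place_particles(n_new, optics, margin_px,
                                       min_sep_px = footprint_px,
                                       existing = ex, method = placement))
      used_cells <- attr(pos, "grid_cells")
      d <- with_seed(derive_seed(seed, 3L * e + 2L), size_sampler(n_new))
      d <- pmin(pmax(d, 50), 10000)
      new <- ground_truth_particles(pos$x_um, pos$y_um, d,
                                    deposit_time_s = epochs$t_start_s[e])
      new$id <- new$id + n_have
      manifest <- rbind(manifest, new)
    }
    epochs$new_particles[e] <- n_new
    epochs$cumulative_particles[e] <- if (is.null(manifest)) 0L else nrow(manifest)
    if (render && keep != "none") {
      t_mid <- (epochs$t_start_s[e] + epochs$t_end_s[e]) / 2
      field <- object_transmittance(manifest, film, optics, t_mid)
      counts <- clean_intensity_counts(field, optics, noise)
      fs <- lapply(seq_len(frames_per_epoch), function(i) {
        hologram_frame(
          apply_sensor_noise(counts, noise,
                             derive_seed(seed, 100000L + e * 100L + i)),
          optics$pixel_pitch_um,
          epochs$t_start_s[e] + (i - 1) * epoch_s / frames_per_epoch, e)
      })
      frames[[e]] <- if (keep == "epoch_mean") average_frames(fs) else fs
    }
  }
  if (is.null(manifest))
    manifest <- ground_truth_particles(numeric(0), numeric(0), numeric(0))
  list(manifest = manifest, epochs = epochs, frames = frames,
       params = list(eta = eta, Q_Lpm = Q_Lpm, rho_kgm3 = rho_kgm3,
                     mean_mass_ug = mbar, duration_h = duration_h,
                     seed = seed, capacity = capacity))
}
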