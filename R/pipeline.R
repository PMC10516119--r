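# End-to-end pipeline: epoch averaging -> background normalization ->
# iterative detection on the hourly (cumulative) images -> sizing ->
# histograms and hourly differencing -> captured and ambient PM, with
# optional collection-efficiency fitting and EPA metrics against a
# reference series.

default_config <- function() {
  list(
    optics = list(sensor_shape = c(128L, 128L)),
    film = list(),
    noise = list(),
    thresholds = "auto",
    calibration = "beads",
    calibration_file = NULL,
    eta = 1.91e-4,
    reference_file = NULL,
    bin_edges_nm = c(50, 100, 200, 500, 1000, 2500),
    rho_kgm3 = 1050,
    Q_Lpm = 4.5,
    start_time_iso = "2023-01-01T00:00:00Z",
    out_dir = "holopm_out",
    seed = 1L,
    verbose = TRUE,
    frames = NULL,     # path to recorded frames (+ sidecar)
    simulate = NULL    # list(concentration_profile, duration_h, size = ...)
  )
}

#' Build and validate a pipeline run configuration
#'
#' Merges user settings (an R list or a YAML file of key-value pairs) over
#' the package defaults and validates them before any computation: exactly
#' one input source (`frames` path or a `simulate` block) must be given,
#' `eta = "fit"` requires a reference file, and every referenced path must
#' exist.
#'
#' @param config A named list, or the path of a YAML configuration file.
#' @return A validated configuration list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- modifyList(default_config(), config)
  has_frames <- !is.null(cfg$frames)
  has_sim <- !is.null(cfg$simulate)
  if (has_frames == has_sim)
    stopf("config needs exactly one input: a 'frames' path or a 'simulate' block")
  if (has_frames && !file.exists(cfg$frames))
    stopf("frames path does not exist: %s", cfg$frames)
  if (identical(cfg$eta, "fit") && is.null(cfg$reference_file))
    stopf("eta = 'fit' requires a reference_file")
  for (p in c(cfg$reference_file, cfg$calibration_file))
    if (!is.null(p) && !file.exists(p)) stopf("file not found: %s", p)
  if (is.numeric(cfg$eta) && !(cfg$eta > 0 && cfg$eta <= 1))
    stopf("eta must be in (0, 1] or 'fit'")
  if (has_sim && is.null(cfg$simulate$duration_h))
    stopf("simulate block needs duration_h")
  structure(cfg, class = "run_config")
}

size_sampler_from_config <- function(spec) {
  if (is.function(spec)) return(spec)
  if (is.null(spec)) spec <- list(type = "lognormal", median_nm = 600, gsd = 1.6)
  switch(spec$type,
    lognormal = function(n) pmin(pmax(
      exp(rnorm(n, log(spec$median_nm), log(spec$gsd))), 50), 10000),
    uniform = function(n) runif(n, spec$min_nm, spec$max_nm),
    fixed = function(n) sample(spec$diameters_nm, n, replace = TRUE),
    stopf("unknown size distribution type '%s'", spec$type))
}

# Detections newly appearing at hour h: those without a counterpart within
# one footprint in the previous hour's set (the sensor is integrative, so
# matching by position is well-defined).
new_detections <- function(now, before, sep_um) {
  if (nrow(now) == 0L) return(now)
  if (is.null(before) || nrow(before) == 0L) return(now)
  keep <- vapply(seq_len(nrow(now)), function(i) {
    min(sqrt((before$x_um - now$x_um[i])^2 +
             (before$y_um - now$y_um[i])^2)) >= sep_um
  }, logical(1))
  now[keep, , drop = FALSE]
}

#' Run the full sensing pipeline
#'
#' Executes every stage of the device's processing chain on recorded or
#' simulated frames and writes the result files (see [write_results()]).
#' Stages: per-epoch frame averaging, background normalization, iterative
#' multi-threshold detection on the image closing each hour, phase-to-
#' diameter calibration, cumulative histograms, hourly differencing,
#' captured and ambient PM (with per-size-bin breakdown), and — when a
#' reference series is supplied — collection-efficiency fitting and EPA
#' performance metrics. Reruns with the same configuration and seed are
#' reproducible.
#'
#' @param config A [run_config()] (or a list / YAML path coerced by it).
#' @return Invisibly, a list with `detections`, `histograms`, `pm_hourly`,
#'   `eta`, `epa`, `calibration`, and the output `paths`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  log_ <- function(fmt, ...) if (isTRUE(cfg$verbose))
    message(sprintf(paste0("[holopm] ", fmt), ...))
  optics <- do.call(optics_config, cfg$optics)
  film <- do.call(film_model, cfg$film)
  noise <- do.call(noise_model, cfg$noise)
  t0 <- as.POSIXct(cfg$start_time_iso, tz = "UTC",
                   format = "%Y-%m-%dT%H:%M:%SZ")

  # --- stage: acquire epoch-averaged frames -------------------------------
  if (!is.null(cfg$simulate)) {
    log_("simulating %s h field run (seed %d)", cfg$simulate$duration_h,
         cfg$seed)
    sim <- simulate_time_series(
      cfg$simulate$concentration_profile,
      size_sampler_from_config(cfg$simulate$size),
      optics, film, noise,
      duration_h = cfg$simulate$duration_h, seed = cfg$seed,
      eta = if (is.numeric(cfg$eta)) cfg$eta else cfg$simulate$eta,
      Q_Lpm = cfg$Q_Lpm, rho_kgm3 = cfg$rho_kgm3, keep = "epoch_mean")
    epoch_frames <- sim$frames
    epoch_ids <- sim$epochs$epoch_id
  } else {
    log_("reading frames from %s", cfg$frames)
    raw <- read_frames(cfg$frames)
    epoch_ids <- sort(unique(vapply(raw, function(f) f$epoch_id, integer(1))))
    epoch_frames <- lapply(epoch_ids, function(e) {
      average_frames(raw[vapply(raw, function(f) f$epoch_id, integer(1)) == e])
    })
    sim <- NULL
  }
  n_epochs <- length(epoch_frames)
  n_hours <- floor(n_epochs / 6)
  if (n_hours < 1L) stopf("run shorter than one hour; nothing to difference")
  log_("%d epochs -> %d full hour(s)", n_epochs, n_hours)

  # --- stage: calibration curve -------------------------------------------
  curve <- if (!is.null(cfg$calibration_file)) {
    fit_calibration(read.csv(cfg$calibration_file))
  } else if (identical(cfg$calibration, "beads")) {
    log_("calibrating from simulated bead ladder")
    calibrate_from_beads(optics = optics, film = film, noise = noise,
                         seed = derive_seed(cfg$seed, 999L))
  } else if (inherits(cfg$calibration, "calibration_curve")) {
    cfg$calibration
  } else stopf("no calibration source configured")

  # --- stage: hourly detection --------------------------------------------
  schedule <- if (identical(cfg$thresholds, "auto")) NULL
              else threshold_schedule(cfg$thresholds)
  sep_um <- 6 * optics$pixel_pitch_um
  hourly <- vector("list", n_hours)
  cum_counts <- numeric(n_hours)
  detections <- NULL
  histograms <- NULL
  for (h in seq_len(n_hours)) {
    fr <- normalize_background(epoch_frames[[6 * h]])
    det <- tryCatch(
      iterative_detect(fr, optics, schedule, z_hint = optics$z_um),
      error = function(e) {
        if (grepl("no signal|no focusable", conditionMessage(e)))
          cbind(detect_at_threshold(matrix(0, 2, 2), 1, 1),
                pass_index = integer(0), z_um = numeric(0))
        else stop(e)
      })
    det <- apply_calibration(det, curve)
    det$epoch_id <- 6L * h
    hourly[[h]] <- det
    cum_counts[h] <- nrow(det)
    log_("hour %d: %d cumulative detection(s)", h, nrow(det))
    histograms <- rbind(histograms,
                        size_histogram(det, cfg$bin_edges_nm, epoch_id = 6L * h))
    new <- new_detections(det, if (h > 1) hourly[[h - 1]] else NULL, sep_um)
    if (nrow(new) > 0) {
      new$hour <- h
      detections <- rbind(detections, new)
    }
  }
  if (is.null(detections))
    detections <- cbind(hourly[[1]][0, , drop = FALSE], hour = integer(0))

  # --- stage: quantification ----------------------------------------------
  pm_bins <- hourly_pm_by_size(detections, n_hours, cfg$bin_edges_nm,
                               cfg$rho_kgm3, cfg$Q_Lpm)
  pm_cap <- colSums(pm_bins)
  reference <- if (!is.null(cfg$reference_file))
    read_reference_series(cfg$reference_file) else NULL
  eta_fit <- NULL
  eta <- cfg$eta
  if (identical(cfg$eta, "fit")) {
    ref_vals <- reference$pm25_ugm3[seq_len(n_hours)]
    eta_fit <- estimate_eta(pm_cap, ref_vals)
    eta <- eta_fit$eta
    log_("fitted eta = %.4g (rmse %.3g ug/m3)", eta, eta_fit$rmse_ugm3)
  }
  pm <- ambient_concentration(pm_cap, eta)
  epa <- NULL
  if (!is.null(reference)) {
    ref_vals <- reference$pm25_ugm3[seq_len(n_hours)]
    if (n_hours >= 3 && var(ref_vals) > 0)
      epa <- epa_metrics(pm, ref_vals)
  }
  pm_hourly <- data.frame(
    hour = seq_len(n_hours),
    hour_end_iso = iso_utc(t0, 3600 * seq_len(n_hours)),
    new_particles = c(cum_counts[1], hourly_new_particles(cum_counts)),
    pm_cap_ugm3 = pm_cap, pm_ugm3 = pm)
  pm_hourly <- cbind(pm_hourly, t(pm_bins))

  # --- stage: outputs ------------------------------------------------------
  cfg_record <- unclass(cfg)
  cfg_record$eta <- eta
  paths <- write_results(detections, histograms, pm_hourly, cfg$out_dir,
                         config = cfg_record, seed = cfg$seed)
  log_("results written to %s", cfg$out_dir)
  invisible(list(detections = detections, hourly = hourly,
                 histograms = histograms, pm_hourly = pm_hourly,
                 eta = eta, eta_fit = eta_fit, epa = epa,
                 calibration = curve, manifest = if (!is.null(sim)) sim$manifest,
                 paths = paths))
}
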