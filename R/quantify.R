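#' Size histogram of detections
#'
#' @param detections Data frame with `diameter_nm`.
#' @param bin_edges_nm Ascending bin edges in nm.
#' @param epoch_id Epoch the histogram belongs to.
#' @return Data frame with `bin_lo_nm`, `bin_hi_nm`, `count`, `epoch_id`.
#' @export
size_histogram <- function(detections,
                           bin_edges_nm = c(50, 100, 200, 500, 1000, 2500),
                           epoch_id = 0L) {
  if (any(diff(bin_edges_nm) <= 0)) stopf("bin edges must be ascending")
  d <- detections$diameter_nm
  counts <- as.integer(table(cut(d, bin_edges_nm, right = TRUE,
                                 include.lowest = TRUE)))
  data.frame(bin_lo_nm = head(bin_edges_nm, -1),
             bin_hi_nm = tail(bin_edges_nm, -1),
             count = counts, epoch_id = as.integer(epoch_id))
}

#' Hourly new-particle counts from cumulative totals
#'
#' The sensor is integrative, so the PM level each hour comes from the change
#' in the cumulative particle count with respect to the previous hour. Works
#' on a numeric vector of hourly cumulative counts, or column-wise on a
#' matrix (size bins x hours).
#'
#' @param cumulative_counts Non-decreasing numeric vector (or matrix with
#'   hours in columns) of cumulative counts at the end of each hour.
#' @return First differences: new particles per hour (length `n - 1`, or a
#'   matrix with `n - 1` columns).
#' @examples
#' hourly_new_particles(c(0, 10, 25, 25))  # 10 15 0
#' @export
hourly_new_particles <- function(cumulative_counts) {
  if (is.matrix(cumulative_counts)) {
    d <- t(apply(cumulative_counts, 1, hourly_new_particles))
    if (ncol(cumulative_counts) == 2L) d <- matrix(d, ncol = 1L)
    dimnames(d) <- list(rownames(cumulative_counts), NULL)
    return(d)
  }
  if (length(cumulative_counts) < 2L)
    stopf("need at least two hourly totals to difference")
  d <- diff(cumulative_counts)
  if (any(d < 0))
    stopf(paste0("cumulative counts decrease at hour(s) %s: the sensor is ",
                 "integrative, so this indicates detection instability"),
          paste(which(d < 0), collapse = ", "))
  d
}

#' Captured PM mass concentration
#'
#' Mass of the particles captured on the sensor during a collection window,
#' expressed as a concentration of the air drawn through the device:
#' `PM_cap = sum_i (pi/6 d_i^3 rho) / (Q t)`. Only particles with
#' `d <= d_max_nm` contribute when computing the PM2.5-comparable value.
#'
#' @param detections Data frame with calibrated `diameter_nm`, or a numeric
#'   vector of diameters in nm.
#' @param rho_kgm3 Particle density (default polystyrene, 1050).
#' @param Q_Lpm Volumetric air flow in L/min.
#' @param t_h Collection time in hours.
#' @param d_max_nm Upper diameter cutoff in nm (2500 for PM2.5).
#' @return Captured mass concentration in ug/m^3.
#' @examples
#' captured_mass_concentration(1000, Q_Lpm = 4.5, t_h = 1)  # one 1-um sphere
#' @export
captured_mass_concentration <- function(detections, rho_kgm3 = 1050,
                                        Q_Lpm = 4.5, t_h = 1,
                                        d_max_nm = 2500) {
  if (!(Q_Lpm > 0 && t_h > 0)) stopf("Q_Lpm and t_h must be > 0")
  d <- if (is.data.frame(detections)) {
    if (!"diameter_nm" %in% names(detections) ||
        anyNA(detections$diameter_nm)) {
      offenders <- if ("diameter_nm" %in% names(detections))
        which(is.na(detections$diameter_nm)) else seq_len(nrow(detections))
      stopf("detections %s have no calibrated diameter",
            paste(offenders, collapse = ", "))
    }
    detections$diameter_nm
  } else as.numeric(detections)
  d <- d[d <= d_max_nm]
  if (length(d) == 0L) return(0)
  mass_ug <- sum(pi / 6 * (d * 1e-9)^3 * rho_kgm3) * 1e9  # kg -> ug
  vol_m3 <- Q_Lpm * 1e-3 * 60 * t_h
  mass_ug / vol_m3
}

#' Ambient PM concentration from the captured value
#'
#' Scales the captured mass concentration by the collection efficiency:
#' `PM = PM_cap / eta`. The efficiency is assumed size-independent by
#' default; a per-size-bin efficiency may be supplied as a vector when
#' `pm_cap_ugm3` is a size-resolved matrix (bins in rows), in which case it
#' is applied row-wise.
#'
#' @param pm_cap_ugm3 Captured mass concentration(s) in ug/m^3; scalar,
#'   vector, or a bins-by-hours matrix from [hourly_pm_by_size()].
#' @param eta Collection efficiency in (0, 1]; scalar, or one value per size
#'   bin for a matrix input.
#' @return Ambient concentration(s) in ug/m^3, same shape as the input.
#' @export
ambient_concentration <- function(pm_cap_ugm3, eta) {
  if (any(eta <= 0 | eta > 1)) stopf("eta must lie in (0, 1]")
  if (length(eta) > 1L) {
    if (!is.matrix(pm_cap_ugm3) || nrow(pm_cap_ugm3) != length(eta))
      stopf("per-bin eta needs a bins-by-hours matrix with %d rows",
            length(eta))
    return(pm_cap_ugm3 / eta)
  }
  pm_cap_ugm3 / eta
}

#' Estimate the collection efficiency against a reference monitor
#'
#' Finds the efficiency that best maps the captured series onto a trusted
#' reference: the through-origin fit in the reference domain,
#' `eta = sum(pm_cap^2) / sum(pm_cap * ref)`, which minimizes
#' `sum((pm_cap/eta - ref)^2)` over `eta > 0`.
#'
#' @param pm_cap_series Hourly captured mass concentrations (ug/m^3).
#' @param reference Aligned hourly reference PM2.5 values (ug/m^3), numeric
#'   or a data frame with a `pm25_ugm3` column.
#' @return List with `eta` and `rmse_ugm3` (RMSE of `pm_cap/eta - ref`).
#' @export
estimate_eta <- function(pm_cap_series, reference) {
  if (is.data.frame(reference)) reference <- reference$pm25_ugm3
  if (length(pm_cap_series) != length(reference))
    stopf("series must be aligned (equal length)")
  if (length(pm_cap_series) < 3L) stopf("need at least 3 aligned hourly pairs")
  if (all(pm_cap_series == 0)) stopf("captured series is identically zero")
  denom <- sum(pm_cap_series * reference)
  if (denom <= 0)
    stopf("sum(pm_cap * reference) <= 0: empty or anti-correlated signal")
  eta <- sum(pm_cap_series^2) / denom
  rmse <- sqrt(mean((pm_cap_series / eta - reference)^2))
  list(eta = eta, rmse_ugm3 = rmse)
}

#' Maximum number of resolvable particles on the sensor
#'
#' Each particle (with its fringes) occupies roughly a square footprint on
#' the sensor, so a sensor of `rows x cols` pixels has room for
#' `floor(rows * cols / footprint^2)` particles before saturating.
#'
#' @param optics An [optics_config], or a single total pixel count.
#' @param footprint_px Linear footprint per particle in pixels (>= 1).
#' @return Maximum particle count (integer-valued numeric).
#' @examples
#' sensor_capacity(3664 * 2748, 10)  # 10-megapixel class sensor
#' @export
sensor_capacity <- function(optics, footprint_px = 10L) {
  if (!is_count(footprint_px)) stopf("footprint_px must be a positive integer")
  total <- if (inherits(optics, "optics_config"))
    prod(as.numeric(optics$sensor_shape)) else as.numeric(optics)
  floor(total / footprint_px^2)
}

#' Concentration ceiling and time to sensor saturation
#'
#' Linear-accumulation forecast anchored at a reference condition: if the
#' device deposits `hourly_rate_at_ref` particles per hour at
#' `ref_concentration`, then in one hour it can accommodate concentrations up
#' to `ceiling = ref_concentration * capacity / hourly_rate_at_ref`, and at a
#' query concentration the film saturates after
#' `capacity / (rate * query / ref)` hours.
#'
#' @param capacity Sensor capacity in particles (see [sensor_capacity()]).
#' @param hourly_rate_at_ref Deposition rate (particles/h) at the reference
#'   concentration.
#' @param ref_concentration Reference concentration in ug/m^3.
#' @param query_concentration Concentration to forecast for, in ug/m^3.
#' @return List with `ceiling_ugm3` and `hours_to_saturation`.
#' @export
saturation_forecast <- function(capacity, hourly_rate_at_ref,
                                ref_concentration, query_concentration) {
  if (any(c(capacity, hourly_rate_at_ref, ref_concentration,
            query_concentration) <= 0))
    stopf("all inputs must be positive")
  list(
    ceiling_ugm3 = ref_concentration * capacity / hourly_rate_at_ref,
    hours_to_saturation = capacity /
      (hourly_rate_at_ref * query_concentration / ref_concentration)
  )
}

#' EPA-style performance metrics against a reference monitor
#'
#' Linearity as the coefficient of determination (R^2) of an ordinary
#' least-squares fit of device readings against the reference (EPA target
#' >= 0.70), precision as the coefficient of variation over replicate device
#' readings at matched conditions (target <= 30%), and the RMSE of the linear
#' fit residuals.
#'
#' @param device_series Device readings aligned with the reference.
#' @param reference Reference values (numeric or data frame with
#'   `pm25_ugm3`).
#' @param replicates Optional matrix of replicate device readings (conditions
#'   in rows, replicates in columns) for the CV.
#' @return List with `r_squared`, `rmse`, and `cv_percent` (`NA` without
#'   replicates).
#' @export
epa_metrics <- function(device_series, reference, replicates = NULL) {
  if (is.data.frame(reference)) reference <- reference$pm25_ugm3
  if (length(device_series) != length(reference))
    stopf("device and reference series must be aligned")
  if (length(device_series) < 3L) stopf("need at least 3 aligned pairs")
  if (var(reference) == 0) stopf("reference has zero variance")
  fit <- lm(device_series ~ reference)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  rmse <- sqrt(mean(resid(fit)^2))
  cv <- NA_real_
  if (!is.null(replicates)) {
    replicates <- as.matrix(replicates)
    pooled_sd <- sqrt(mean(apply(replicates, 1, var)))
    m <- mean(replicates)
    if (m == 0) stopf("replicate mean is zero; CV undefined")
    cv <- 100 * pooled_sd / m
  }
  list(r_squared = r2, cv_percent = cv, rmse = rmse)
}

#' Size-resolved captured PM per hour
#'
#' Splits each hour's newly captured mass across diameter bins. Rows are size
#' bins, columns hours; the column sums equal the total hourly captured PM
#' exactly, since the bins partition the retained diameters.
#'
#' @param detections Data frame with `diameter_nm` and `hour` (1-based hour
#'   index in which each particle was newly detected).
#' @param n_hours Number of hours in the run.
#' @param bin_edges_nm Ascending bin edges in nm.
#' @param rho_kgm3,Q_Lpm Density and flow, as in
#'   [captured_mass_concentration()].
#' @param d_max_nm Upper diameter cutoff.
#' @return Matrix (bins x hours) of captured PM in ug/m^3, with bin labels.
#' @export
hourly_pm_by_size <- function(detections, n_hours,
                              bin_edges_nm = c(50, 100, 200, 500, 1000, 2500),
                              rho_kgm3 = 1050, Q_Lpm = 4.5, d_max_nm = 2500) {
  nb <- length(bin_edges_nm) - 1L
  out <- matrix(0, nb, n_hours,
                dimnames = list(paste0(head(bin_edges_nm, -1), "-",
                                       tail(bin_edges_nm, -1), "nm"), NULL))
  if (nrow(detections) == 0L) return(out)
  keep <- detections$diameter_nm <= d_max_nm &
    detections$diameter_nm >= bin_edges_nm[1] &
    detections$diameter_nm <= bin_edges_nm[nb + 1L]
  det <- detections[keep, , drop = FALSE]
  bins <- as.integer(cut(det$diameter_nm, bin_edges_nm, include.lowest = TRUE))
  for (i in seq_len(nrow(det))) {
    h <- det$hour[i]
    if (h >= 1 && h <= n_hours)
      out[bins[i], h] <- out[bins[i], h] +
        captured_mass_concentration(det$diameter_nm[i], rho_kgm3, Q_Lpm,
                                    t_h = 1, d_max_nm = d_max_nm)
  }
  out
}
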