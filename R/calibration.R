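# Phase -> diameter calibration. The sizing observable is the peak phase of a
# particle in the focused reconstruction; a fitted three-parameter curve maps
# it to a physical diameter. The default functional form is the invertible
# power law D = A * (phi_pk - C)^B, strictly increasing for A, B > 0; an
# exponential alternative can be selected through form_id without touching
# any other code.

calibration_forms <- list(
  power = list(
    predict = function(phi, p) p$A * pmax(phi - p$C, 1e-12)^p$B,
    inverse = function(D, p) p$C + (D / p$A)^(1 / p$B),
    formula = D ~ A * pmax(phi - C, 1e-12)^B,
    start = function(phi, D) {
      C0 <- min(phi) / 2
      fit <- lm(log(D) ~ log(phi - C0))
      list(A = exp(coef(fit)[[1]]), B = coef(fit)[[2]], C = C0)
    },
    upper = function(phi) c(A = Inf, B = Inf, C = min(phi) - 1e-6),
    lower = function(phi) c(A = 1e-12, B = 1e-6, C = -Inf)
  ),
  exponential = list(
    predict = function(phi, p) p$A * exp(p$B * phi) + p$C,
    inverse = function(D, p) log((D - p$C) / p$A) / p$B,
    formula = D ~ A * exp(B * phi) + C,
    start = function(phi, D) {
      B0 <- diff(range(log(pmax(D, 1)))) / diff(range(phi))
      list(A = min(D) / exp(B0 * min(phi)), B = B0, C = 0)
    },
    upper = function(phi) c(A = Inf, B = Inf, C = Inf),
    lower = function(phi) c(A = 1e-12, B = 1e-6, C = -Inf)
  )
)

new_calibration_curve <- function(A, B, C, form_id, valid_phase_range,
                                  rmse_nm = NA_real_, residuals = NULL) {
  structure(list(A = A, B = B, C = C, form_id = form_id,
                 valid_phase_range = valid_phase_range, rmse_nm = rmse_nm,
                 residuals = residuals),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve [%s]> A = %.6g, B = %.6g, C = %.6g, phase in [%.4g, %.4g]%s\n",
    x$form_id, x$A, x$B, x$C, x$valid_phase_range[1], x$valid_phase_range[2],
    if (is.finite(x$rmse_nm)) sprintf(", rmse %.3g nm", x$rmse_nm) else ""))
  invisible(x)
}

#' Ground-truth peak-phase curve of the simulator
#'
#' The simulator assigns each particle a peak object-plane phase from an
#' invertible three-parameter curve in the same family as the sizing
#' calibration, so that calibration recovery is exactly testable. The default
#' is linear in diameter with a small offset (to first order the nanolens
#' peak optical path, and hence the phase, grows in proportion to particle
#' size): ~0.1 rad at 100 nm, ~0.8 rad at 1 um, staying below pi across the
#' PM2.5 size range.
#'
#' @param A,B,C Curve parameters (power form, `D = A * (phi - C)^B`).
#' @return A `calibration_curve` usable with [phase_for_diameter()] and
#'   [phase_to_diameter()].
#' @export
true_phase_curve <- function(A = 1300, B = 1.0, C = 0.02) {
  new_calibration_curve(A, B, C, "power",
                        valid_phase_range = c(1e-6, pi))
}

#' Peak phase imprinted by a particle of known diameter
#'
#' Inverse of the calibration curve: the ground-truth peak phase a particle of
#' diameter `diameter_nm` imprints at the object plane (fresh film).
#'
#' @param curve A `calibration_curve`.
#' @param diameter_nm Diameter(s) in nm.
#' @return Peak phase(s) in radians.
#' @export
phase_for_diameter <- function(curve, diameter_nm) {
  form <- calibration_forms[[curve$form_id]]
  form$inverse(diameter_nm, curve)
}

#' Fit the phase-to-diameter calibration curve
#'
#' Least-squares fit of the three-parameter sizing curve to measured
#' (diameter, peak phase) pairs, as produced by imaging beads of known size.
#' Requires at least four pairs spanning at least two distinct diameters. The
#' fitted curve must be strictly increasing on the data's phase range.
#'
#' @param pairs Data frame with columns `diameter_nm` and `peak_phase_rad`.
#' @param form_id Functional form: `"power"` (default) or `"exponential"`.
#' @return A `calibration_curve` with residual diagnostics (`rmse_nm`,
#'   `residuals`).
#' @examples
#' truth <- true_phase_curve()
#' d <- c(100, 200, 300, 500, 1000)
#' pairs <- data.frame(diameter_nm = d,
#'                     peak_phase_rad = phase_for_diameter(truth, d))
#' fit_calibration(pairs)
#' @export
fit_calibration <- function(pairs, form_id = "power") {
  if (!all(c("diameter_nm", "peak_phase_rad") %in% names(pairs)))
    stopf("pairs must have columns diameter_nm and peak_phase_rad")
  pairs <- pairs[complete.cases(pairs[c("diameter_nm", "peak_phase_rad")]), ]
  if (nrow(pairs) < 4L)
    stopf("need at least 4 calibration pairs (got %d); fit is under-determined",
          nrow(pairs))
  if (length(unique(pairs$diameter_nm)) < 2L)
    stopf("degenerate calibration data: all pairs share one diameter")
  if (any(pairs$peak_phase_rad <= 0))
    stopf("calibration phases must be positive")
  form <- calibration_forms[[form_id]]
  if (is.null(form)) stopf("unknown calibration form '%s'", form_id)
  phi <- pairs$peak_phase_rad
  D <- pairs$diameter_nm
  start <- form$start(phi, D)
  fit <- minpack.lm::nlsLM(
    form$formula, data = data.frame(phi = phi, D = D), start = start,
    lower = form$lower(phi), upper = form$upper(phi),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  p <- as.list(coef(fit))
  rng <- range(phi)
  # Monotonicity audit on the fitted range.
  grid <- seq(rng[1], rng[2], length.out = 64)
  pred <- form$predict(grid, p)
  if (any(diff(pred) <= 0) || any(pred <= 0))
    stopf(paste0("fitted calibration is not strictly increasing and positive ",
                 "on the data's phase range; add calibration points"))
  res <- D - form$predict(phi, p)
  new_calibration_curve(p$A, p$B, p$C, form_id, rng,
                        rmse_nm = sqrt(mean(res^2)), residuals = res)
}

#' Convert measured peak phase to particle diameter
#'
#' Evaluates the calibration curve; strictly increasing in phase. Phases
#' outside the curve's valid range are clamped to its ends with a warning and
#' a `clamped` attribute marking the affected entries.
#'
#' @param peak_phase_rad Measured peak phase(s) in radians.
#' @param curve A `calibration_curve` from [fit_calibration()] or
#'   [true_phase_curve()].
#' @return Diameter(s) in nm, with attribute `clamped` (logical vector).
#' @export
phase_to_diameter <- function(peak_phase_rad, curve) {
  if (!inherits(curve, "calibration_curve"))
    stopf("curve must be a calibration_curve")
  rng <- curve$valid_phase_range
  clamped <- peak_phase_rad < rng[1] | peak_phase_rad > rng[2]
  if (any(clamped))
    warnf("%d phase value(s) outside the calibrated range [%.4g, %.4g]; clamped",
          sum(clamped), rng[1], rng[2])
  phi <- pmin(pmax(peak_phase_rad, rng[1]), rng[2])
  d <- calibration_forms[[curve$form_id]]$predict(phi, curve)
  attr(d, "clamped") <- clamped
  d
}

#' Attach calibrated diameters to a detection table
#'
#' @param detections Data frame of detections with `peak_phase_rad`.
#' @param curve A `calibration_curve`.
#' @return The detections with `diameter_nm` and logical `clamped` columns.
#' @export
apply_calibration <- function(detections, curve) {
  if (nrow(detections) == 0L) {
    detections$diameter_nm <- numeric(0)
    detections$clamped <- logical(0)
    return(detections)
  }
  d <- phase_to_diameter(detections$peak_phase_rad, curve)
  detections$diameter_nm <- as.numeric(d)
  detections$clamped <- attr(d, "clamped")
  detections
}
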