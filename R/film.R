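#' Vapor-condensed nanolens film model
#'
#' Parametric model of the polyethylene-glycol film that forms a liquid
#' meniscus ("nanolens") around each deposited particle. The as-deposited
#' thickness evaporates exponentially, `h(t) = thickness0 * exp(-t / tau)`,
#' in the style of ellipsometry decay fits; the defaults (110 nm from a 5-min
#' deposition, 48 h e-folding) hold the film near 50 nm for a day or two.
#'
#' The nanolens signal of a particle of diameter `d` decays with the film as
#' `retention = (h(t)/h0)^(sensitivity * (200/d)^2)`: a few nanometers of lost
#' film is a large fraction of a small particle's meniscus, so the smallest
#' particles lose signal first. With the defaults, 200 nm particles fall below
#' the detection floor after about a day while 1 um particles remain
#' detectable for many days, and 500 nm particles fade around day six.
#'
#' @param thickness0_nm As-deposited film thickness in nm.
#' @param decay_time_h Exponential e-folding time of the film thickness, in
#'   hours.
#' @param meniscus_width_factor Lateral extent of the particle's phase bump as
#'   a multiple of the particle radius (must be >= 1).
#' @param sensitivity Exponent coupling thickness loss to signal loss for a
#'   200 nm particle.
#' @return An object of class `film_model`.
#' @export
film_model <- function(thickness0_nm = 110, decay_time_h = 48,
                       meniscus_width_factor = 10, sensitivity = 8) {
  if (!(thickness0_nm >= 0)) stopf("thickness0_nm must be >= 0")
  if (!(decay_time_h > 0)) stopf("decay_time_h must be > 0")
  if (!(meniscus_width_factor >= 1)) stopf("meniscus_width_factor must be >= 1")
  if (!(sensitivity > 0)) stopf("sensitivity must be > 0")
  structure(list(thickness0_nm = thickness0_nm, decay_time_h = decay_time_h,
                 meniscus_width_factor = meniscus_width_factor,
                 sensitivity = sensitivity),
            class = "film_model")
}

#' Film thickness after evaporation
#'
#' @param film A [film_model].
#' @param t_h Elapsed time since deposition in hours.
#' @return Thickness in nm.
#' @export
film_thickness <- function(film, t_h) {
  film$thickness0_nm * exp(-t_h / film$decay_time_h)
}

#' Fraction of a particle's peak phase retained as the film evaporates
#'
#' @param film A [film_model].
#' @param diameter_nm Particle diameter(s) in nm.
#' @param t_h Time since the particle landed, in hours.
#' @return Retention factor in (0, 1]; monotone increasing in diameter and
#'   decreasing in time.
#' @export
phase_retention <- function(film, diameter_nm, t_h) {
  t_h <- pmax(t_h, 0)
  ratio <- exp(-t_h / film$decay_time_h)
  ratio^(film$sensitivity * (200 / diameter_nm)^2)
}

#' Warn when the film is too old for reliable sub-200 nm sizing
#'
#' Sub-200 nm particles lose their nanolens within about a day of film life;
#' calibration phases measured on a fresh film do not transfer to an aged one.
#'
#' @param film A [film_model].
#' @param age_h Film age in hours.
#' @param max_age_h Age beyond which the warning fires.
#' @return `TRUE` (invisibly) if the film is still fresh, otherwise `FALSE`
#'   with a warning.
#' @export
check_film_age <- function(film, age_h, max_age_h = 24) {
  if (age_h > max_age_h) {
    warnf(paste0("film is %.1f h old; sizing of sub-200 nm particles is ",
                 "unreliable beyond %.0f h"), age_h, max_age_h)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
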