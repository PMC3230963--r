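# Rotation-elimination estimator for the first-order mass moment.
#
# Rotating segment S1 by theta about a fixed centre, while the rest of the
# system stays put, displaces the whole-system CoM by
#   CoM_alpha - CoM_beta = (I - R(theta)) CoM_1,alpha * (M1 / M).
# Everything static (rest of body, board, frame) cancels in the difference,
# so solving the 2x2 system and multiplying the solved vector's norm by the
# measured total mass M yields the segment's first-order moment
#   M1 * |CoM_1,alpha|  (kg.cm)
# without ever knowing M1 or the static masses individually.

# Default tolerance on the alpha/beta total-mass agreement. The difference of
# two three-reading sums has standard deviation sqrt(6) * sigma_scale; with
# the instrument's stated precision of 1.5 g the 3-sigma band is ~11 g.
DEFAULT_MASS_TOL_KG <- 3 * sqrt(6) * 0.0015

#' Pair of whole-system CoM measurements around one segment rotation
#'
#' Bundles the two board measurements (reference posture alpha, rotated
#' posture beta), the rotation angle, and the rotation centre the
#' coordinates are referred to. The two postures must agree on the total
#' supported mass (nothing is added or removed between them).
#'
#' @param state_alpha,state_beta [body_state()] objects for the reference and
#'   rotated postures.
#' @param theta_deg Segment rotation angle from alpha to beta, degrees,
#'   counter-clockwise positive; must pass [check_rotation_angle()].
#' @param rotation_center The segment's centre of rotation, (x, y) cm in the
#'   same frame as the CoM coordinates. It is an input measured on the
#'   apparatus, never estimated here.
#' @param mass_tol_kg Maximum admissible difference between the two total
#'   masses; the default is a 3-sigma band under the scale's stated 1.5 g
#'   precision. Widen it when the readings carry heavier simulated noise.
#' @param angle_tol_deg Singularity guard band passed to
#'   [check_rotation_angle()].
#' @return An object of class `measurement_pair`.
#' @export
measurement_pair <- function(state_alpha, state_beta, theta_deg,
                             rotation_center = c(0, 0),
                             mass_tol_kg = DEFAULT_MASS_TOL_KG,
                             angle_tol_deg = 1) {
  stopifnot(inherits(state_alpha, "body_state"), inherits(state_beta, "body_state"))
  check_rotation_angle(theta_deg, angle_tol_deg)
  rotation_center <- check_planar_point(rotation_center, "rotation_center")
  dm <- state_alpha$total_mass_kg - state_beta$total_mass_kg
  if (abs(dm) > mass_tol_kg) {
    stop_segmoment(
      sprintf("total supported mass differs between postures by %.4f kg (tolerance %.4f kg)",
              dm, mass_tol_kg),
      "segmoment_inconsistent_session"
    )
  }
  structure(
    list(state_alpha = state_alpha, state_beta = state_beta,
         theta_deg = theta_deg, rotation_center = rotation_center),
    class = "measurement_pair"
  )
}

#' Estimate the first-order mass moment from one measurement pair
#'
#' Solves `(I - R(theta)) v = CoM_alpha - CoM_beta` for the mass-scaled
#' segment CoM vector `v = CoM_1,alpha * (M1 / M)` (both CoMs re-expressed
#' relative to the rotation centre; the centre cancels in the difference)
#' and returns `|v| * M` with `M` the mean of the two measured totals.
#'
#' @param pair A [measurement_pair()].
#' @return An object of class `moment_estimate` with elements
#'   `moment_kgcm`, `com1_alpha` (the solved vector, cm scaled by M1/M),
#'   `theta_deg` and `total_mass_kg`.
#' @export
estimate_moment <- function(pair) {
  stopifnot(inherits(pair, "measurement_pair"))
  delta <- (pair$state_alpha$com - pair$rotation_center) -
    (pair$state_beta$com - pair$rotation_center)
  v <- solve(difference_operator(pair$theta_deg), delta)
  m_total <- (pair$state_alpha$total_mass_kg + pair$state_beta$total_mass_kg) / 2
  structure(
    list(moment_kgcm = sqrt(sum(v^2)) * m_total,
         com1_alpha = as.numeric(v),
         theta_deg = pair$theta_deg,
         total_mass_kg = m_total),
    class = "moment_estimate"
  )
}

#' @export
print.moment_estimate <- function(x, ...) {
  cat(sprintf("moment estimate: %.4f kg.cm  (theta = %.2f deg, M = %.4f kg)\n",
              x$moment_kgcm, x$theta_deg, x$total_mass_kg))
  invisible(x)
}

#' Closed-form (chord) moment estimator
#'
#' The difference operator is a scaled rotation, so the matrix solve reduces
#' to a division by the chord gain: the moment equals
#' `total_mass * |CoM_alpha - CoM_beta| / (2 sin(theta / 2))`.
#' Agrees with [estimate_moment()] to machine precision; used for
#' cross-checking and for analytic uncertainty propagation.
#'
#' @param delta_com_norm_cm Norm of the CoM displacement between postures, cm.
#' @param theta_deg Rotation angle, degrees.
#' @param total_mass_kg Total supported mass, kg.
#' @param angle_tol_deg Singularity guard band.
#' @return The moment in kg.cm.
#' @export
estimate_moment_scalar <- function(delta_com_norm_cm, theta_deg, total_mass_kg,
                                   angle_tol_deg = 1) {
  check_finite_scalar(delta_com_norm_cm, "delta_com_norm_cm")
  check_finite_scalar(total_mass_kg, "total_mass_kg")
  total_mass_kg * delta_com_norm_cm / chord_gain(theta_deg, angle_tol_deg)
}

moment_values <- function(estimates) {
  if (is.numeric(estimates)) return(as.numeric(estimates))
  if (inherits(estimates, "moment_estimate")) estimates <- list(estimates)
  vapply(estimates, function(e) {
    stopifnot(inherits(e, "moment_estimate"))
    e$moment_kgcm
  }, numeric(1))
}

#' Summary statistics over repeated moment measurements
#'
#' Aggregates repeated estimates into the conventional accuracy/precision
#' report: mean, sample standard deviation (n - 1 denominator), and, when a
#' calibrated reference moment is available, the RMS of the deviations from
#' it. Relative figures are percentages of the calibrated value when given,
#' else of the mean.
#'
#' @param estimates A list of [estimate_moment()] results, or a plain numeric
#'   vector of moments in kg.cm.
#' @param calibrated_kgcm Optional calibrated (ground-truth) moment, kg.cm.
#' @return An object of class `session_summary` with `n`, `mean_kgcm`,
#'   `sd_kgcm` (NA for n = 1), `rms_vs_calibrated_kgcm`, `relative_sd_pct`
#'   and `relative_rms_pct` (the latter two NULL-free, NA where undefined).
#' @examples
#' summarize_session(c(118.3, 114.3), calibrated_kgcm = 116.3)  # RMS 2.0
#' @export
summarize_session <- function(estimates, calibrated_kgcm = NULL) {
  m <- moment_values(estimates)
  if (length(m) < 1L) {
    stop_segmoment("no estimates to summarize", "segmoment_invalid_input")
  }
  if (!is.null(calibrated_kgcm)) check_finite_scalar(calibrated_kgcm, "calibrated_kgcm")
  n <- length(m)
  mean_m <- mean(m)
  sd_m <- if (n >= 2L) stats::sd(m) else NA_real_
  rms <- if (!is.null(calibrated_kgcm)) sqrt(mean((m - calibrated_kgcm)^2)) else NA_real_
  reference <- calibrated_kgcm %||% mean_m
  structure(
    list(n = n,
         mean_kgcm = mean_m,
         sd_kgcm = sd_m,
         rms_vs_calibrated_kgcm = rms,
         calibrated_kgcm = calibrated_kgcm %||% NA_real_,
         reference_kgcm = reference,
         relative_sd_pct = relative_figure(sd_m, reference),
         relative_rms_pct = if (!is.null(calibrated_kgcm)) {
           relative_figure(rms, calibrated_kgcm)
         } else {
           NA_real_
         }),
    class = "session_summary"
  )
}

#' Relative precision figure
#'
#' Expresses a dispersion statistic as a percentage of a reference moment,
#' the arithmetic behind every relative precision number in the reports.
#'
#' @param value Dispersion (SD or RMS), kg.cm; NA propagates.
#' @param reference_kgcm Positive reference moment, kg.cm.
#' @return `100 * value / reference_kgcm`.
#' @export
relative_figure <- function(value, reference_kgcm) {
  if (is.na(value)) return(NA_real_)
  check_finite_scalar(value, "value")
  check_finite_scalar(reference_kgcm, "reference_kgcm")
  if (reference_kgcm <= 0) {
    stop_segmoment("'reference_kgcm' must be positive", "segmoment_invalid_input")
  }
  100 * value / reference_kgcm
}

#' @export
print.session_summary <- function(x, ...) {
  for (line in render_report(x)) cat(line, "\n", sep = "")
  invisible(x)
}
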