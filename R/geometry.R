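# Planar rotation geometry used by the moment estimator.
#
# All user-facing angles are in degrees (the convention in which rotation
# protocols are recorded); conversion to radians happens here and nowhere
# else. Positive angles are counter-clockwise in the top-down view of the
# board. The estimator itself is insensitive to the handedness convention
# because it only uses the magnitude of the solved vector.

deg2rad <- function(deg) deg * pi / 180

#' Planar rotation matrix
#'
#' Builds the 2x2 rotation matrix for a rotation of `theta_deg` degrees,
#' counter-clockwise positive in the top-down view of the measurement board.
#'
#' @param theta_deg Rotation angle in degrees (any finite value).
#' @return A 2x2 orthogonal matrix with determinant +1.
#' @examples
#' rotation_matrix(90)   # quarter turn
#' rotation_matrix(0)    # identity
#' @export
rotation_matrix <- function(theta_deg) {
  check_finite_scalar(theta_deg, "theta_deg")
  th <- deg2rad(theta_deg)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
}

#' Rotation difference operator I - R(theta)
#'
#' The operator that maps the segment centre-of-mass vector (at the reference
#' posture, relative to the rotation centre) to the displacement of the
#' whole-system centre of mass scaled by the mass ratio. It is a scaled
#' rotation: both singular values equal `2 * abs(sin(theta/2))`, so it is
#' singular exactly at theta = 0 (mod 360).
#'
#' Singularity is not rejected here; use [check_rotation_angle()] or
#' [chord_gain()] where an invertible operator is required.
#'
#' @inheritParams rotation_matrix
#' @return A 2x2 matrix, `diag(2) - rotation_matrix(theta_deg)`.
#' @export
difference_operator <- function(theta_deg) {
  diag(2) - rotation_matrix(theta_deg)
}

#' Guard against near-singular rotation angles
#'
#' Rotations close to 0 (mod 360) degrees make the difference operator
#' nearly singular: the centre-of-mass displacement shrinks as
#' `2 sin(theta/2)` and measurement noise is amplified without bound.
#' Angles within `tol_deg` of 0 or 360 (after reducing modulo 360 of the
#' absolute angle) are rejected.
#'
#' @inheritParams rotation_matrix
#' @param tol_deg Rejection band around the singular angles, degrees.
#' @return Invisibly, `theta_deg`; raises a `segmoment_singular_angle`
#'   condition when the angle is inside the rejection band.
#' @export
check_rotation_angle <- function(theta_deg, tol_deg = 1) {
  check_finite_scalar(theta_deg, "theta_deg")
  check_finite_scalar(tol_deg, "tol_deg")
  phi <- abs(theta_deg) %% 360
  if (phi < tol_deg || phi > 360 - tol_deg) {
    stop_segmoment(
      sprintf("rotation angle %.4g deg is within %.3g deg of the singular configuration (0 or 360 deg)",
              theta_deg, tol_deg),
      "segmoment_singular_angle"
    )
  }
  invisible(theta_deg)
}

#' Chord gain of a rotation
#'
#' The factor `2 * abs(sin(theta/2))` by which a rotation of `theta_deg`
#' displaces a point at unit distance from the rotation centre (the chord of
#' the arc). Its inverse is the noise amplification of the moment estimator:
#' small rotation angles produce small centre-of-mass displacements and
#' correspondingly noisy estimates.
#'
#' @inheritParams check_rotation_angle
#' @return The scalar chord gain, in (0, 2].
#' @export
chord_gain <- function(theta_deg, tol_deg = 1) {
  check_rotation_angle(theta_deg, tol_deg)
  2 * abs(sin(deg2rad(theta_deg) / 2))
}
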