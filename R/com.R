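# Whole-system centre of mass from three support-point scale readings.
#
# The board rests on three non-collinear support points; the load at each is
# weighed (in grams, the instrument's native unit) and the system CoM is the
# reading-weighted mean of the support positions. Masses are carried in kg
# and positions in cm throughout the package, so moments come out in kg.cm.

signed_triangle_area <- function(points) {
  a <- points[2L, ] - points[1L, ]
  b <- points[3L, ] - points[1L, ]
  0.5 * (a[1L] * b[2L] - a[2L] * b[1L])
}

#' Three support points with scale readings
#'
#' One atomic observation of the load distribution: the planar positions of
#' the three support points (cm) and the scale reading at each (grams).
#' In practice the three points are weighed sequentially with a single scale
#' while the posture is held fixed; the set is still modelled as one
#' observation, and drift between the three weighings is a simulator noise
#' option, not a data-model feature.
#'
#' @param points A 3x2 numeric matrix of support positions, one row per
#'   support, columns x and y in cm.
#' @param reading_g Numeric vector of three non-negative scale readings, grams.
#' @param area_eps_cm2 Minimum admissible triangle area; smaller (collinear)
#'   configurations are rejected.
#' @return An object of class `support_set` with elements `points`,
#'   `reading_g` and `mass_kg`.
#' @export
support_set <- function(points, reading_g, area_eps_cm2 = 1e-6) {
  points <- as.matrix(points)
  if (!is.numeric(points) || !all(dim(points) == c(3L, 2L)) || !all(is.finite(points))) {
    stop_segmoment("'points' must be a finite 3x2 numeric matrix (cm)",
                   "segmoment_invalid_input")
  }
  if (!is.numeric(reading_g) || length(reading_g) != 3L || !all(is.finite(reading_g))) {
    stop_segmoment("'reading_g' must be three finite scale readings in grams",
                   "segmoment_invalid_input")
  }
  if (any(reading_g < 0)) {
    stop_segmoment("scale readings must be non-negative", "segmoment_invalid_input")
  }
  if (abs(signed_triangle_area(points)) <= area_eps_cm2) {
    stop_segmoment("support points are collinear (degenerate triangle)",
                   "segmoment_degenerate_geometry")
  }
  dimnames(points) <- list(paste0("P", 1:3), c("x", "y"))
  structure(
    list(points = points, reading_g = as.numeric(reading_g),
         mass_kg = as.numeric(reading_g) / 1000),
    class = "support_set"
  )
}

#' Whole-system state at one posture
#'
#' @param com Centre of mass, numeric (x, y) in cm relative to the declared
#'   origin (normally the rotation centre).
#' @param total_mass_kg Total supported mass, kg; must be positive.
#' @param label Optional posture label, conventionally `"alpha"` (reference)
#'   or `"beta"` (rotated).
#' @return An object of class `body_state`.
#' @export
body_state <- function(com, total_mass_kg, label = NA_character_) {
  com <- check_planar_point(com, "com")
  check_finite_scalar(total_mass_kg, "total_mass_kg")
  if (total_mass_kg <= 0) {
    stop_segmoment("'total_mass_kg' must be positive", "segmoment_invalid_input")
  }
  structure(list(com = com, total_mass_kg = total_mass_kg, label = label),
            class = "body_state")
}

#' @export
print.body_state <- function(x, ...) {
  cat(sprintf("body state%s: CoM = (%.4f, %.4f) cm, total mass = %.4f kg\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
              x$com[1L], x$com[2L], x$total_mass_kg))
  invisible(x)
}

#' Centre of mass from support readings
#'
#' Computes the whole-system centre of mass as the reading-weighted mean of
#' the three support positions, and the total supported mass as the sum of
#' the readings. With non-negative readings the result always lies inside or
#' on the support triangle.
#'
#' @param supports A [support_set()].
#' @param label Optional posture label carried into the returned state.
#' @return A [body_state()] with the computed CoM and summed mass.
#' @examples
#' ss <- support_set(rbind(c(0, 0), c(100, 0), c(0, 100)),
#'                   reading_g = c(20000, 30000, 50000))
#' compute_com(ss)   # CoM (30, 50) cm, 100 kg
#' @export
compute_com <- function(supports, label = NA_character_) {
  stopifnot(inherits(supports, "support_set"))
  total <- sum(supports$mass_kg)
  if (total <= 0) {
    stop_segmoment("all three scale readings are zero: no load on the supports",
                   "segmoment_empty_load")
  }
  com <- colSums(supports$points * supports$mass_kg) / total
  body_state(unname(com), total, label)
}

#' Mass-conservation check against a declared total
#'
#' Quality-control comparison of the summed scale readings against an
#' independently known total mass (e.g. the weighed masses of the segment,
#' ballast and board). The default tolerance is three times the scale's
#' stated precision of 1.5 g. Report-only: never raises an error.
#'
#' @param state A [body_state()] whose `total_mass_kg` is the summed readings.
#' @param declared_total_kg Independently declared total mass, kg.
#' @param tol_kg Pass/fail tolerance, kg.
#' @return A list with `pass` (logical), `deviation_kg` (signed
#'   readings-minus-declared difference) and `tol_kg`.
#' @export
check_total_mass <- function(state, declared_total_kg, tol_kg = 3 * 0.0015) {
  stopifnot(inherits(state, "body_state"))
  check_finite_scalar(declared_total_kg, "declared_total_kg")
  if (declared_total_kg <= 0) {
    stop_segmoment("'declared_total_kg' must be positive", "segmoment_invalid_input")
  }
  dev <- state$total_mass_kg - declared_total_kg
  list(pass = abs(dev) <= tol_kg, deviation_kg = dev, tol_kg = tol_kg)
}
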