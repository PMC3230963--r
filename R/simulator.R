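# Forward measurement model and synthetic session generator.
#
# Ground truth is a rigid planar system: a segment that rotates about the
# origin, a static remainder, and a static carrier (board or frame), all
# resting on three non-collinear supports. The forward model computes the
# exact support loads by statics (barycentric coordinates), then corrupts
# them with an instrument/digitisation noise model.

#' Rigid segment under test
#'
#' @param mass_kg Segment mass, kg; positive.
#' @param com_local_cm Segment centre of mass, (x, y) cm in the segment frame
#'   whose origin is the rotation centre. At the reference posture (alpha)
#'   the segment frame coincides with the board frame.
#' @return An object of class `rigid_segment`.
#' @export
rigid_segment <- function(mass_kg, com_local_cm) {
  check_finite_scalar(mass_kg, "mass_kg")
  if (mass_kg <= 0) stop_segmoment("segment mass must be positive", "segmoment_invalid_input")
  com_local_cm <- check_planar_point(com_local_cm, "com_local_cm")
  structure(list(mass_kg = mass_kg, com_local_cm = com_local_cm),
            class = "rigid_segment")
}

# Signed distance from a point to each triangle edge, positive inside.
inward_edge_distances <- function(p, triangle) {
  orient <- sign(signed_triangle_area(triangle))
  vapply(1:3, function(i) {
    a <- triangle[i, ]
    b <- triangle[i %% 3L + 1L, ]
    e <- b - a
    orient * (e[1L] * (p[2L] - a[2L]) - e[2L] * (p[1L] - a[1L])) / sqrt(sum(e^2))
  }, numeric(1))
}

#' Ground-truth rigid-body configuration for the simulator
#'
#' The simulated system is the rotating segment, a static remainder (the
#' rest of the body or a ballast block), and a static carrier (the board or
#' frame whose weight also rests on the supports). As the segment sweeps its
#' full circle the system CoM traces a circle of radius
#' `segment mass * |com_local| / total mass`; the constructor verifies that
#' this whole circle stays inside the support triangle, so no simulated
#' posture can tip the board.
#'
#' @param segment A [rigid_segment()].
#' @param rest_mass_kg,rest_com_cm Mass (kg, >= 0) and fixed CoM (cm) of the
#'   static remainder.
#' @param carrier_mass_kg,carrier_com_cm Mass and CoM of the static board or
#'   frame. Any static mass cancels in the estimator; it is carried
#'   separately only so the support loads are physically complete.
#' @param support_triangle 3x2 matrix of support positions, cm, in the board
#'   frame whose origin is the rotation centre.
#' @return An object of class `rigid_body_model`.
#' @export
rigid_body_model <- function(segment, rest_mass_kg, rest_com_cm,
                             carrier_mass_kg = 0, carrier_com_cm = c(0, 0),
                             support_triangle = default_support_triangle()) {
  stopifnot(inherits(segment, "rigid_segment"))
  check_finite_scalar(rest_mass_kg, "rest_mass_kg")
  check_finite_scalar(carrier_mass_kg, "carrier_mass_kg")
  if (rest_mass_kg < 0 || carrier_mass_kg < 0) {
    stop_segmoment("static masses must be non-negative", "segmoment_invalid_input")
  }
  rest_com_cm <- check_planar_point(rest_com_cm, "rest_com_cm")
  carrier_com_cm <- check_planar_point(carrier_com_cm, "carrier_com_cm")
  support_triangle <- as.matrix(support_triangle)
  if (!all(dim(support_triangle) == c(3L, 2L)) || !all(is.finite(support_triangle))) {
    stop_segmoment("'support_triangle' must be a finite 3x2 matrix (cm)",
                   "segmoment_invalid_input")
  }
  if (abs(signed_triangle_area(support_triangle)) <= 1e-6) {
    stop_segmoment("support triangle is degenerate", "segmoment_degenerate_geometry")
  }
  total <- segment$mass_kg + rest_mass_kg + carrier_mass_kg
  static_moment <- rest_mass_kg * rest_com_cm + carrier_mass_kg * carrier_com_cm
  centre <- static_moment / total
  radius <- segment$mass_kg * sqrt(sum(segment$com_local_cm^2)) / total
  if (any(inward_edge_distances(centre, support_triangle) < radius)) {
    stop_segmoment(
      "system CoM leaves the support triangle at some rotation angle (board would tip)",
      "segmoment_tipping"
    )
  }
  structure(
    list(segment = segment,
         rest_mass_kg = rest_mass_kg, rest_com_cm = rest_com_cm,
         carrier_mass_kg = carrier_mass_kg, carrier_com_cm = carrier_com_cm,
         support_triangle = support_triangle,
         total_mass_kg = total),
    class = "rigid_body_model"
  )
}

#' True first-order mass moment of a model
#'
#' @param model A [rigid_body_model()].
#' @return Segment mass times the distance from rotation centre to segment
#'   CoM, kg.cm.
#' @export
true_moment <- function(model) {
  stopifnot(inherits(model, "rigid_body_model"))
  model$segment$mass_kg * sqrt(sum(model$segment$com_local_cm^2))
}

#' Measurement noise model
#'
#' Defaults follow the instrument specification of the weighing protocol
#' (precision 1.5 g, reading resolution 0.1 g) and engineering estimates for
#' manual protractor/straightedge digitisation of the overhead photographs
#' (0.5 deg on the rotation angle, 0.2 cm on support positions). Support
#' positions are digitised once per measurement set and shared between the
#' two postures, since the supports do not move; this makes position error
#' largely cancel in the CoM difference.
#'
#' @param scale_sigma_g Gaussian scale noise SD per reading, grams.
#' @param scale_quantum_g Reading quantisation step, grams, applied after the
#'   Gaussian noise; 0 disables quantisation.
#' @param angle_sigma_deg Gaussian noise SD on the recorded rotation angle.
#' @param position_sigma_cm Gaussian noise SD per coordinate on the recorded
#'   support positions (one draw per set).
#' @param drift_sigma_cm Posture drift between the three sequential
#'   single-scale weighings: SD of an independent perturbation of the true
#'   system CoM for each support reading. Default 0 (rigid dummy).
#' @param seed Optional RNG seed for reproducible sessions.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(scale_sigma_g = 1.5, scale_quantum_g = 0.1,
                        angle_sigma_deg = 0.5, position_sigma_cm = 0.2,
                        drift_sigma_cm = 0, seed = NULL) {
  for (nm in c("scale_sigma_g", "scale_quantum_g", "angle_sigma_deg",
               "position_sigma_cm", "drift_sigma_cm")) {
    v <- get(nm)
    check_finite_scalar(v, nm)
    if (v < 0) stop_segmoment(sprintf("'%s' must be >= 0", nm), "segmoment_invalid_input")
  }
  structure(
    list(scale_sigma_g = scale_sigma_g, scale_quantum_g = scale_quantum_g,
         angle_sigma_deg = angle_sigma_deg, position_sigma_cm = position_sigma_cm,
         drift_sigma_cm = drift_sigma_cm, seed = seed),
    class = "noise_model"
  )
}

#' Noise-free noise model
#'
#' Convenience constructor with every noise source (including quantisation)
#' set to zero; used for inverse-crime checks of the estimator.
#' @param seed Optional RNG seed (unused when all sigmas are zero).
#' @return A [noise_model()] with all sigmas and the quantum equal to 0.
#' @export
zero_noise <- function(seed = NULL) {
  noise_model(scale_sigma_g = 0, scale_quantum_g = 0, angle_sigma_deg = 0,
              position_sigma_cm = 0, drift_sigma_cm = 0, seed = seed)
}

#' Whole-system centre of mass at a segment posture
#'
#' Rotates the segment CoM about the origin by `theta_deg` and mass-weights
#' it with the static remainder and carrier.
#'
#' @param model A [rigid_body_model()].
#' @param theta_deg Segment rotation from the reference posture, degrees.
#' @return A [body_state()] (label `"alpha"` at theta = 0, `"beta"` otherwise).
#' @export
system_com <- function(model, theta_deg) {
  stopifnot(inherits(model, "rigid_body_model"))
  seg_com <- as.numeric(rotation_matrix(theta_deg) %*% model$segment$com_local_cm)
  num <- model$segment$mass_kg * seg_com +
    model$rest_mass_kg * model$rest_com_cm +
    model$carrier_mass_kg * model$carrier_com_cm
  body_state(num / model$total_mass_kg, model$total_mass_kg,
             label = if (theta_deg == 0) "alpha" else "beta")
}

barycentric_weights <- function(com, triangle) {
  A <- rbind(t(triangle), rep(1, 3))
  as.numeric(solve(A, c(com, 1)))
}

#' Exact support loads for a given system CoM (inverse statics)
#'
#' Solves the three-support statics balance: the loads are the barycentric
#' coordinates of the CoM in the support triangle times the total mass.
#' A CoM outside the triangle would require a negative (tensile) support
#' load, i.e. the board tips; that raises a `segmoment_tipping` condition.
#'
#' @param com System centre of mass, (x, y) cm.
#' @param total_mass_kg Total supported mass, kg.
#' @param triangle 3x2 matrix of support positions, cm.
#' @param tip_eps Numerical slack on the non-negativity of the loads.
#' @return A [support_set()] whose readings reproduce `com` and
#'   `total_mass_kg` exactly under [compute_com()].
#' @export
forward_loads <- function(com, total_mass_kg, triangle, tip_eps = 1e-9) {
  com <- check_planar_point(com, "com")
  check_finite_scalar(total_mass_kg, "total_mass_kg")
  triangle <- as.matrix(triangle)
  w <- barycentric_weights(com, triangle)
  if (any(w < -tip_eps)) {
    stop_segmoment(
      sprintf("system CoM (%.3f, %.3f) lies outside the support triangle: board tips",
              com[1L], com[2L]),
      "segmoment_tipping"
    )
  }
  support_set(triangle, pmax(w, 0) * total_mass_kg * 1000)
}

quantize <- function(x, q) if (q > 0) round(x / q) * q else x

# One noisy triple of readings (grams) for a posture. With posture drift the
# three supports are weighed against independently perturbed true CoMs,
# emulating sequential single-scale measurement of a non-rigid subject.
noisy_readings <- function(model, state, noise) {
  tri <- model$support_triangle
  if (noise$drift_sigma_cm > 0) {
    reading_kg <- vapply(1:3, function(i) {
      com_i <- state$com + stats::rnorm(2, 0, noise$drift_sigma_cm)
      forward_loads(com_i, state$total_mass_kg, tri)$mass_kg[i]
    }, numeric(1))
  } else {
    reading_kg <- forward_loads(state$com, state$total_mass_kg, tri)$mass_kg
  }
  g <- reading_kg * 1000 + stats::rnorm(3, 0, noise$scale_sigma_g)
  quantize(g, noise$scale_quantum_g)
}

#' Simulate a measurement session
#'
#' For each requested rotation angle (times `n_repeats`), generates the
#' exact support loads at the reference posture (alpha, theta = 0) and the
#' rotated posture (beta), corrupts the readings with scale noise and
#' quantisation, digitises the support positions once per set with position
#' noise, and records the rotation angle with angle noise. Reproducible for
#' a fixed `noise$seed`.
#'
#' @param model A [rigid_body_model()].
#' @param theta_deg Vector of true rotation angles, degrees; each must pass
#'   the singularity guard.
#' @param noise A [noise_model()].
#' @param n_repeats Number of sets generated per angle.
#' @return An object of class `simulated_session`: a list with `pairs` (each
#'   holding `alpha`/`beta` [support_set()]s built on the recorded support
#'   positions, the recorded and true angles and a `set_id`), `truth`
#'   (`model` and `moment_kgcm`) and the `noise` model used.
#' @export
simulate_session <- function(model, theta_deg, noise = noise_model(),
                             n_repeats = 1) {
  stopifnot(inherits(model, "rigid_body_model"), inherits(noise, "noise_model"))
  for (th in theta_deg) check_rotation_angle(th)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  thetas <- rep(theta_deg, times = n_repeats)
  pairs <- vector("list", length(thetas))
  for (k in seq_along(thetas)) {
    th <- thetas[k]
    state_a <- system_com(model, 0)
    state_b <- system_com(model, th)
    tri_rec <- model$support_triangle +
      matrix(stats::rnorm(6, 0, noise$position_sigma_cm), 3L, 2L)
    read_a <- noisy_readings(model, state_a, noise)
    read_b <- noisy_readings(model, state_b, noise)
    th_rec <- th + stats::rnorm(1, 0, noise$angle_sigma_deg)
    pairs[[k]] <- list(
      set_id = sprintf("set%03d", k),
      alpha = support_set(tri_rec, read_a),
      beta = support_set(tri_rec, read_b),
      theta_deg = th_rec,
      theta_true_deg = th
    )
  }
  structure(
    list(pairs = pairs,
         truth = list(model = model, moment_kgcm = true_moment(model)),
         noise = noise),
    class = "simulated_session"
  )
}

# alpha/beta total-mass tolerance consistent with a noise model: 6 sigma of
# the sum difference, never below the instrument-precision default.
session_mass_tol_kg <- function(noise) {
  max(DEFAULT_MASS_TOL_KG, 6 * sqrt(6) * noise$scale_sigma_g / 1000)
}

#' Estimate the moment for every set of a simulated session
#'
#' Runs the full analysis path (support readings -> CoM -> pair -> moment)
#' on each simulated set, exactly as it would run on real session data.
#'
#' @param session A [simulate_session()] result.
#' @param rotation_center Rotation centre used by the estimator, cm (the
#'   simulator's origin).
#' @return A list of [estimate_moment()] results, one per set.
#' @export
estimate_session <- function(session, rotation_center = c(0, 0)) {
  stopifnot(inherits(session, "simulated_session"))
  tol <- session_mass_tol_kg(session$noise)
  lapply(session$pairs, function(p) {
    pair <- measurement_pair(
      compute_com(p$alpha, label = "alpha"),
      compute_com(p$beta, label = "beta"),
      theta_deg = p$theta_deg,
      rotation_center = rotation_center,
      mass_tol_kg = tol
    )
    estimate_moment(pair)
  })
}

#' Default support triangle for the presets
#'
#' The standard tripod layout: three supports at 120 deg spacing on a 75 cm
#' circle around the static load centre (cm, origin at the rotation
#' centre). An equilateral layout has an isotropic second moment of the
#' support positions, so the CoM sensitivity to reading noise is the same
#' in every direction and the single-set SD follows the inverse chord-gain
#' law in the rotation angle. The physical layouts behind the published
#' experiments were not reported; noise figures obtained with the presets
#' are conditional on this geometry.
#' @return A 3x2 matrix of support positions, cm.
#' @export
default_support_triangle <- function() {
  centre <- c(10, 10)
  radius <- 75
  ang <- deg2rad(c(90, 210, 330))
  cbind(centre[1] + radius * cos(ang), centre[2] + radius * sin(ang))
}

#' Dummy-bar calibration preset
#'
#' The aluminium-bar demonstration configuration: a uniform bar of 3.013 kg
#' and 77.2 cm pivoted at its end (segment CoM at mid-length, 38.6 cm from
#' the rotation centre; calibrated moment 116.3018 kg.cm), a 52.066 kg
#' ballast block as the static remainder, and an 11.627 kg board as carrier.
#' Remainder/carrier CoM positions and the support triangle are plausible
#' stand-ins for the unreported bench layout.
#'
#' @param support_triangle Support layout, 3x2 matrix in cm.
#' @return A [rigid_body_model()].
#' @export
dummy_bar_model <- function(support_triangle = default_support_triangle()) {
  rigid_body_model(
    segment = rigid_segment(mass_kg = 3.013, com_local_cm = c(77.2 / 2, 0)),
    rest_mass_kg = 52.066, rest_com_cm = c(10, 10),
    carrier_mass_kg = 11.627, carrier_com_cm = c(15, 15),
    support_triangle = support_triangle
  )
}

#' Human-leg emulation preset
#'
#' Emulates the leg-rotation session: subject plus clothes 63.460 kg on a
#' 15.569 kg frame, rotation angle 48.8 deg. The subject's true leg
#' parameters are unknown; the segment is tuned so the true moment equals
#' the session mean of 388.8 kg.cm, with a leg mass of 16% of body mass (a
#' standard anthropometric fraction). Intended for qualitative noise studies
#' only.
#'
#' @param support_triangle Support layout, 3x2 matrix in cm.
#' @return A [rigid_body_model()].
#' @export
human_leg_model <- function(support_triangle = default_support_triangle()) {
  leg_mass <- 0.16 * 63.460
  rigid_body_model(
    segment = rigid_segment(mass_kg = leg_mass, com_local_cm = c(388.8 / leg_mass, 0)),
    rest_mass_kg = 63.460 - leg_mass, rest_com_cm = c(12, 8),
    carrier_mass_kg = 15.569, carrier_com_cm = c(10, 10),
    support_triangle = support_triangle
  )
}
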