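# Propagation of measurement noise into moment uncertainty.
#
# Two routes: Monte Carlo through the full simulate -> estimate pipeline,
# and a first-order delta-method closed form through the chord expression
#   moment = M |dCoM| / (2 sin(theta/2)).
# The closed form covers the scale, position and angle sources; posture
# drift (non-rigid subjects) is Monte Carlo only.

#' Monte Carlo uncertainty of a single measurement set
#'
#' Repeats the simulate-then-estimate pipeline `n_reps` times at one
#' rotation angle and reports the spread of the recovered moments around the
#' model's true moment. Replicates whose noisy posture tips the board are
#' dropped and counted; the run aborts if more than `max_tip_frac` of them
#' tip, since the surviving sample would be biased.
#'
#' @param model A [rigid_body_model()].
#' @param theta_deg Rotation angle of the simulated sets, degrees.
#' @param noise A [noise_model()]; its own `seed` is ignored in favour of
#'   `seed`.
#' @param n_reps Number of Monte Carlo replicates (>= 100).
#' @param seed RNG seed for the whole run.
#' @param breakdown If TRUE, also runs one-factor-at-a-time replicates for
#'   the scale, angle and position sources (and drift when active) and
#'   reports each source's share of the summed variance, in percent.
#' @param max_tip_frac Maximum tolerated fraction of tipped replicates.
#' @return An object of class `uncertainty_report`: `mc_mean_kgcm`,
#'   `mc_sd_kgcm`, `mc_relative_sd_pct` (percent of the true moment),
#'   `analytic_sd_kgcm`, `truth_kgcm`, `n_reps`, `n_tipped`, `theta_deg`,
#'   and `breakdown_pct` (named vector or NULL).
#' @export
monte_carlo <- function(model, theta_deg, noise = noise_model(), n_reps = 2000,
                        seed = NULL, breakdown = FALSE, max_tip_frac = 0.01) {
  stopifnot(inherits(model, "rigid_body_model"), inherits(noise, "noise_model"))
  if (n_reps < 100) {
    stop_segmoment("'n_reps' must be at least 100", "segmoment_invalid_input")
  }
  check_rotation_angle(theta_deg)
  if (!is.null(seed)) set.seed(seed)

  run <- function(nz) {
    nz$seed <- NULL
    moments <- numeric(n_reps)
    tipped <- 0L
    kept <- 0L
    for (i in seq_len(n_reps)) {
      m <- tryCatch({
        s <- simulate_session(model, theta_deg, nz, n_repeats = 1)
        estimate_session(s)[[1L]]$moment_kgcm
      }, segmoment_tipping = function(e) NA_real_)
      if (is.na(m)) tipped <- tipped + 1L else {
        kept <- kept + 1L
        moments[kept] <- m
      }
    }
    if (tipped > max_tip_frac * n_reps) {
      stop_segmoment(
        sprintf("%d of %d replicates tipped the board (> %.1f%% allowed); the noise model is too violent for this geometry",
                tipped, n_reps, 100 * max_tip_frac),
        "segmoment_tipping"
      )
    }
    list(moments = moments[seq_len(kept)], tipped = tipped)
  }

  full <- run(noise)
  truth <- true_moment(model)

  breakdown_pct <- NULL
  if (isTRUE(breakdown)) {
    zero <- zero_noise()
    sources <- list(
      scale = utils::modifyList(zero, unclass(noise)[c("scale_sigma_g", "scale_quantum_g")]),
      angle = utils::modifyList(zero, unclass(noise)["angle_sigma_deg"]),
      position = utils::modifyList(zero, unclass(noise)["position_sigma_cm"])
    )
    if (noise$drift_sigma_cm > 0) {
      sources$drift <- utils::modifyList(zero, unclass(noise)["drift_sigma_cm"])
    }
    vars <- vapply(sources, function(nz) {
      class(nz) <- "noise_model"
      stats::var(run(nz)$moments)
    }, numeric(1))
    breakdown_pct <- 100 * vars / sum(vars)
  }

  structure(
    list(mc_mean_kgcm = mean(full$moments),
         mc_sd_kgcm = stats::sd(full$moments),
         mc_relative_sd_pct = 100 * stats::sd(full$moments) / truth,
         analytic_sd_kgcm = if (noise$drift_sigma_cm > 0) NA_real_
                            else analytic_sd(model, theta_deg, noise),
         truth_kgcm = truth,
         n_reps = n_reps,
         n_tipped = full$tipped,
         theta_deg = theta_deg,
         breakdown_pct = breakdown_pct),
    class = "uncertainty_report"
  )
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf("Monte Carlo uncertainty (theta = %.1f deg, %d replicates, %d tipped)\n",
              x$theta_deg, x$n_reps, x$n_tipped))
  cat(sprintf("  true moment     : %.4f kg.cm\n", x$truth_kgcm))
  cat(sprintf("  MC mean         : %.4f kg.cm\n", x$mc_mean_kgcm))
  cat(sprintf("  MC SD           : %.4f kg.cm (%.2f%% of truth)\n",
              x$mc_sd_kgcm, x$mc_relative_sd_pct))
  if (!is.na(x$analytic_sd_kgcm)) {
    cat(sprintf("  analytic SD     : %.4f kg.cm\n", x$analytic_sd_kgcm))
  }
  if (!is.null(x$breakdown_pct)) {
    cat("  variance shares :",
        paste(sprintf("%s %.1f%%", names(x$breakdown_pct), x$breakdown_pct),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' First-order analytic moment uncertainty
#'
#' Delta-method standard deviation of a single-set moment estimate through
#' `moment = M |dCoM| / (2 sin(theta/2))`, combining in quadrature:
#' \itemize{
#'   \item scale noise (Gaussian SD plus quantisation variance q^2/12 per
#'     reading) propagated through the reading-weighted CoM of each posture
#'     and projected on the CoM-difference direction;
#'   \item support-position digitisation noise, shared between the two
#'     postures of a set, which therefore enters only through the change in
#'     barycentric load weights between postures;
#'   \item angle-recording noise through the derivative
#'     `-M |dCoM| cos(theta/2) / (4 sin^2(theta/2))`.
#' }
#' Valid in the small-noise regime; posture drift is not covered (use
#' [monte_carlo()]).
#'
#' @inheritParams monte_carlo
#' @return The predicted SD of a single-set moment estimate, kg.cm.
#' @export
analytic_sd <- function(model, theta_deg, noise = noise_model()) {
  stopifnot(inherits(model, "rigid_body_model"), inherits(noise, "noise_model"))
  check_rotation_angle(theta_deg)
  if (noise$drift_sigma_cm > 0) {
    stop_segmoment("posture drift is not covered by the analytic propagation; use monte_carlo()",
                   "segmoment_invalid_input")
  }
  th <- deg2rad(theta_deg)
  g <- chord_gain(theta_deg)
  state_a <- system_com(model, 0)
  state_b <- system_com(model, theta_deg)
  M <- model$total_mass_kg
  delta <- state_a$com - state_b$com
  dn <- sqrt(sum(delta^2))
  tri <- model$support_triangle

  # scale + quantisation, independent across the six readings of a set
  s2_read <- (noise$scale_sigma_g / 1000)^2 + (noise$scale_quantum_g / 1000)^2 / 12
  Sigma <- matrix(0, 2, 2)
  for (state in list(state_a, state_b)) {
    for (i in 1:3) {
      d <- tri[i, ] - state$com
      Sigma <- Sigma + (s2_read / M^2) * (d %*% t(d))
    }
  }
  var_delta_scale <- if (dn > 0) {
    u <- delta / dn
    as.numeric(t(u) %*% Sigma %*% u)
  } else {
    # on-axis segment CoM: no preferred direction, use the mean eigenvalue
    sum(diag(Sigma)) / 2
  }
  var_scale <- M^2 * var_delta_scale / g^2

  # shared position digitisation: only the weight CHANGE between postures
  w_a <- barycentric_weights(state_a$com, tri)
  w_b <- barycentric_weights(state_b$com, tri)
  var_pos <- M^2 * noise$position_sigma_cm^2 * sum((w_a - w_b)^2) / g^2

  # recorded-angle noise
  dm_dth <- M * dn * cos(th / 2) / (4 * sin(th / 2)^2)
  var_angle <- (dm_dth * deg2rad(noise$angle_sigma_deg))^2

  sqrt(var_scale + var_pos + var_angle)
}

#' Uncertainty sweep over rotation angles
#'
#' Convenience wrapper running [monte_carlo()] (and [analytic_sd()]) on a
#' grid of angles; useful for choosing the rotation angle of a protocol.
#'
#' @inheritParams monte_carlo
#' @param theta_grid_deg Vector of rotation angles, degrees.
#' @return A data.frame with columns `theta_deg`, `mc_mean_kgcm`,
#'   `mc_sd_kgcm`, `mc_relative_sd_pct`, `analytic_sd_kgcm`.
#' @export
angle_sweep <- function(model, theta_grid_deg, noise = noise_model(),
                        n_reps = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(theta_grid_deg, function(th) {
    rep_ <- monte_carlo(model, th, noise, n_reps = n_reps, seed = NULL)
    data.frame(theta_deg = th,
               mc_mean_kgcm = rep_$mc_mean_kgcm,
               mc_sd_kgcm = rep_$mc_sd_kgcm,
               mc_relative_sd_pct = rep_$mc_relative_sd_pct,
               analytic_sd_kgcm = rep_$analytic_sd_kgcm)
  })
  do.call(rbind, rows)
}
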