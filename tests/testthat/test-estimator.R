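pair_from <- function(com_a, com_b, theta, mass = 10) {
  measurement_pair(body_state(com_a, mass, "alpha"),
                   body_state(com_b, mass, "beta"), theta)
}

test_that("moment estimator inverts the rotation difference", {
  # theta = 180: (I - R) = 2I, so moment = M |dCoM| / 2
  est <- estimate_moment(pair_from(c(1, 0), c(0, 0), 180, mass = 10))
  expect_equal(est$moment_kgcm, 5)
  expect_equal(est$com1_alpha, c(0.5, 0))

  # segment CoM on the rotation axis: no displacement, zero moment
  est0 <- estimate_moment(pair_from(c(3, 4), c(3, 4), 90))
  expect_equal(est0$moment_kgcm, 0)

  # moment invariants carried by the estimate object
  expect_equal(est$moment_kgcm,
               sqrt(sum(est$com1_alpha^2)) * est$total_mass_kg)
})

test_that("scalar chord form equals the matrix solve", {
  expect_equal(estimate_moment_scalar(1, 60, 50), 50, tolerance = 1e-15)
  expect_equal(estimate_moment_scalar(2, 180, 10), 10)

  set.seed(4)
  for (i in 1:1000) {
    th <- stats::runif(1, 2, 358)
    mass <- stats::runif(1, 10, 100)
    com_a <- stats::rnorm(2, sd = 5)
    com_b <- as.numeric(rotation_matrix(th) %*% com_a)
    # construct a pair whose CoM difference is (I - R) com_a
    delta <- com_a - com_b
    est <- estimate_moment(pair_from(com_a, com_b, th, mass))
    expect_equal(est$moment_kgcm,
                 estimate_moment_scalar(sqrt(sum(delta^2)), th, mass),
                 tolerance = 1e-12)
    expect_equal(est$com1_alpha, com_a, tolerance = 1e-9)
  }
})

test_that("noiseless estimates are independent of rotation angle and of handedness", {
  model <- dummy_bar_model()
  truth <- true_moment(model)
  for (th in seq(5, 355, by = 25)) {
    sim <- simulate_session(model, th, zero_noise())
    est <- estimate_session(sim)[[1]]
    expect_lt(rel_err(est$moment_kgcm, truth), 1e-10)
  }
  # mirror convention: theta and -theta give identical moments
  sim <- simulate_session(model, 70, zero_noise())
  st_a <- compute_com(sim$pairs[[1]]$alpha)
  st_b <- compute_com(sim$pairs[[1]]$beta)
  m_pos <- estimate_moment(measurement_pair(st_a, st_b, 70))$moment_kgcm
  m_neg <- estimate_moment(measurement_pair(st_a, st_b, -70))$moment_kgcm
  expect_equal(m_pos, m_neg, tolerance = 1e-12)
})

test_that("static carrier mass and placement cancel out of the estimate", {
  seg <- rigid_segment(3.013, c(38.6, 0))
  base <- rigid_body_model(seg, rest_mass_kg = 52.066, rest_com_cm = c(10, 10),
                           carrier_mass_kg = 0)
  variants <- list(
    base,
    rigid_body_model(seg, 52.066, c(10, 10), carrier_mass_kg = 11.627,
                     carrier_com_cm = c(15, 15)),
    rigid_body_model(seg, 52.066, c(10, 10), carrier_mass_kg = 40,
                     carrier_com_cm = c(-5, 20)),
    rigid_body_model(seg, 30, c(-4, 12), carrier_mass_kg = 11.627,
                     carrier_com_cm = c(15, 15))
  )
  for (m in variants) {
    est <- estimate_session(simulate_session(m, 120, zero_noise()))[[1]]
    expect_lt(rel_err(est$moment_kgcm, true_moment(m)), 1e-10)
    expect_equal(true_moment(m), 116.3018)
  }
})

test_that("inconsistent totals and singular angles are rejected at pairing", {
  a <- body_state(c(1, 1), 50, "alpha")
  b_bad <- body_state(c(1, 2), 50.5, "beta")
  expect_error(measurement_pair(a, b_bad, 90),
               class = "segmoment_inconsistent_session")
  expect_silent(measurement_pair(a, b_bad, 90, mass_tol_kg = 1))
  expect_error(measurement_pair(a, body_state(c(1, 2), 50), 0.2),
               class = "segmoment_singular_angle")
})

test_that("session summaries reproduce the textbook statistics", {
  # frozen oracle: sqrt((2^2 + 2^2) / 2) = 2 for deviations of +/- 2
  s <- summarize_session(c(118.3, 114.3), calibrated_kgcm = 116.3)
  expect_equal(s$n, 2L)
  expect_equal(s$mean_kgcm, 116.3)
  expect_equal(s$rms_vs_calibrated_kgcm, 2)
  expect_equal(s$sd_kgcm, stats::sd(c(118.3, 114.3)))

  # single estimate: SD undefined, mean is the value
  s1 <- summarize_session(105.5)
  expect_equal(s1$mean_kgcm, 105.5)
  expect_true(is.na(s1$sd_kgcm))
  expect_true(is.na(s1$rms_vs_calibrated_kgcm))

  # relative figures against calibrated reference, one-decimal presentation
  expect_equal(round(relative_figure(1.619, 116.3), 1), 1.4)
  expect_equal(round(relative_figure(5.3, 388.8), 1), 1.4)
  expect_error(summarize_session(numeric(0)), class = "segmoment_invalid_input")
})
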