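test_that("system CoM rotates the segment and mass-weights the statics", {
  # pure segment: CoM follows the rotation
  solo <- rigid_body_model(rigid_segment(2, c(10, 0)), rest_mass_kg = 0,
                           rest_com_cm = c(0, 0))
  expect_equal(system_com(solo, 90)$com, c(0, 10), tolerance = 1e-12)

  # segment CoM on the axis: system CoM independent of theta
  axis <- rigid_body_model(rigid_segment(2, c(0, 0)), rest_mass_kg = 50,
                           rest_com_cm = c(8, 3))
  for (th in c(0, 45, 160, 300)) {
    expect_equal(system_com(axis, th)$com, system_com(axis, 0)$com,
                 tolerance = 1e-12)
  }

  # chord oracle: |dCoM| between 0 and 180 deg = 2 * moment / total mass
  dummy <- dummy_bar_model()
  d <- system_com(dummy, 0)$com - system_com(dummy, 180)$com
  expect_equal(sqrt(sum(d^2)), 2 * 116.3018 / 66.706, tolerance = 1e-12)
})

test_that("forward statics solves the unique load triple", {
  tri <- right_triangle()
  # frozen oracle: 3x3 linear statics solve
  ss <- forward_loads(c(30, 50), 100, tri)
  expect_equal(ss$mass_kg, c(20, 30, 50))

  centroid <- colMeans(tri)
  expect_equal(forward_loads(centroid, 60, tri)$mass_kg, rep(20, 3))
  expect_equal(forward_loads(tri[1, ], 10, tri)$mass_kg, c(10, 0, 0))

  expect_error(forward_loads(c(80, 80), 100, tri), class = "segmoment_tipping")
})

test_that("forward loads and CoM computation are exact inverses", {
  set.seed(5)
  tri <- rbind(c(-50, -40), c(70, -40), c(10, 80))
  for (i in 1:1000) {
    p <- random_interior_point(tri)
    mass <- stats::runif(1, 10, 120)
    ss <- forward_loads(p, mass, tri)
    st <- compute_com(ss)
    expect_lt(max(abs(st$com - p)) / max(1, sqrt(sum(p^2))), 1e-12)
    expect_lt(abs(st$total_mass_kg - mass) / mass, 1e-12)
    # load conservation before any noise
    expect_equal(sum(ss$mass_kg), mass, tolerance = 1e-13)
  }
})

test_that("noiseless simulation commits the inverse crime exactly", {
  set.seed(6)
  for (i in 1:10) {
    model <- random_model()
    th <- stats::runif(1, 20, 340)
    est <- estimate_session(simulate_session(model, th, zero_noise()))[[1]]
    expect_lt(rel_err(est$moment_kgcm, true_moment(model)), 1e-10)
  }
})

test_that("sessions are reproducible for a fixed seed and vary otherwise", {
  model <- dummy_bar_model()
  nz <- noise_model(seed = 99)
  s1 <- simulate_session(model, c(40, 90, 150), nz, n_repeats = 2)
  s2 <- simulate_session(model, c(40, 90, 150), nz, n_repeats = 2)
  expect_identical(s1$pairs, s2$pairs)

  s3 <- simulate_session(model, c(40, 90, 150), noise_model(seed = 100),
                         n_repeats = 2)
  expect_false(identical(s1$pairs, s3$pairs))
  expect_length(s1$pairs, 6)
})

test_that("noise enters each documented channel", {
  model <- dummy_bar_model()
  # scale noise only: positions and angle stay exact, readings do not
  s <- simulate_session(model, 90, noise_model(scale_sigma_g = 1.5,
                                               scale_quantum_g = 0,
                                               angle_sigma_deg = 0,
                                               position_sigma_cm = 0,
                                               seed = 1))
  p <- s$pairs[[1]]
  expect_identical(unname(p$alpha$points), unname(model$support_triangle))
  expect_identical(p$theta_deg, 90)
  exact <- forward_loads(system_com(model, 0)$com, model$total_mass_kg,
                         model$support_triangle)
  expect_false(any(p$alpha$reading_g == exact$reading_g))

  # quantisation: readings are multiples of the quantum
  sq <- simulate_session(model, 90, noise_model(seed = 2))
  steps <- sq$pairs[[1]]$beta$reading_g / 0.1
  expect_lt(max(abs(steps - round(steps))), 1e-6)

  # truth sidecar
  expect_equal(s$truth$moment_kgcm, 116.3018)
})

test_that("models whose CoM circle leaves the triangle are rejected", {
  expect_error(
    rigid_body_model(rigid_segment(30, c(60, 0)), rest_mass_kg = 5,
                     rest_com_cm = c(0, 0)),
    class = "segmoment_tipping"
  )
  expect_error(
    rigid_body_model(rigid_segment(1, c(1, 0)), rest_mass_kg = 10,
                     rest_com_cm = c(0, 0),
                     support_triangle = rbind(c(0, 0), c(1, 1), c(2, 2))),
    class = "segmoment_degenerate_geometry"
  )
})
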