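test_that("zero noise collapses the Monte Carlo to the truth", {
  model <- dummy_bar_model()
  rep0 <- monte_carlo(model, 90, zero_noise(), n_reps = 100, seed = 1)
  expect_equal(rep0$mc_sd_kgcm, 0)
  expect_equal(rep0$mc_mean_kgcm, true_moment(model), tolerance = 1e-10)
  expect_equal(rep0$analytic_sd_kgcm, 0)
  expect_identical(rep0$n_tipped, 0L)
})

test_that("moment SD doubles with the scale noise and shrinks with the chord gain", {
  model <- dummy_bar_model()
  scale_only <- function(sig) {
    noise_model(scale_sigma_g = sig, scale_quantum_g = 0,
                angle_sigma_deg = 0, position_sigma_cm = 0)
  }
  r1 <- monte_carlo(model, 90, scale_only(1.5), n_reps = 1500, seed = 10)
  r2 <- monte_carlo(model, 90, scale_only(3.0), n_reps = 1500, seed = 11)
  expect_equal(r2$mc_sd_kgcm / r1$mc_sd_kgcm, 2, tolerance = 0.1)

  # analytic scaling in theta follows 1 / (2 sin(theta/2)) for CoM-level
  # noise; the tripod layout makes the residual anisotropy negligible
  a30 <- analytic_sd(model, 30, scale_only(1.5))
  a180 <- analytic_sd(model, 180, scale_only(1.5))
  expect_equal(a30 / a180, chord_gain(180) / chord_gain(30), tolerance = 0.01)
})

test_that("relative SD is non-increasing in theta under CoM-level noise", {
  model <- dummy_bar_model()
  nz <- noise_model(scale_sigma_g = 1.5, scale_quantum_g = 0.1,
                    angle_sigma_deg = 0, position_sigma_cm = 0)
  set.seed(12)
  sweep <- angle_sweep(model, c(30, 60, 90, 135, 180), nz, n_reps = 1200)
  # allow Monte Carlo jitter on what is a strongly decreasing trend
  expect_true(all(diff(sweep$mc_relative_sd_pct) < 0.05 * sweep$mc_relative_sd_pct[-5]))
  expect_gt(sweep$mc_relative_sd_pct[1], 2 * sweep$mc_relative_sd_pct[5])
})

test_that("first-order propagation matches Monte Carlo in the small-noise regime", {
  model <- dummy_bar_model()
  nz <- noise_model()
  mc <- monte_carlo(model, 90, nz, n_reps = 5000, seed = 13)
  expect_lt(abs(mc$analytic_sd_kgcm - mc$mc_sd_kgcm) / mc$mc_sd_kgcm, 0.15)

  # and at a second angle where the angle term dominates differently
  mc2 <- monte_carlo(model, 150, nz, n_reps = 5000, seed = 14)
  expect_lt(abs(mc2$analytic_sd_kgcm - mc2$mc_sd_kgcm) / mc2$mc_sd_kgcm, 0.15)
})

test_that("the norm estimator is biased upward at high noise and unbiased in the limit", {
  model <- dummy_bar_model()
  heavy <- noise_model(scale_sigma_g = 400, scale_quantum_g = 0,
                       angle_sigma_deg = 0, position_sigma_cm = 0)
  light <- noise_model(scale_sigma_g = 1.5, scale_quantum_g = 0,
                       angle_sigma_deg = 0, position_sigma_cm = 0)
  truth <- true_moment(model)
  bias_heavy <- monte_carlo(model, 90, heavy, n_reps = 2000, seed = 15)$mc_mean_kgcm - truth
  bias_light <- monte_carlo(model, 90, light, n_reps = 2000, seed = 16)$mc_mean_kgcm - truth
  expect_gt(bias_heavy, 1)          # clearly positive, kg.cm
  expect_lt(abs(bias_light), 0.05)  # vanishing with the noise
  expect_gt(bias_heavy, abs(bias_light))
})

test_that("per-source variance breakdown identifies the dominant source", {
  model <- dummy_bar_model()
  rep_ <- monte_carlo(model, 90, noise_model(), n_reps = 600, seed = 17,
                      breakdown = TRUE)
  expect_equal(sum(rep_$breakdown_pct), 100)
  expect_named(rep_$breakdown_pct, c("scale", "angle", "position"))
  # with the default manual-digitisation model the angle term dominates
  expect_gt(rep_$breakdown_pct[["angle"]], 50)
})

test_that("violent noise aborts on excessive tipping and drift blocks the analytic form", {
  tiny_tri <- rbind(c(-6, -5), c(8, -5), c(1, 9))
  model <- rigid_body_model(rigid_segment(2, c(2, 0)), rest_mass_kg = 30,
                            rest_com_cm = c(1, 1), support_triangle = tiny_tri)
  wild <- noise_model(scale_sigma_g = 0, angle_sigma_deg = 0,
                      position_sigma_cm = 0, drift_sigma_cm = 8)
  expect_error(monte_carlo(model, 90, wild, n_reps = 100, seed = 18),
               class = "segmoment_tipping")
  expect_error(analytic_sd(model, 90, wild), class = "segmoment_invalid_input")
  expect_error(monte_carlo(model, 90, noise_model(), n_reps = 10),
               class = "segmoment_invalid_input")
})
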