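ref_hist <- simulate_decay(decay_sim_spec(3.6, 1, total_photons = 1e6))

test_that("theoretical reference modulation and phase match the closed form", {
  w <- 2 * pi / 50
  m_th <- 1 / sqrt(1 + (w * 3.6)^2)
  phi_th <- atan(w * 3.6)
  # frozen from the brute-force integration oracle below
  expect_equal(m_th, 0.91110, tolerance = 1e-4)
  expect_equal(phi_th, 0.42484, tolerance = 1e-4)
  # brute-force integration agrees with the closed form
  num <- phasor_numeric(3.6, 1)
  expect_equal(sqrt(sum(num^2)), m_th, tolerance = 1e-6)
  expect_equal(atan2(num["s"], num["g"]), phi_th,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("an ideally simulated reference self-calibrates to ~identity", {
  cal <- build_calibration(ref_hist, 3.6, 1:8)
  expect_equal(cal$scale, rep(1, 8), tolerance = 1e-3)
  expect_equal(cal$offset, rep(0, 8), tolerance = 1e-3)
  # applying the calibration to the reference's own phasors lands exactly on
  # the theoretical mono-exponential point
  pts <- apply_calibration(phasor_transform(ref_hist, 1:8), cal)
  expect_equal(pts$m, 1 / sqrt(1 + (pts$omega * 3.6)^2), tolerance = 1e-9)
  expect_equal(pts$phi, atan(pts$omega * 3.6), tolerance = 1e-9)
  on_circle <- (pts$g - 0.5)^2 + pts$s^2 - 0.25
  expect_equal(on_circle, rep(0, 8), tolerance = 1e-9)
})

test_that("a phase-rotated reference shifts the offset by exactly the rotation", {
  # circularly advancing the histogram by m bins rotates the measured phase
  # at harmonic k by exactly -m*k*2*pi/n_bins, so the offset grows by +rot
  m_bins <- 8
  rot <- 2 * pi * m_bins / 256
  shifted <- decay_histogram(c(tail(ref_hist$counts, -m_bins),
                               head(ref_hist$counts, m_bins)))
  cal0 <- build_calibration(ref_hist, 3.6, 1:2)
  cal1 <- build_calibration(shifted, 3.6, 1:2)
  expect_equal(cal1$offset - cal0$offset, rot * (1:2), tolerance = 1e-9)
  expect_equal(cal1$scale, cal0$scale, tolerance = 1e-9)
})

test_that("mono-exponential lifetimes are recovered by phase and modulation", {
  cal <- build_calibration(ref_hist, 3.6, 1)
  pt <- apply_calibration(phasor_transform(ref_hist, 1), cal)
  est <- mono_lifetime(pt)
  expect_equal(est$tau_phase_ns, 3.6, tolerance = 0.01)
  expect_equal(est$tau_mod_ns, 3.6, tolerance = 0.01)

  # phi = 0, m = 1 gives zero lifetime by both routes
  zero <- structure(data.frame(harmonic = 1, omega = 2 * pi / 50, g = 1,
                               s = 0, m = 1, phi = 0, photons = 1),
                    period_ns = 50, n_bins = 256,
                    class = c("phasor_set", "data.frame"))
  est0 <- mono_lifetime(zero)
  expect_equal(est0$tau_phase_ns, 0)
  expect_equal(est0$tau_mod_ns, 0)

  # unphysical points are flagged, not silently inverted
  bad <- zero; bad$m <- 1.2; bad$phi <- -0.1
  expect_warning(estb <- mono_lifetime(bad), "physical")
  expect_true(is.na(estb$tau_phase_ns))
})

test_that("inside the universal circle, tau_mod exceeds tau_phase", {
  cal <- build_calibration(ref_hist, 3.6, 1)
  for (a1 in seq(0.1, 0.9, 0.2)) {
    h <- simulate_decay(decay_sim_spec(c(0.4, 3), c(a1, 1 - a1)))
    est <- mono_lifetime(apply_calibration(phasor_transform(h, 1), cal))
    expect_gt(est$tau_mod_ns, est$tau_phase_ns)
  }
})

test_that("calibration errors: missing harmonic and zero modulation", {
  cal <- build_calibration(ref_hist, 3.6, 1:2)
  pts <- phasor_transform(ref_hist, 1:4)
  expect_error(apply_calibration(pts, cal), "harmonic")
  expect_error(build_calibration(decay_histogram(rep(1, 256)), 3.6, 1),
               "modulation")
})
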