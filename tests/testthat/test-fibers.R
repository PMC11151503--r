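test_that("Herman endpoints: aligned, random and perpendicular cases", {
  # all mass at the reference angle
  expect_equal(hermans_index(rep(30, 50), reference_angle_deg = 30)$S, 1)
  # delta law via the sampler
  ang <- sample_fiber_angles(list(type = "delta", theta0_deg = 12), 100)
  expect_true(all(ang == 12))
  expect_equal(hermans_index(ang)$S, 1)
  # uniform law: S ~ 0 against a fixed axis
  u <- sample_fiber_angles(list(type = "uniform"), 10000, seed = 7)
  expect_lt(abs(hermans_index(u, reference_angle_deg = 0)$S), 0.02)
  # all mass perpendicular to an explicitly fixed reference axis
  expect_equal(hermans_index(rep(0, 10), reference_angle_deg = 90)$S, -1,
               tolerance = 1e-12)
  expect_error(hermans_index(numeric(0)), "empty")
})

test_that("the principal-axis reference maximizes S and keeps it in [0,1]", {
  set.seed(3)
  for (th0 in c(-60, 0, 40)) {
    ang <- sample_fiber_angles(list(type = "wrapped_normal", theta0_deg = th0,
                                    kappa = 4), 2000)
    res <- hermans_index(ang)
    expect_gte(res$S, 0)
    expect_lte(res$S, 1)
    expect_lt(abs(wrap_angle_deg(res$reference_angle_deg - th0)), 5)
    # any other reference gives a smaller S
    expect_gte(res$S + 1e-12,
               hermans_index(ang, reference_angle_deg = th0 + 15)$S)
  }
})

test_that("S is monotone in the wrapped-normal concentration", {
  S <- vapply(c(0, 0.5, 1, 2, 5, 20), function(kappa) {
    ang <- sample_fiber_angles(list(type = "wrapped_normal", theta0_deg = 0,
                                    kappa = kappa), 10000, seed = 71)
    hermans_index(ang, reference_angle_deg = 0)$S
  }, numeric(1))
  expect_true(all(diff(S) > 0))
  # kappa -> infinity collapses to the delta law
  ang <- sample_fiber_angles(list(type = "wrapped_normal", theta0_deg = 25,
                                  kappa = 1e8), 100, seed = 1)
  expect_equal(ang, rep(25, 100), tolerance = 1e-2)
})

test_that("structure-tensor orientation recovers rendered fiber angles", {
  sim <- simulate_fiber_image(fiber_scene_spec(
    c(384, 384), 40, list(type = "delta", theta0_deg = 30),
    fiber_width_px = 6, seed = 1))
  od <- orientation_distribution(sim$image)
  res <- hermans_index(od)
  expect_equal(res$S, 1, tolerance = 0.01)
  expect_lt(abs(wrap_angle_deg(res$reference_angle_deg - 30)), 2)
  expect_error(orientation_distribution(channel_image(matrix(1, 32, 32))),
               "constant")
})

test_that("orientation analysis is equivariant under image rotation by 90 deg", {
  sim <- simulate_fiber_image(fiber_scene_spec(
    c(256, 256), 30, list(type = "delta", theta0_deg = 20),
    fiber_width_px = 5, seed = 4))
  rot <- channel_image(t(unclass(sim$image))[, nrow(sim$image):1],
                       pixel_size_um = attr(sim$image, "pixel_size_um"))
  a1 <- hermans_index(orientation_distribution(sim$image))
  a2 <- hermans_index(orientation_distribution(rot))
  expect_lt(abs(wrap_angle_deg(a2$reference_angle_deg -
                                 (a1$reference_angle_deg + 90))), 2)
  expect_equal(a1$S, a2$S, tolerance = 0.02)
})

test_that("a many-fiber uniform scene has a roughly flat image distribution", {
  # scaled-down flatness check: a few hundred rendered fibers leave visible
  # per-bin sampling noise (sd ~ 1/sqrt(n_fibers)), so the bound is on gross
  # anisotropy only; heavier occlusion would saturate the field
  sim <- simulate_fiber_image(fiber_scene_spec(
    c(512, 512), 200, list(type = "uniform"), fiber_width_px = 4, seed = 9))
  od <- orientation_distribution(sim$image)
  h <- tapply(od$weights, cut(od$angles_deg, seq(-90, 90, by = 10)), sum)
  h[is.na(h)] <- 0
  expect_lt(max(h), 2.5 / length(h))
  expect_lt(abs(hermans_index(od, reference_angle_deg = 0)$S), 0.15)
})

test_that("fiber diameters are recovered within discretization tolerance", {
  one <- simulate_fiber_image(fiber_scene_spec(
    c(256, 256), 1, list(type = "delta", theta0_deg = 20),
    fiber_width_px = 10, pixel_size_um = 0.05, seed = 2))
  fd <- fiber_diameter(one$image)
  expect_equal(fd$mean_um, 0.5, tolerance = 0.1 * 0.5)
  # doubling the width doubles the estimate
  two <- simulate_fiber_image(fiber_scene_spec(
    c(256, 256), 1, list(type = "delta", theta0_deg = 20),
    fiber_width_px = 20, pixel_size_um = 0.05, seed = 2))
  fd2 <- fiber_diameter(two$image)
  expect_equal(fd2$mean_um / fd$mean_um, 2, tolerance = 0.15)
  expect_error(fiber_diameter(channel_image(matrix(0:1, 2, 2) * 0)),
               "constant|foreground")
})

test_that("fiber scenes are reproducible and validated", {
  spec <- fiber_scene_spec(c(64, 64), 5, list(type = "uniform"),
                           fiber_width_px = 4, seed = 3)
  expect_identical(unclass(simulate_fiber_image(spec)$image),
                   unclass(simulate_fiber_image(spec)$image))
  expect_error(fiber_scene_spec(c(64, 64), 0), "n_fibers")
  expect_error(fiber_scene_spec(c(64, 64), 5, fiber_width_px = 0),
               "zero-width")
  expect_error(fiber_scene_spec(c(64, 64), 5,
                                orientation_law = list(type = "delta",
                                                       theta0_deg = 90)),
               "theta0")
})
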