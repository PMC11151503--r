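cal <- build_calibration(simulate_decay(decay_sim_spec(3.6, 1,
                                                       total_photons = 1e6)),
                         3.6, 1:8)

two_pop_scene <- function(noise = "poisson", seed = 7) {
  cells <- list(
    cell_desc(c(18, 18), 10, 4,
              decay = list(lifetimes_ns = c(0.4, 2.5),
                           amplitude_fractions = c(0.3, 0.7),
                           photons_per_pixel = 3000)),
    cell_desc(c(46, 46), 10, 4,
              decay = list(lifetimes_ns = c(0.4, 2.5),
                           amplitude_fractions = c(0.8, 0.2),
                           photons_per_pixel = 3000)))
  scene_spec(c(64, 64), cells = cells, noise_model = noise, seed = seed)
}

test_that("per-cell fits separate two programmed metabolic populations", {
  sim <- simulate_flim_image(two_pop_scene())
  tab <- per_cell_flim(sim$flim, sim$ground_truth$cell_labels, cal)
  expect_equal(nrow(tab), 2)
  truth <- sim$ground_truth$cells
  expect_equal(tab$alpha1, truth$true_alpha1, tolerance = 0.02)
  # indices form disjoint clusters in the right order (0.3/0.7 vs 0.8/0.2)
  expect_lt(tab$metabolic_index[tab$cell_id == 1], 1)
  expect_gt(tab$metabolic_index[tab$cell_id == 2], 2)
})

test_that("zero-background FLIM scenes have photons only inside cells", {
  sim <- simulate_flim_image(two_pop_scene(noise = "none"))
  totals <- apply(sim$flim$counts, c(1, 2), sum)
  expect_true(all((totals > 0) == (unclass(sim$ground_truth$cell_labels) > 0)))
})

test_that("an empty scene yields all-zero histograms and an empty label map", {
  sim <- simulate_flim_image(scene_spec(c(16, 16), cells = list()))
  expect_true(all(sim$flim$counts == 0))
  expect_true(all(sim$ground_truth$cell_labels == 0))
  tab <- per_cell_flim(sim$flim, sim$ground_truth$cell_labels, cal)
  expect_equal(nrow(tab), 0)
})

test_that("a homogeneous field gives equal per-cell indices", {
  cells <- lapply(list(c(16, 16), c(16, 48), c(48, 16), c(48, 48)),
                  function(p) cell_desc(p, 9, 4,
                    decay = list(lifetimes_ns = c(0.4, 2.5),
                                 amplitude_fractions = c(0.6, 0.4),
                                 photons_per_pixel = 2000)))
  sim <- simulate_flim_image(scene_spec(c(64, 64), cells = cells))
  tab <- per_cell_flim(sim$flim, sim$ground_truth$cell_labels, cal)
  expect_equal(nrow(tab), 4)
  expect_lt(diff(range(tab$metabolic_index)), 1e-6)
})

test_that("an infinite photon threshold drops every cell with a warning", {
  sim <- simulate_flim_image(two_pop_scene())
  expect_warning(
    tab <- per_cell_flim(sim$flim, sim$ground_truth$cell_labels, cal,
                         min_photons = Inf),
    "dropped")
  expect_equal(nrow(tab), 0)
})

test_that("overlapping cells are resolved by nearest center with a warning", {
  cells <- list(
    cell_desc(c(20, 20), 10, 4,
              decay = list(lifetimes_ns = 2, amplitude_fractions = 1,
                           photons_per_pixel = 100)),
    cell_desc(c(28, 20), 10, 4,
              decay = list(lifetimes_ns = 2, amplitude_fractions = 1,
                           photons_per_pixel = 100)))
  expect_warning(sim <- simulate_flim_image(scene_spec(c(48, 48),
                                                       cells = cells)),
                 "nearest-center")
  lab <- unclass(sim$ground_truth$cell_labels)
  expect_setequal(setdiff(unique(as.vector(lab)), 0L), c(1L, 2L))
  # the midpoint column splits between the two centers
  expect_equal(lab[20, 22], 1L)
  expect_equal(lab[20, 26], 2L)
})

test_that("calibrated mono-exponential phasors satisfy the universal circle", {
  # continuum identity: verified at fine binning where discretization is
  # negligible; the 256-bin instrument layout has a documented ~5e-5 floor
  ref <- simulate_decay(decay_sim_spec(3.6, 1, n_bins = 4096,
                                       total_photons = 1e6))
  calf <- build_calibration(ref, 3.6, 1)
  for (tau in c(0.4, 1, 3.6, 9)) {
    h <- simulate_decay(decay_sim_spec(tau, 1, n_bins = 4096))
    p <- apply_calibration(phasor_transform(h, 1), calf)
    expect_lt(abs((p$g - 0.5)^2 + p$s^2 - 0.25), 1e-6)
  }
})

test_that("the phase-lifetime display map is uniform on a uniform cell", {
  cells <- list(cell_desc(c(16, 16), 10, 4,
                          decay = list(lifetimes_ns = 2,
                                       amplitude_fractions = 1,
                                       photons_per_pixel = 4000)))
  sim <- simulate_flim_image(scene_spec(c(32, 32), cells = cells))
  m <- flim_phase_lifetime_map(sim$flim, cal)
  vals <- m[!is.na(m)]
  expect_gt(length(vals), 100)
  expect_equal(unname(vals), rep(2, length(vals)), tolerance = 0.01)
})
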