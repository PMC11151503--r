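mk_img <- function(m, ch = "NADH", norm = FALSE) {
  channel_image(m, ch, normalized = norm)
}

test_that("ORR boundary identities hold exactly", {
  z <- matrix(0, 8, 8)
  pos <- matrix(5, 8, 8)
  expect_true(all(orr_map(mk_img(z, "NADH"), mk_img(pos, "FAD"))$orr_map == 1))
  expect_true(all(orr_map(mk_img(pos, "NADH"), mk_img(z, "FAD"))$orr_map == 0))
  expect_true(all(orr_map(mk_img(pos, "NADH"),
                          mk_img(pos, "FAD"))$orr_map == 0.5))
  # undefined pixels are masked, never imputed
  both0 <- orr_map(mk_img(z, "NADH"), mk_img(z, "FAD"))
  expect_true(all(is.na(both0$orr_map)))
})

test_that("ORR is within [0,1], monotone in FAD, and errors on mismatches", {
  set.seed(1)
  n <- matrix(rexp(64, 1 / 50), 8, 8)
  f1 <- matrix(rexp(64, 1 / 30), 8, 8)
  o1 <- orr_map(mk_img(n, "NADH"), mk_img(f1, "FAD"))$orr_map
  o2 <- orr_map(mk_img(n, "NADH"), mk_img(f1 * 2, "FAD"))$orr_map
  expect_true(all(o1 >= 0 & o1 <= 1, na.rm = TRUE))
  expect_true(all(o2 >= o1, na.rm = TRUE))
  expect_error(orr_map(mk_img(n, "NADH"), mk_img(matrix(1, 4, 4), "FAD")),
               "shape")
  expect_error(orr_map(mk_img(n, "NADH", norm = TRUE), mk_img(f1, "FAD")),
               "normalization")
})

test_that("reference normalization removes acquisition gain exactly", {
  set.seed(2)
  img <- matrix(runif(100, 10, 100), 10, 10)
  ref <- matrix(20, 10, 10)
  out <- normalize_by_reference(mk_img(img), mk_img(ref, "reference"))
  expect_equal(as.vector(out), as.vector(img / 20))
  expect_true(attr(out, "normalized"))
  # self-normalization has unit spatial mean
  self <- normalize_by_reference(mk_img(img), mk_img(img))
  expect_equal(mean(self), 1, tolerance = 1e-12)
  # two acquisitions differing only by gain agree after own-reference scaling
  k <- 3.7
  a <- normalize_by_reference(mk_img(img), mk_img(ref, "reference"))
  b <- normalize_by_reference(mk_img(img * k), mk_img(ref * k, "reference"))
  expect_equal(unclass(a), unclass(b), tolerance = 1e-9)
  expect_error(normalize_by_reference(mk_img(img),
                                      mk_img(matrix(0, 10, 10), "reference")),
               "mean")
})

test_that("joint gain changes leave the ORR map unchanged", {
  set.seed(3)
  n <- matrix(runif(64, 5, 50), 8, 8)
  f <- matrix(runif(64, 5, 50), 8, 8)
  ref <- matrix(10, 8, 8)
  o1 <- orr_map(normalize_by_reference(mk_img(n, "NADH"), mk_img(ref)),
                normalize_by_reference(mk_img(f, "FAD"), mk_img(ref)))
  k <- 2.4
  o2 <- orr_map(normalize_by_reference(mk_img(n * k, "NADH"), mk_img(ref * k)),
                normalize_by_reference(mk_img(f * k, "FAD"), mk_img(ref * k)))
  expect_equal(o1$orr_map, o2$orr_map, tolerance = 1e-9)
})

orr_scene <- function(orr_values, noise = "none", seed = NULL) {
  cells <- lapply(seq_along(orr_values), function(i) {
    fad <- 100 * orr_values[i] / (1 - orr_values[i])
    cell_desc(c(20 + 40 * (i - 1), 20), 12, 5,
              channels = list(NADH = 100, FAD = fad))
  })
  simulate_channel_scene(scene_spec(c(40, 40 * length(orr_values)),
                                    cells = cells, noise_model = noise,
                                    seed = seed),
                         c("NADH", "FAD"))
}

test_that("per-cell ORR recovers programmed redox states exactly when noiseless", {
  sim <- orr_scene(c(0.31, 0.27))
  res <- per_cell_orr(orr_map(sim$images$NADH, sim$images$FAD),
                      sim$ground_truth$cell_labels,
                      sim$ground_truth$nucleus_labels)
  expect_equal(res$per_cell$mean_orr, c(0.31, 0.27), tolerance = 1e-9)
  expect_equal(diff(res$per_cell$mean_orr), -0.04, tolerance = 1e-9)
})

test_that("nucleus exclusion shields the per-cell mean from nuclear pixels", {
  sim <- orr_scene(0.31)
  m <- orr_map(sim$images$NADH, sim$images$FAD)
  base <- per_cell_orr(m, sim$ground_truth$cell_labels,
                       sim$ground_truth$nucleus_labels)$per_cell$mean_orr
  # poison the nucleus pixels with extreme values
  poisoned <- m
  poisoned$orr_map[unclass(sim$ground_truth$nucleus_labels) > 0] <- 1
  after <- per_cell_orr(poisoned, sim$ground_truth$cell_labels,
                        sim$ground_truth$nucleus_labels)$per_cell$mean_orr
  expect_equal(after, base, tolerance = 1e-12)
  # excluding an empty nucleus mask equals whole-cell aggregation
  empty <- label_map(matrix(0L, 40, 40), "nuclei")
  whole <- per_cell_orr(m, sim$ground_truth$cell_labels)$per_cell
  with_empty <- per_cell_orr(m, sim$ground_truth$cell_labels, empty)$per_cell
  expect_equal(whole, with_empty)
})

test_that("cells below the pixel floor are dropped with a warning", {
  sim <- orr_scene(c(0.31, 0.27))
  m <- orr_map(sim$images$NADH, sim$images$FAD)
  # mask out most of cell 2
  m$orr_map[, 41:80][unclass(sim$ground_truth$cell_labels)[, 41:80] == 2] <- NA
  keep <- which(unclass(sim$ground_truth$cell_labels) == 2)[1:5]
  m$orr_map[keep] <- 0.27
  expect_warning(res <- per_cell_orr(m, sim$ground_truth$cell_labels,
                                     sim$ground_truth$nucleus_labels),
                 "dropped")
  expect_equal(res$per_cell$cell_id, 1)
})
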