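test_that("integrated intensity is exact, linear, and conserves photons", {
  img <- matrix(0, 32, 32)
  mask <- raster_disk(32, 8)
  img[mask] <- 3.5
  lab <- as_labels(mask, "cell")
  tab <- integrated_intensity(channel_image(img), lab)
  expect_equal(tab$integrated_intensity, 3.5 * sum(mask))
  expect_equal(tab$area_px, sum(mask))
  tab2 <- integrated_intensity(channel_image(img * 2), lab)
  expect_equal(tab2$integrated_intensity, 2 * tab$integrated_intensity)
  # bookkeeping against the generator ground truth, and against the image total
  sc <- scene_spec(c(64, 64), cells = list(
    cell_desc(c(20, 20), 10, 4, channels = list(vimentin = 7)),
    cell_desc(c(45, 45), 12, 5, channels = list(vimentin = 11))))
  sim <- simulate_channel_scene(sc, "vimentin")
  got <- integrated_intensity(sim$images$vimentin, sim$ground_truth$cell_labels)
  expect_equal(got$integrated_intensity,
               sim$ground_truth$cells$true_integrated_vimentin,
               tolerance = 1e-6)
  expect_lte(sum(got$integrated_intensity), sum(sim$images$vimentin))
  # empty labels yield an empty table
  empty <- integrated_intensity(channel_image(img),
                                label_map(matrix(0L, 32, 32), "cell"))
  expect_equal(nrow(empty), 0)
})

test_that("fold change normalizes to the baseline condition mean", {
  tab <- data.frame(cell_id = 1:6,
                    condition = rep(c("random", "aligned"), each = 3),
                    integrated_intensity = c(10, 10, 10, 11.3, 11.3, 11.3))
  out <- fold_change(tab, "random")
  expect_equal(mean(out$fold_change[out$condition == "random"]), 1)
  expect_equal(mean(out$fold_change[out$condition == "aligned"]), 1.13)
  same <- fold_change(data.frame(cell_id = 1:4,
                                 condition = rep(c("a", "b"), 2),
                                 integrated_intensity = rep(5, 4)), "a")
  expect_true(all(same$fold_change == 1))
  single <- fold_change(data.frame(cell_id = 1:2, condition = c("a", "b"),
                                   integrated_intensity = c(4, 6)), "a")
  expect_equal(single$fold_change, c(1, 1.5))
  expect_error(fold_change(tab, "missing"), "baseline")
})

test_that("circularity matches closed forms on rasterized shapes", {
  disk <- nuclear_circularity(as_labels(raster_disk(256, 100)))
  expect_equal(disk$circularity_raw, 1, tolerance = 0.02)
  expect_lte(disk$circularity, 1)

  sq <- matrix(FALSE, 256, 256); sq[53:203, 50:200] <- TRUE
  square <- nuclear_circularity(as_labels(sq))
  expect_equal(square$circularity_raw, pi / 4, tolerance = 0.03)

  ell <- nuclear_circularity(as_labels(raster_ellipse(300, 100, 50)))
  oracle <- 4 * pi * (pi * 100 * 50) / ramanujan_perimeter(100, 50)^2
  expect_equal(ell$circularity_raw, oracle, tolerance = 0.03)
})

test_that("circularity is invariant to translation and rotation", {
  base <- nuclear_circularity(as_labels(raster_ellipse(300, 80, 40)))
  shifted <- nuclear_circularity(as_labels(
    raster_ellipse(300, 80, 40) |> (\(m) {
      out <- matrix(FALSE, 300, 300)
      out[31:300, 16:300] <- m[1:270, 1:285]
      out
    })()))
  expect_equal(shifted$circularity_raw, base$circularity_raw, tolerance = 0.03)
  for (ang in c(20, 45, 75)) {
    rot <- nuclear_circularity(as_labels(raster_ellipse(300, 80, 40, ang)))
    expect_equal(rot$circularity_raw, base$circularity_raw, tolerance = 0.03)
  }
})

test_that("degenerate objects are flagged and the estimator switch works", {
  lab <- matrix(0L, 8, 8); lab[3, 3] <- 1L
  expect_warning(res <- nuclear_circularity(label_map(lab, "nuclei")),
                 "single pixel")
  expect_true(is.na(res$circularity))
  # the naive pixel-edge estimator biases disk circularity low, as documented
  disk <- as_labels(raster_disk(128, 40))
  crofton <- nuclear_circularity(disk)$circularity_raw
  edge <- nuclear_circularity(disk, perimeter_method = "edge")$circularity_raw
  expect_lt(edge, 0.7)
  expect_gt(crofton, 0.97)
})
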