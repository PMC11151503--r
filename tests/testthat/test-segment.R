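nuclei_scene <- function(k = 3, noise = "poisson", seed = 5) {
  pos <- list(c(20, 20), c(60, 24), c(40, 60), c(75, 70))[seq_len(k)]
  cells <- lapply(pos, function(p)
    cell_desc(p, 11, 6, channels = list(vimentin = 80, DRAQ5 = 4),
              nucleus_channels = list(DRAQ5 = 150, vimentin = 25)))
  simulate_channel_scene(scene_spec(c(96, 96), cells = cells,
                                    background_level = 2, noise_model = noise,
                                    seed = seed),
                         c("vimentin", "DRAQ5"))
}

test_that("the Li threshold minimizes the cross-entropy objective", {
  set.seed(11)
  img <- matrix(c(rnorm(600, 20, 3), rnorm(424, 120, 10)), 32, 32)
  thr <- threshold_li(img)
  # the threshold separates the two modes (tolerating tail overlap)
  truth <- rep(c(FALSE, TRUE), c(600, 424))
  expect_lt(mean((as.vector(img) > thr) != truth), 0.02)
  # independent oracle: brute-force scan of the cross-entropy objective over
  # every distinct split of the sorted data; the histogram-based threshold
  # must attain (near) the global optimum of the same objective
  v <- sort(as.vector(img))
  tot <- sum(v); cum <- cumsum(v)
  ce <- sapply(seq_len(length(v) - 1), function(i) {
    mu0 <- cum[i] / i; mu1 <- (tot - cum[i]) / (length(v) - i)
    -(cum[i] * log(mu0) + (tot - cum[i]) * log(mu1))
  })
  n_below <- sum(as.vector(img) <= thr)
  expect_lte(ce[n_below], min(ce) + 1e-4 * abs(min(ce)))
  expect_error(threshold_li(matrix(3, 5, 5)), "constant")
})

test_that("nuclei are segmented one label per nucleus with high overlap", {
  sim <- nuclei_scene(3)
  nuc <- segment_nuclei(sim$images$DRAQ5, min_area_px = 40)
  expect_equal(max(nuc), 3)
  for (id in 1:3) {
    jac <- jaccard_best(unclass(nuc) == id,
                        unclass(sim$ground_truth$nucleus_labels))
    expect_gte(jac, 0.95)
  }
})

test_that("the size filter removes small objects", {
  img <- matrix(1, 64, 64)
  img[raster_disk(64, 10, 20, 20)] <- 100
  img[raster_disk(64, 3, 50, 50)] <- 100
  ch <- channel_image(img, "DRAQ5")
  all_objs <- segment_nuclei(ch, min_area_px = 5, declump = FALSE)
  expect_equal(max(all_objs), 2)
  big_only <- segment_nuclei(ch, min_area_px = 50, declump = FALSE)
  expect_equal(max(big_only), 1)
  # a blank image plus one bright disk yields exactly one label
  img2 <- matrix(0, 64, 64); img2[raster_disk(64, 12)] <- 50
  expect_equal(max(segment_nuclei(channel_image(img2, "DRAQ5"))), 1)
})

test_that("propagated cells contain their nuclei and match ground truth", {
  sim <- nuclei_scene(3)
  nuc <- segment_nuclei(sim$images$DRAQ5, min_area_px = 40)
  cells <- propagate_cells(nuc, sim$images$vimentin)
  expect_true(all(unclass(cells)[unclass(nuc) > 0] ==
                    unclass(nuc)[unclass(nuc) > 0]))
  for (id in 1:3) {
    jac <- jaccard_best(unclass(cells) == id,
                        unclass(sim$ground_truth$cell_labels))
    expect_gte(jac, 0.9)
  }
})

test_that("uniform cytoplasm reduces propagation to geodesic nearest-seed", {
  # two seeds in a C-shaped corridor: geodesic, not Euclidean, assignment
  fg <- matrix(FALSE, 30, 30)
  fg[3:27, 3:8] <- TRUE; fg[3:8, 3:27] <- TRUE; fg[3:27, 22:27] <- TRUE
  img <- matrix(10, 30, 30); img[!fg] <- 0
  seeds <- matrix(0L, 30, 30)
  seeds[25, 4:6] <- 1L; seeds[25, 23:25] <- 2L
  # foreground threshold will pick up the corridor exactly
  cells <- propagate_cells(label_map(seeds, "nuclei"),
                           channel_image(img, "vimentin"))
  oracle <- bfs_geodesic_labels(fg, seeds)
  inside <- fg & oracle$labels > 0
  expect_true(all(unclass(cells)[inside] == oracle$labels[inside]))
  expect_error(propagate_cells(label_map(matrix(0L, 4, 4), "nuclei"),
                               channel_image(matrix(1, 4, 4))), "empty")
})
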