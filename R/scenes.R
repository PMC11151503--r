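#' Describe one synthetic cell
#'
#' A circular cell with a (possibly elongated, rotated) elliptical nucleus
#' centered on it, per-channel mean cytoplasmic intensities, optional
#' nucleus-specific intensities, and optional NADH decay parameters for FLIM
#' scenes. The nucleus geometric-mean radius is `nucleus_radius_px`; its
#' semi-axes are `r*sqrt(ratio)` and `r/sqrt(ratio)` so elongation preserves
#' area. The nucleus must lie inside the cell.
#'
#' @param center `c(x, y)` center in pixels (x = column, y = row).
#' @param radius_px cell radius in pixels.
#' @param nucleus_radius_px nucleus geometric-mean radius in pixels.
#' @param nucleus_axis_ratio major/minor axis ratio of the nucleus (>= 1).
#' @param nucleus_angle_deg orientation of the nucleus major axis, degrees in
#'   \[-90, 90), 0 = x-axis, counter-clockwise.
#' @param channels named list of mean cytoplasmic intensities per channel.
#' @param nucleus_channels named list of mean intensities on nucleus pixels;
#'   channels absent here inherit the cytoplasmic value.
#' @param decay optional list with `lifetimes_ns`, `amplitude_fractions` and
#'   `photons_per_pixel` describing the per-pixel NADH decay for FLIM scenes.
#' @return an object of class `cell_desc`.
#' @export
cell_desc <- function(center, radius_px, nucleus_radius_px,
                      nucleus_axis_ratio = 1, nucleus_angle_deg = 0,
                      channels = list(), nucleus_channels = list(),
                      decay = NULL) {
  check_positive(radius_px, "radius_px")
  check_positive(nucleus_radius_px, "nucleus_radius_px")
  check_positive(nucleus_axis_ratio, "nucleus_axis_ratio")
  if (nucleus_radius_px * sqrt(nucleus_axis_ratio) > radius_px) {
    stop_field("nucleus_radius_px",
               "nucleus (major semi-axis) must lie inside its cell")
  }
  if (length(channels) && any(unlist(channels) < 0)) {
    stop_field("channels", "intensities must be >= 0")
  }
  structure(
    list(center = as.numeric(center), radius_px = radius_px,
         nucleus_radius_px = nucleus_radius_px,
         nucleus_axis_ratio = nucleus_axis_ratio,
         nucleus_angle_deg = wrap_angle_deg(nucleus_angle_deg),
         channels = channels, nucleus_channels = nucleus_channels,
         decay = decay),
    class = "cell_desc"
  )
}

#' Describe a synthetic field of view
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size_um physical pixel size.
#' @param cells list of [cell_desc()] objects.
#' @param background_level background intensity (photons/pixel for FLIM
#'   scenes).
#' @param noise_model `"none"`, `"poisson"`, or `list(type = "gaussian",
#'   sd = <sigma>)`.
#' @param seed integer seed for the noise draws.
#' @param flim_period_ns,flim_n_bins decay-histogram layout for FLIM scenes.
#' @param background_decay decay parameters of background photons in FLIM
#'   scenes (list with `lifetimes_ns`, `amplitude_fractions`).
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(128, 128), pixel_size_um = 0.39,
                       cells = list(), background_level = 0,
                       noise_model = "none", seed = NULL,
                       flim_period_ns = 50, flim_n_bins = 256,
                       background_decay = list(lifetimes_ns = 2.5,
                                               amplitude_fractions = 1)) {
  if (length(image_shape) != 2 || any(image_shape < 1)) {
    stop_field("image_shape", "must be two positive extents")
  }
  check_positive(background_level, "background_level", strict = FALSE)
  if (is.character(noise_model)) {
    noise_model <- match.arg(noise_model, c("none", "poisson"))
  } else if (!(is.list(noise_model) && identical(noise_model$type, "gaussian") &&
               is.numeric(noise_model$sd))) {
    stop_field("noise_model", "must be 'none', 'poisson' or list(type='gaussian', sd=..)")
  }
  stopifnot(all(vapply(cells, inherits, TRUE, "cell_desc")))
  structure(
    list(image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
         cells = cells, background_level = background_level,
         noise_model = noise_model, seed = seed,
         flim_period_ns = flim_period_ns, flim_n_bins = as.integer(flim_n_bins),
         background_decay = background_decay),
    class = "scene_spec"
  )
}

# Rasterize the cell and nucleus label maps of a scene. Overlapping cells are
# resolved by nearest-center assignment (with a warning).
scene_masks <- function(scene) {
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  cell_lab <- matrix(0L, nr, nc)
  nuc_lab <- matrix(0L, nr, nc)
  if (length(scene$cells) == 0) {
    return(list(cells = label_map(cell_lab, "cell", "synthetic scene"),
                nuclei = label_map(nuc_lab, "nuclei", "synthetic scene")))
  }
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  dist2_best <- matrix(Inf, nr, nc)
  overlap <- FALSE
  for (i in seq_along(scene$cells)) {
    cd <- scene$cells[[i]]
    dx <- xs - cd$center[1]; dy <- ys - cd$center[2]
    d2 <- dx^2 + dy^2
    inside <- d2 <= cd$radius_px^2
    if (any(inside & cell_lab > 0)) overlap <- TRUE
    take <- inside & d2 < dist2_best
    cell_lab[take] <- i
    dist2_best[take] <- d2[take]
    # nucleus: ellipse rotated by nucleus_angle_deg around the cell center
    th <- cd$nucleus_angle_deg * pi / 180
    # +y is down in image coordinates; positive angles rotate counter-clockwise
    u <- dx * cos(th) - dy * sin(th)
    v <- dx * sin(th) + dy * cos(th)
    a <- cd$nucleus_radius_px * sqrt(cd$nucleus_axis_ratio)
    b <- cd$nucleus_radius_px / sqrt(cd$nucleus_axis_ratio)
    nuc <- (u / a)^2 + (v / b)^2 <= 1
    nuc_lab[nuc & take] <- i
    nuc_lab[cell_lab == i & !take] <- 0L  # keep nucleus with its winning cell
  }
  if (overlap) {
    warning("overlapping cells resolved by nearest-center assignment",
            call. = FALSE)
  }
  list(cells = label_map(cell_lab, "cell", "synthetic scene"),
       nuclei = label_map(nuc_lab, "nuclei", "synthetic scene"))
}

apply_scene_noise <- function(img, noise_model) {
  if (identical(noise_model, "none")) return(img)
  if (identical(noise_model, "poisson")) {
    return(matrix(stats::rpois(length(img), img), nrow(img), ncol(img)))
  }
  pmax(img + matrix(stats::rnorm(length(img), 0, noise_model$sd),
                    nrow(img), ncol(img)), 0)
}

#' Simulate multi-channel intensity images of a cell field
#'
#' Renders one intensity image per requested channel on a shared pixel grid:
#' background plus per-cell cytoplasmic intensities, with nucleus pixels
#' overridden by nucleus-specific intensities where provided. Per-cell true
#' integrated intensities (from the noiseless render) are recorded in the
#' ground truth for bookkeeping oracles.
#'
#' @param scene a [scene_spec()].
#' @param channels character vector of channel names to render; every name
#'   must appear in each cell's `channels` or `nucleus_channels`.
#' @return list with `images` (named list of [channel_image()]s) and
#'   `ground_truth` (label maps + per-cell truth table).
#' @export
simulate_channel_scene <- function(scene, channels) {
  stopifnot(inherits(scene, "scene_spec"))
  masks <- scene_masks(scene)
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  known <- c("NADH", "FAD", "2NBDG", "vimentin", "DRAQ5", "reference", "other")
  for (ch in channels) {
    for (cd in scene$cells) {
      if (is.null(cd$channels[[ch]]) && is.null(cd$nucleus_channels[[ch]])) {
        stop(sprintf("unknown channel '%s': not named in every cell descriptor", ch),
             call. = FALSE)
      }
    }
  }
  cl <- unclass(masks$cells); nl <- unclass(masks$nuclei)
  truth_rows <- list()
  images <- list()
  noiseless <- list()
  for (ch in channels) {
    img <- matrix(scene$background_level, nr, nc)
    for (i in seq_along(scene$cells)) {
      cd <- scene$cells[[i]]
      cyto_val <- cd$channels[[ch]] %||% 0
      nuc_val <- cd$nucleus_channels[[ch]] %||% cyto_val
      img[cl == i] <- cyto_val
      img[nl == i] <- nuc_val
    }
    noiseless[[ch]] <- img
  }
  truth <- data.frame(cell_id = seq_along(scene$cells))
  for (ch in channels) {
    truth[[paste0("true_integrated_", ch)]] <- vapply(
      seq_along(scene$cells),
      function(i) sum(noiseless[[ch]][cl == i]), numeric(1))
    truth[[paste0("true_mean_", ch)]] <- vapply(
      seq_along(scene$cells),
      function(i) mean(noiseless[[ch]][cl == i]), numeric(1))
  }
  if (all(c("NADH", "FAD") %in% channels)) {
    truth$true_orr <- vapply(seq_along(scene$cells), function(i) {
      cd <- scene$cells[[i]]
      fad <- cd$channels[["FAD"]] %||% 0
      nadh <- cd$channels[["NADH"]] %||% 0
      if (fad + nadh == 0) NA_real_ else fad / (fad + nadh)
    }, numeric(1))
  }
  images <- with_seed(scene$seed, {
    lapply(noiseless, function(img) apply_scene_noise(img, scene$noise_model))
  })
  images <- Map(function(img, ch) {
    tag <- if (ch %in% known) ch else "other"
    channel_image(img, tag, pixel_size_um = scene$pixel_size_um)
  }, images, channels)
  names(images) <- channels
  list(images = images,
       ground_truth = structure(
         list(cell_labels = masks$cells, nucleus_labels = masks$nuclei,
              cells = truth),
         class = "ground_truth"))
}

#' Simulate a FLIM image of a cell field
#'
#' Builds a per-pixel decay-histogram stack. Each pixel's decay parameters
#' follow its owning region: cell cytoplasm and nucleus use the cell's
#' `decay` (nucleus optionally distinct via `decay$nucleus`), background
#' pixels use the scene's `background_decay` scaled to `background_level`
#' photons. Noise `"poisson"` draws per-bin counts; `"none"` stores exact
#' expectations.
#'
#' @param scene a [scene_spec()] whose cells all carry decay parameters.
#' @return list with `flim` (a `flim_image`: array rows x cols x n_bins plus
#'   layout) and `ground_truth` (label maps + per-cell true decay
#'   parameters).
#' @export
simulate_flim_image <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  for (cd in scene$cells) {
    if (is.null(cd$decay)) {
      stop("every cell descriptor must carry decay parameters for a FLIM scene",
           call. = FALSE)
    }
  }
  masks <- scene_masks(scene)
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  nb <- scene$flim_n_bins
  arr <- array(0, dim = c(nr, nc, nb))
  cl <- unclass(masks$cells)

  fill_region <- function(arr, idx, lifetimes, fracs, photons) {
    if (length(idx) == 0 || photons <= 0) return(arr)
    prof <- decay_bin_fractions(lifetimes, fracs, scene$flim_period_ns, nb)
    expected <- outer(rep(photons, length(idx)), prof)  # pixels x bins
    counts <- if (identical(scene$noise_model, "poisson")) {
      matrix(stats::rpois(length(expected), expected), nrow(expected))
    } else {
      expected
    }
    for (b in seq_len(nb)) {
      plane <- arr[, , b]
      plane[idx] <- counts[, b]
      arr[, , b] <- plane
    }
    arr
  }

  arr <- with_seed(scene$seed, {
    if (scene$background_level > 0) {
      idx <- which(cl == 0)
      arr <- fill_region(arr, idx, scene$background_decay$lifetimes_ns,
                         scene$background_decay$amplitude_fractions,
                         scene$background_level)
    }
    for (i in seq_along(scene$cells)) {
      cd <- scene$cells[[i]]
      arr <- fill_region(arr, which(cl == i), cd$decay$lifetimes_ns,
                         cd$decay$amplitude_fractions,
                         cd$decay$photons_per_pixel %||% 5000)
    }
    arr
  })

  truth <- data.frame(
    cell_id = seq_along(scene$cells),
    true_alpha1 = vapply(scene$cells, function(cd)
      cd$decay$amplitude_fractions[1], numeric(1)),
    true_tau1 = vapply(scene$cells, function(cd)
      cd$decay$lifetimes_ns[1], numeric(1)),
    true_tau2 = vapply(scene$cells, function(cd)
      if (length(cd$decay$lifetimes_ns) > 1) cd$decay$lifetimes_ns[2] else NA_real_,
      numeric(1))
  )
  flim <- structure(
    list(counts = arr, n_bins = nb, period_ns = scene$flim_period_ns,
         pixel_size_um = scene$pixel_size_um),
    class = "flim_image"
  )
  list(flim = flim,
       ground_truth = structure(
         list(cell_labels = masks$cells, nucleus_labels = masks$nuclei,
              cells = truth),
         class = "ground_truth"))
}

#' @export
print.flim_image <- function(x, ...) {
  cat(sprintf("<flim_image> %dx%d px, %d bins over %g ns, %0.4g photons\n",
              dim(x$counts)[1], dim(x$counts)[2], x$n_bins, x$period_ns,
              sum(x$counts)))
  invisible(x)
}
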