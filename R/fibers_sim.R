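#' Specification of a synthetic fiber mat image
#'
#' Describes an SEM-like image of straight electrospun fibers: the number of
#' fibers, the law their orientations are drawn from, their width
#' distribution and intensity. Angles follow the shared convention: degrees
#' in \[-90, 90), 0 = image x-axis, counter-clockwise positive.
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param n_fibers number of fibers (>= 1).
#' @param orientation_law list with `type` in `"delta"`, `"uniform"`,
#'   `"wrapped_normal"`; `theta0_deg` for delta/wrapped-normal; `kappa`
#'   (concentration, 1/radians^2; 0 = uniform) for wrapped-normal.
#' @param fiber_width_px scalar width or `list(mean = , sd = )` for a
#'   truncated-normal width distribution (px, > 0).
#' @param intensity fiber peak intensity.
#' @param pixel_size_um physical pixel size.
#' @param noise_model `"none"`, `"poisson"` or `list(type="gaussian", sd=..)`.
#' @param seed integer seed.
#' @return an object of class `fiber_scene_spec`.
#' @export
fiber_scene_spec <- function(image_shape = c(512, 512), n_fibers = 50,
                             orientation_law = list(type = "uniform"),
                             fiber_width_px = 6, intensity = 1,
                             pixel_size_um = 0.05,
                             noise_model = "none", seed = NULL) {
  if (n_fibers < 1) stop_field("n_fibers", "must be >= 1")
  if (!orientation_law$type %in% c("delta", "uniform", "wrapped_normal")) {
    stop_field("orientation_law", "type must be delta, uniform or wrapped_normal")
  }
  th0 <- orientation_law$theta0_deg %||% 0
  if (th0 < -90 || th0 >= 90) {
    stop_field("orientation_law", "theta0_deg must be in [-90, 90)")
  }
  wmin <- if (is.list(fiber_width_px)) fiber_width_px$mean else fiber_width_px
  if (any(wmin <= 0)) stop_field("fiber_width_px", "zero-width fibers rejected")
  structure(
    list(image_shape = as.integer(image_shape), n_fibers = as.integer(n_fibers),
         orientation_law = orientation_law, fiber_width_px = fiber_width_px,
         intensity = intensity, pixel_size_um = pixel_size_um,
         noise_model = noise_model, seed = seed),
    class = "fiber_scene_spec"
  )
}

#' Draw fiber orientation angles from an orientation law
#'
#' `delta`: all angles equal `theta0_deg`. `uniform`: uniform on \[-90, 90).
#' `wrapped_normal`: normal with standard deviation `1/sqrt(kappa)` radians
#' around `theta0_deg`, wrapped into \[-90, 90) (kappa = 0 gives the uniform
#' law; kappa to infinity collapses to the delta law).
#'
#' @param law orientation law (see [fiber_scene_spec()]).
#' @param n number of angles.
#' @param seed integer seed.
#' @return numeric vector of angles in degrees, in \[-90, 90).
#' @export
sample_fiber_angles <- function(law, n, seed = NULL) {
  th0 <- law$theta0_deg %||% 0
  with_seed(seed, {
    switch(law$type,
      delta = rep(th0, n),
      uniform = stats::runif(n, -90, 90),
      wrapped_normal = {
        kappa <- law$kappa %||% 1
        if (kappa <= 0) {
          stats::runif(n, -90, 90)
        } else {
          sd_deg <- (1 / sqrt(kappa)) * 180 / pi
          wrap_angle_deg(stats::rnorm(n, th0, sd_deg))
        }
      },
      stop_field("orientation_law", "unknown type"))
  })
}

#' Simulate a fiber mat image
#'
#' Renders `n_fibers` anti-aliased straight fibers spanning the field of
#' view at angles drawn from the orientation law; overlaps are composited
#' with `max` (fibers occlude, as in SEM). The true angles and widths are
#' returned as ground truth.
#'
#' @param spec a [fiber_scene_spec()].
#' @return list with `image` (a [channel_image()]) and `ground_truth`
#'   (data frame of per-fiber true `angle_deg` and `width_px`).
#' @export
simulate_fiber_image <- function(spec) {
  stopifnot(inherits(spec, "fiber_scene_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  out <- with_seed(spec$seed, {
    angles <- sample_fiber_angles(spec$orientation_law, spec$n_fibers)
    widths <- if (is.list(spec$fiber_width_px)) {
      w <- stats::rnorm(spec$n_fibers, spec$fiber_width_px$mean,
                        spec$fiber_width_px$sd %||% 0)
      pmax(w, 1)
    } else {
      rep(spec$fiber_width_px, spec$n_fibers)
    }
    img <- matrix(0, nr, nc)
    xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    ys <- matrix(rep(seq_len(nr), nc), nr, nc)
    for (f in seq_len(spec$n_fibers)) {
      th <- angles[f] * pi / 180
      # direction (x = col, y = row down): (cos th, -sin th); normal (sin th, cos th)
      cx <- stats::runif(1, 1, nc); cy <- stats::runif(1, 1, nr)
      d <- abs((xs - cx) * sin(th) + (ys - cy) * cos(th))
      prof <- spec$intensity * pmin(pmax(widths[f] / 2 + 0.5 - d, 0), 1)
      img <- pmax(img, prof)
    }
    img <- apply_scene_noise(img, spec$noise_model)
    list(img = img, angles = angles, widths = widths)
  })
  list(image = channel_image(out$img, "other",
                             pixel_size_um = spec$pixel_size_um),
       ground_truth = data.frame(fiber_id = seq_len(spec$n_fibers),
                                 angle_deg = out$angles,
                                 width_px = out$widths))
}
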