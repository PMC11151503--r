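#' Weighted fiber-orientation distribution
#'
#' Construct an orientation distribution from angles (degrees in
#' \[-90, 90)) and optional non-negative weights; weights are normalized to
#' sum to 1.
#'
#' @param angles_deg angles in degrees.
#' @param weights non-negative weights (default uniform).
#' @param source free-text provenance (`"per-fiber"` or `"per-pixel tensor"`).
#' @return an object of class `orientation_distribution`.
#' @export
as_orientation_distribution <- function(angles_deg, weights = NULL,
                                        source = "per-fiber") {
  if (length(angles_deg) == 0) stop("empty orientation distribution", call. = FALSE)
  weights <- weights %||% rep(1, length(angles_deg))
  check_positive(weights, "weights", strict = FALSE)
  s <- sum(weights)
  if (s <= 0) stop("weights sum to zero", call. = FALSE)
  structure(
    list(angles_deg = wrap_angle_deg(angles_deg), weights = weights / s,
         source = source),
    class = "orientation_distribution"
  )
}

#' Local-orientation distribution of a fiber image
#'
#' Per-pixel orientation from the 2x2 structure tensor: gradients are taken
#' at a derivative scale `grad_sigma`, the tensor components are smoothed at
#' `tensor_scale_px`, and the local fiber orientation (perpendicular to the
#' dominant gradient) is extracted per pixel. Weights are tensor coherence
#' times gradient energy; low-energy (background) pixels below
#' `energy_frac` of the maximum energy are excluded.
#'
#' @param image a [channel_image()] or numeric matrix.
#' @param tensor_scale_px Gaussian smoothing scale of the tensor (px).
#' @param grad_sigma derivative (pre-smoothing) scale (px).
#' @param energy_frac energy cutoff as a fraction of the maximum.
#' @return an `orientation_distribution` with `source = "per-pixel tensor"`.
#' @export
orientation_distribution <- function(image, tensor_scale_px = 3,
                                     grad_sigma = 1, energy_frac = 0.05) {
  img <- unclass(image)
  if (diff(range(img)) == 0) {
    stop("constant image: no orientation information", call. = FALSE)
  }
  if (grad_sigma > 0) img <- EBImage::gblur(img, sigma = grad_sigma)
  nr <- nrow(img); nc <- ncol(img)
  # centered differences; x = columns, y = rows (down)
  gx <- (shift_mat(img, 0, -1, NA) - shift_mat(img, 0, 1, NA)) / 2
  gy <- (shift_mat(img, -1, 0, NA) - shift_mat(img, 1, 0, NA)) / 2
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  jxx <- EBImage::gblur(gx * gx, sigma = tensor_scale_px)
  jyy <- EBImage::gblur(gy * gy, sigma = tensor_scale_px)
  jxy <- EBImage::gblur(gx * gy, sigma = tensor_scale_px)
  energy <- jxx + jyy
  coher <- ifelse(energy > 0,
                  sqrt((jxx - jyy)^2 + 4 * jxy^2) / energy, 0)
  # dominant gradient direction phi; the fiber runs perpendicular to it.
  # With y pointing down, a fiber at angle theta (CCW from x-axis) has
  # gradient along (sin theta, cos theta), so theta = 90 - phi.
  phi <- 0.5 * atan2(2 * jxy, jxx - jyy)
  theta <- wrap_angle_deg(90 - phi * 180 / pi)
  keep <- energy >= energy_frac * max(energy)
  # trim the image border where the centered differences are one-sided
  border <- matrix(TRUE, nr, nc)
  border[c(1, nr), ] <- FALSE; border[, c(1, nc)] <- FALSE
  keep <- keep & border
  if (!any(keep)) stop("no pixels above the energy cutoff", call. = FALSE)
  as_orientation_distribution(theta[keep], (coher * energy)[keep],
                              source = "per-pixel tensor")
}

#' Herman's orientation index
#'
#' The 2D Herman orientation index `S = 2 <cos^2 theta> - 1`, with `theta`
#' measured from the reference axis: `S = 1` for perfect alignment along the
#' reference, `0` for a fully random (isotropic) mat, `-1` for alignment
#' perpendicular to a fixed reference. When `reference_angle_deg` is absent
#' it is set to the principal direction (the maximizer of S, the resultant
#' direction of the doubled angles), which guarantees `S` in \[0, 1\] and
#' makes the index rotation-invariant.
#'
#' @param dist an `orientation_distribution` (or numeric vector of angles).
#' @param reference_angle_deg optional fixed reference axis (degrees).
#' @param form `"2d"` (default) or `"3d"` (`(3<cos^2>-1)/2`).
#' @return an `orientation_result`: list with `S`, `reference_angle_deg`,
#'   `n_samples`.
#' @export
hermans_index <- function(dist, reference_angle_deg = NULL,
                          form = c("2d", "3d")) {
  form <- match.arg(form)
  if (is.numeric(dist)) dist <- as_orientation_distribution(dist)
  stopifnot(inherits(dist, "orientation_distribution"))
  th <- dist$angles_deg * pi / 180
  w <- dist$weights
  if (is.null(reference_angle_deg)) {
    # principal direction from the mean resultant of the doubled angles
    c2 <- sum(w * cos(2 * th)); s2 <- sum(w * sin(2 * th))
    reference_angle_deg <- wrap_angle_deg(0.5 * atan2(s2, c2) * 180 / pi)
  }
  rel <- th - reference_angle_deg * pi / 180
  mean_cos2 <- sum(w * cos(rel)^2)
  S <- switch(form,
              "2d" = 2 * mean_cos2 - 1,
              "3d" = (3 * mean_cos2 - 1) / 2)
  structure(list(S = S, reference_angle_deg = reference_angle_deg,
                 n_samples = length(th), form = form),
            class = "orientation_result")
}

#' @export
print.orientation_result <- function(x, ...) {
  cat(sprintf("<orientation_result> S = %.4f (%s form) about %.2f deg, n = %d\n",
              x$S, x$form, x$reference_angle_deg, x$n_samples))
  invisible(x)
}

# Zhang-Suen morphological thinning to a 1-px skeleton (vectorized sweeps).
skeletonize <- function(mask) {
  m <- mask
  nbrs <- function(m) {
    list(p2 = shift_mat(m, 1, 0, FALSE),   # north neighbor value at each pixel
         p3 = shift_mat(m, 1, -1, FALSE),
         p4 = shift_mat(m, 0, -1, FALSE),
         p5 = shift_mat(m, -1, -1, FALSE),
         p6 = shift_mat(m, -1, 0, FALSE),
         p7 = shift_mat(m, -1, 1, FALSE),
         p8 = shift_mat(m, 0, 1, FALSE),
         p9 = shift_mat(m, 1, 1, FALSE))
  }
  for (iter in seq_len(200)) {
    changed <- FALSE
    for (sub in 1:2) {
      n <- nbrs(m)
      b <- n$p2 + n$p3 + n$p4 + n$p5 + n$p6 + n$p7 + n$p8 + n$p9
      seqn <- list(n$p2, n$p3, n$p4, n$p5, n$p6, n$p7, n$p8, n$p9, n$p2)
      a <- Reduce(`+`, lapply(1:8, function(i) (!seqn[[i]]) & seqn[[i + 1]]))
      cond <- m & b >= 2 & b <= 6 & a == 1
      if (sub == 1) {
        cond <- cond & !(n$p2 & n$p4 & n$p6) & !(n$p4 & n$p6 & n$p8)
      } else {
        cond <- cond & !(n$p2 & n$p4 & n$p8) & !(n$p2 & n$p6 & n$p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Fiber diameter distribution
#'
#' Thresholds the fiber image (minimum cross-entropy), skeletonizes the
#' foreground and takes twice the Euclidean distance-transform value at each
#' skeleton pixel as the local fiber diameter, converted to micrometers via
#' the image pixel size.
#'
#' @param image a [channel_image()] of a fiber mat.
#' @param pixel_size_um physical pixel size; defaults to the image attribute.
#' @return list with `diameters_um` (per skeleton pixel), `mean_um`, `sd_um`,
#'   `n`.
#' @export
fiber_diameter <- function(image, pixel_size_um = NULL) {
  pixel_size_um <- pixel_size_um %||% attr(image, "pixel_size_um") %||% 1
  img <- unclass(image)
  thr <- threshold_li(img)
  mask <- img > thr
  if (!any(mask)) stop("empty fiber foreground after thresholding", call. = FALSE)
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
  skel <- skeletonize(mask)
  d_px <- 2 * dm[skel]
  d_um <- d_px * pixel_size_um
  list(diameters_um = d_um, mean_um = mean(d_um), sd_um = stats::sd(d_um),
       n = length(d_um))
}
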