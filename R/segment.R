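#' Global minimum cross-entropy (Li) threshold
#'
#' Chooses the threshold minimizing the cross-entropy between the image and
#' its two-class segmentation (Li & Lee's criterion), by exact minimization
#' over a histogram of candidate thresholds:
#' `eta(t) = -[ S0(t) log mu0(t) + S1(t) log mu1(t) ]`, where `S0`, `S1` are
#' the sums of intensities below/above `t` and `mu0`, `mu1` the class means.
#'
#' @param image numeric matrix or [channel_image()].
#' @param n_levels number of histogram levels scanned.
#' @return the threshold value (on the image's intensity scale).
#' @export
threshold_li <- function(image, n_levels = 256) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) {
    stop("no threshold: image is constant", call. = FALSE)
  }
  # cross-entropy needs positive intensities; shift if necessary
  shift <- if (rng[1] <= 0) -rng[1] + diff(rng) * 1e-6 else 0
  x <- x + shift
  breaks <- seq(min(x), max(x), length.out = n_levels + 1)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  cnt <- h$counts
  mid <- h$mids
  w0 <- cumsum(cnt)
  s0 <- cumsum(cnt * mid)
  w1 <- sum(cnt) - w0
  s1 <- sum(cnt * mid) - s0
  valid <- which(w0 > 0 & w1 > 0)
  mu0 <- s0[valid] / w0[valid]
  mu1 <- s1[valid] / w1[valid]
  eta <- -(s0[valid] * log(mu0) + s1[valid] * log(mu1))
  best <- valid[which.min(eta)]
  # threshold between the two classes: upper edge of the winning bin
  breaks[best + 1] - shift
}

#' Segment nuclei as primary objects
#'
#' Minimum cross-entropy threshold, connected components, size filtering and
#' optional distance-transform watershed declumping of touching nuclei
#' (distance map smoothed at `smooth_sigma` pixels before watershed).
#'
#' @param nuclei_channel a [channel_image()] of the nuclear stain (DRAQ5).
#' @param min_area_px,max_area_px object size filter in pixels.
#' @param declump split touching objects by distance-transform watershed.
#' @param smooth_sigma Gaussian smoothing scale (px) of the distance map.
#' @return a nuclei [label_map()] with contiguous labels.
#' @export
segment_nuclei <- function(nuclei_channel, min_area_px = 50,
                           max_area_px = 10000, declump = TRUE,
                           smooth_sigma = 2) {
  img <- unclass(nuclei_channel)
  thr <- threshold_li(img)
  mask <- img > thr
  if (!any(mask)) stop("no foreground after thresholding", call. = FALSE)
  labels <- if (declump) {
    dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
    if (smooth_sigma > 0) {
      dm <- EBImage::gblur(dm, sigma = smooth_sigma)
      dm[!mask] <- 0
    }
    EBImage::imageData(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    EBImage::imageData(EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask))))
  }
  labels <- matrix(as.integer(labels), nrow(mask))
  sizes <- tabulate(labels[labels > 0])
  bad <- which(sizes < min_area_px | sizes > max_area_px)
  labels[labels %in% bad] <- 0L
  label_map(relabel_contiguous(labels), "nuclei",
            provenance = sprintf("minimum cross-entropy threshold %.4g%s",
                                 thr, if (declump) " + watershed declump" else ""))
}

# Shift a matrix by (di, dj), padding with `fill`.
shift_mat <- function(m, di, dj, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- seq_len(nr) - di; ci <- seq_len(nc) - dj
  ok_r <- ri >= 1 & ri <= nr; ok_c <- ci >= 1 & ci <= nc
  out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
  out
}

#' Propagate cell outlines from nucleus seeds
#'
#' Locates whole cells as secondary objects: the foreground is the minimum
#' cross-entropy threshold of the cytoplasmic channel united with the nuclei;
#' each foreground pixel is assigned to the nucleus seed reached at minimal
#' cumulative cost, where a step of length `d` between pixels of intensity
#' difference `dI` costs `d * sqrt(1 + (dI/alpha)^2)`. With uniform
#' cytoplasmic intensity this reduces to nearest-seed geodesic distance
#' within the foreground. Each cell label contains its nucleus.
#'
#' @param nuclei a nuclei [label_map()] (the seeds).
#' @param cyto_channel a [channel_image()] of the cytoplasmic stain.
#' @param alpha regularization between the spatial and intensity terms;
#'   smaller values make intensity differences more costly.
#' @param max_iter cap on label-propagation sweeps.
#' @return a cell [label_map()]; labels match the nucleus ids.
#' @export
propagate_cells <- function(nuclei, cyto_channel, alpha = 0.05,
                            max_iter = NULL) {
  stopifnot(inherits(nuclei, "label_map"))
  if (!any(nuclei > 0)) stop("nuclei map is empty", call. = FALSE)
  img <- unclass(cyto_channel)
  stopifnot(all(dim(img) == dim(nuclei)))
  thr <- threshold_li(img)
  fg <- img > thr | unclass(nuclei) > 0
  if (!any(fg)) stop("no foreground in cytoplasmic channel", call. = FALSE)
  nr <- nrow(img); nc <- ncol(img)
  # intensity differences enter the cost on a [0, 1] scale so `alpha` is
  # comparable across images with different dynamic ranges
  rng <- range(img)
  imgn <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  cost <- matrix(Inf, nr, nc)
  labels <- matrix(0L, nr, nc)
  seeds <- unclass(nuclei) > 0
  cost[seeds] <- 0
  labels[seeds] <- unclass(nuclei)[seeds]
  offsets <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  steps <- sqrt(offsets[, 1]^2 + offsets[, 2]^2)
  max_iter <- max_iter %||% (nr + nc)
  # Jacobi relaxation of the shortest-path (geodesic) assignment
  for (it in seq_len(max_iter)) {
    changed <- FALSE
    for (k in seq_len(nrow(offsets))) {
      di <- offsets[k, 1]; dj <- offsets[k, 2]
      nb_cost <- shift_mat(cost, di, dj, Inf)
      nb_lab <- shift_mat(labels, di, dj, 0L)
      dI <- abs(imgn - shift_mat(imgn, di, dj, NA))
      step_cost <- steps[k] * sqrt(1 + (dI / alpha)^2)
      cand <- nb_cost + step_cost
      upd <- fg & !seeds & is.finite(cand) & cand < cost - 1e-12 & nb_lab > 0
      if (any(upd)) {
        cost[upd] <- cand[upd]
        labels[upd] <- nb_lab[upd]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  label_map(labels, "cell",
            provenance = sprintf("propagation from nuclei (alpha = %g)", alpha))
}
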