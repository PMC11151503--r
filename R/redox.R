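#' Normalize an intensity image by a reference-dye image
#'
#' Divides an image by the spatial mean of a reference image (e.g. a
#' Rhodamine B solution) acquired at the same channel settings, removing
#' gain/power differences between acquisitions. The result carries
#' `normalized = TRUE`.
#'
#' @param image a [channel_image()].
#' @param reference a [channel_image()] of the uniform reference dye.
#' @return the normalized [channel_image()].
#' @export
normalize_by_reference <- function(image, reference) {
  stopifnot(inherits(image, "channel_image"), inherits(reference, "channel_image"))
  ref_mean <- mean(reference)
  if (!is.finite(ref_mean) || ref_mean <= 0) {
    stop("reference image has non-positive mean; cannot normalize", call. = FALSE)
  }
  channel_image(unclass(image) / ref_mean, attr(image, "channel"),
                pixel_size_um = attr(image, "pixel_size_um"),
                normalized = TRUE)
}

#' Pixel-wise optical redox ratio map
#'
#' Computes `ORR = I_FAD / (I_FAD + I_NADH)` per pixel after optional
#' per-channel background subtraction (negative values clipped to zero).
#' Pixels with zero denominator are masked (`NA`), never imputed. An ORR of 1
#' indicates a shift toward oxidative phosphorylation; values near 0 indicate
#' a more glycolytic state.
#'
#' @param nadh,fad [channel_image()]s on the same grid, both raw or both
#'   reference-normalized.
#' @param background optional named numeric `c(NADH = ..., FAD = ...)`
#'   per-channel background levels to subtract.
#' @return an `orr_result` with element `orr_map` (matrix in \[0, 1\] with
#'   `NA` where undefined).
#' @export
orr_map <- function(nadh, fad, background = NULL) {
  stopifnot(inherits(nadh, "channel_image"), inherits(fad, "channel_image"))
  if (!all(dim(nadh) == dim(fad))) {
    stop("NADH and FAD images have different shapes", call. = FALSE)
  }
  if (!identical(attr(nadh, "normalized"), attr(fad, "normalized"))) {
    stop("normalization flag mismatch: normalize both channels or neither",
         call. = FALSE)
  }
  n <- unclass(nadh); f <- unclass(fad)
  if (!is.null(background)) {
    n <- pmax(n - (background[["NADH"]] %||% 0), 0)
    f <- pmax(f - (background[["FAD"]] %||% 0), 0)
  }
  denom <- n + f
  map <- ifelse(denom > 0, f / denom, NA_real_)
  structure(list(orr_map = map, per_cell = NULL), class = "orr_result")
}

#' Per-cell mean optical redox ratio, nucleus excluded
#'
#' Averages the ORR map per cell over cytoplasmic pixels: cell mask minus
#' nucleus mask minus masked (undefined) pixels. Cells with fewer than
#' `min_pixels` qualifying pixels are dropped with a warning.
#'
#' @param result an `orr_result` from [orr_map()].
#' @param cell_labels,nucleus_labels [label_map()]s sharing the image grid.
#' @param min_pixels minimum number of qualifying pixels per cell.
#' @return the `orr_result` with `per_cell` filled in: a data frame of
#'   `cell_id`, `mean_orr`, `n_pixels`.
#' @export
per_cell_orr <- function(result, cell_labels, nucleus_labels = NULL,
                         min_pixels = 20) {
  stopifnot(inherits(result, "orr_result"), inherits(cell_labels, "label_map"))
  map <- result$orr_map
  if (!all(dim(map) == dim(cell_labels))) {
    stop("label map does not share the ORR image grid", call. = FALSE)
  }
  nuc <- if (is.null(nucleus_labels)) matrix(0L, nrow(map), ncol(map)) else {
    stopifnot(all(dim(nucleus_labels) == dim(map)))
    unclass(nucleus_labels)
  }
  ids <- sort(setdiff(unique(as.vector(cell_labels)), 0L))
  keep <- !is.na(map) & nuc == 0
  rows <- list()
  dropped <- integer(0)
  for (id in ids) {
    sel <- as.vector(cell_labels) == id & as.vector(keep)
    n <- sum(sel)
    if (n < min_pixels) {
      dropped <- c(dropped, id)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      cell_id = id, mean_orr = mean(map[matrix(sel, nrow(map))]), n_pixels = n)
  }
  if (length(dropped)) {
    warning(sprintf("dropped cell(s) with < %d qualifying pixels: %s",
                    min_pixels, paste(dropped, collapse = ",")), call. = FALSE)
  }
  if (length(rows) == 0) {
    stop("no cell has enough qualifying ORR pixels", call. = FALSE)
  }
  result$per_cell <- do.call(rbind, rows)
  result
}

#' Background level estimate outside all cells
#'
#' Default background estimator for ORR visualization: the mean intensity
#' over pixels outside every cell label.
#'
#' @param image a [channel_image()].
#' @param cell_labels a cell [label_map()].
#' @return scalar mean background intensity.
#' @export
estimate_background <- function(image, cell_labels) {
  sel <- unclass(cell_labels) == 0
  if (!any(sel)) stop("no background pixels outside cell labels", call. = FALSE)
  mean(unclass(image)[sel])
}

#' Seeded random subsample of cells
#'
#' The source protocol selected a few cells per field at random; this helper
#' reproduces that fidelity mode on any per-cell table.
#'
#' @param per_cell data frame with a `cell_id` column.
#' @param n number of cells to keep.
#' @param seed integer seed.
#' @return the subsampled data frame.
#' @export
subsample_cells <- function(per_cell, n, seed = NULL) {
  if (n >= nrow(per_cell)) return(per_cell)
  idx <- with_seed(seed, sample(nrow(per_cell), n))
  per_cell[sort(idx), , drop = FALSE]
}
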