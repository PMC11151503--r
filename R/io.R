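# File interfaces: 32-bit float TIFF for intensity images, 16-bit TIFF for
# label maps, multi-frame TIFF (one frame per time bin) + JSON sidecar for
# FLIM stacks, CSV for tables.

#' Write / read a single-channel image as 32-bit float TIFF
#'
#' Intensities are stored scaled to \[0, 1\]; the scale factor is recorded in
#' a small JSON sidecar at `<path>.json` and re-applied on read.
#'
#' @param image a [channel_image()] (or numeric matrix).
#' @param path output path.
#' @export
write_channel_tiff <- function(image, path) {
  scale <- max(max(image), 1e-12)
  tiff::writeTIFF(unclass(image) / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(intensity_scale = scale,
                            channel = attr(image, "channel") %||% "other",
                            pixel_size_um = attr(image, "pixel_size_um") %||% 1),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_channel_tiff
#' @param channel,pixel_size_um metadata overrides; by default read from the
#'   sidecar when present.
#' @export
read_channel_tiff <- function(path, channel = NULL, pixel_size_um = NULL) {
  meta <- if (file.exists(paste0(path, ".json"))) {
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  } else {
    list(intensity_scale = 1)
  }
  m <- tiff::readTIFF(path) * meta$intensity_scale
  channel_image(m, channel %||% meta$channel %||% "other",
                pixel_size_um = pixel_size_um %||% meta$pixel_size_um %||% 1)
}

#' Write / read a label map as 16-bit TIFF
#'
#' @param labels a [label_map()].
#' @param path output path.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(unclass(labels) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_tiff
#' @param kind object kind of the loaded map.
#' @export
read_label_tiff <- function(path, kind = "nuclei") {
  m <- tiff::readTIFF(path)
  label_map(matrix(as.integer(round(m * 65535)), nrow(m)), kind,
            provenance = path)
}

#' Write / read a FLIM stack as multi-frame TIFF plus JSON sidecar
#'
#' One TIFF frame per time bin (bin index = frame order); the sidecar
#' records `period_ns` and `n_bins`.
#'
#' @param flim a `flim_image`.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @export
write_flim_stack <- function(flim, path) {
  stopifnot(inherits(flim, "flim_image"))
  peak <- max(flim$counts)
  frames <- lapply(seq_len(flim$n_bins), function(b) {
    flim$counts[, , b] / max(peak, 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(period_ns = flim$period_ns, n_bins = flim$n_bins,
                            pixel_size_um = flim$pixel_size_um,
                            count_scale = max(peak, 1)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_flim_stack
#' @export
read_flim_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (b in seq_along(frames)) arr[, , b] <- frames[[b]] * meta$count_scale
  structure(list(counts = arr, n_bins = meta$n_bins,
                 period_ns = meta$period_ns,
                 pixel_size_um = meta$pixel_size_um %||% 1),
            class = "flim_image")
}
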