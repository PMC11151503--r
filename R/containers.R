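#' Single-channel intensity image
#'
#' A 2D matrix of non-negative intensities tagged with its channel name
#' (NADH, FAD, 2NBDG, vimentin, DRAQ5, reference, other), physical pixel size
#' and a `normalized` flag recording whether reference-dye normalization has
#' been applied.
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param channel channel tag.
#' @param pixel_size_um physical pixel size in micrometers.
#' @param normalized logical; `TRUE` after [normalize_by_reference()].
#' @return a `channel_image` (a classed matrix).
#' @export
channel_image <- function(pixels,
                          channel = c("other", "NADH", "FAD", "2NBDG",
                                      "vimentin", "DRAQ5", "reference"),
                          pixel_size_um = 1, normalized = FALSE) {
  channel <- match.arg(channel)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop_field("pixels", "must be a numeric matrix")
  }
  if (any(pixels < 0, na.rm = TRUE)) stop_field("pixels", "must be >= 0")
  structure(pixels, channel = channel, pixel_size_um = pixel_size_um,
            normalized = normalized, class = c("channel_image", "matrix", "array"))
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %dx%d px (%g um/px)%s\n",
              attr(x, "channel"), nrow(x), ncol(x), attr(x, "pixel_size_um"),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else ""))
  invisible(x)
}

#' Integer-labeled segmentation map
#'
#' A 2D integer matrix sharing the pixel grid of its channel images;
#' 0 is background and positive labels identify objects. For paired nucleus
#' and cell maps, matching objects carry the same label.
#'
#' @param labels integer matrix of labels (0 = background).
#' @param kind what the objects are: nuclei, whole cells or cytoplasm.
#' @param provenance free-text description of how the map was produced.
#' @return a `label_map` (a classed integer matrix).
#' @export
label_map <- function(labels, kind = c("nuclei", "cell", "cytoplasm"),
                      provenance = "") {
  kind <- match.arg(kind)
  if (!is.matrix(labels)) stop_field("labels", "must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) stop_field("labels", "must be >= 0")
  structure(labels, kind = kind, provenance = provenance,
            class = c("label_map", "matrix", "array"))
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %s: %d object(s) on %dx%d px\n",
              attr(x, "kind"), length(setdiff(unique(as.vector(x)), 0L)),
              nrow(x), ncol(x)))
  invisible(x)
}

# Relabel positive labels to contiguous 1..k preserving order of first use.
relabel_contiguous <- function(labels) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (length(ids) == 0) return(labels)
  lookup <- integer(max(ids))
  lookup[ids] <- seq_along(ids)
  out <- labels
  pos <- labels > 0
  out[pos] <- lookup[labels[pos]]
  out
}
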