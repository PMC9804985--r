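# Image I/O. IF images are stored as three single-channel TIFFs sharing a
# path prefix with _dapi / _syn / _ins suffixes; IHC tiles as RGB PNG.

CHANNEL_SUFFIX <- c(dapi = "_dapi.tif", synaptophysin = "_syn.tif",
                    insulin = "_ins.tif")

#' Write a multichannel IF image as per-channel TIFF files
#'
#' @param img an `islet_image`.
#' @param prefix path prefix; `<prefix>_dapi.tif`, `<prefix>_syn.tif` and
#'   `<prefix>_ins.tif` are written at the image's bit depth.
#' @return `prefix`, invisibly.
#' @export
write_if_image <- function(img, prefix) {
  stopifnot(inherits(img, "islet_image"))
  maxval <- 2^img$bit_depth - 1
  for (ch in names(CHANNEL_SUFFIX)) {
    tiff::writeTIFF(img$channels[[ch]] / maxval,
                    paste0(prefix, CHANNEL_SUFFIX[[ch]]),
                    bits.per.sample = img$bit_depth,
                    compression = "none")
  }
  invisible(prefix)
}

#' Read a multichannel IF image from per-channel TIFF files
#'
#' @param prefix path prefix as written by [write_if_image()].
#' @param pixel_size um/px of the scan (TIFF carries no calibrated pixel
#'   size here, so the manifest supplies it).
#' @return an `islet_image`.
#' @export
read_if_image <- function(prefix, pixel_size) {
  channels <- list()
  bit_depth <- 8L
  for (ch in names(CHANNEL_SUFFIX)) {
    path <- paste0(prefix, CHANNEL_SUFFIX[[ch]])
    if (!file.exists(path)) stop("missing channel file: ", path)
    x <- tiff::readTIFF(path, as.is = TRUE)
    bit_depth <- if (max(x) > 255 || attr(x, "bits.per.sample") %||% 8 > 8)
      16L else 8L
    channels[[ch]] <- as.matrix(x) * 1.0
  }
  shapes <- vapply(channels, dim, integer(2))
  if (any(shapes != shapes[, 1])) stop("channel shapes differ for ", prefix)
  structure(list(channels = channels, pixel_size = pixel_size,
                 bit_depth = bit_depth),
            class = "islet_image")
}

#' Write an IHC RGB tile as PNG
#'
#' @param tile an `ihc_tile` or an `h x w x 3` array on the 0..255 scale.
#' @param path output PNG path (8-bit).
#' @export
write_ihc_png <- function(tile, path) {
  rgb <- if (inherits(tile, "ihc_tile")) tile$rgb else tile
  png::writePNG(pmin(pmax(rgb / 255, 0), 1), path)
  invisible(path)
}

#' Read an IHC RGB tile from PNG
#'
#' @param path PNG path.
#' @return `h x w x 3` array on the 0..255 float scale.
#' @export
read_ihc_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) stop("expected an RGB PNG, got greyscale: ", path)
  x[, , 1:3, drop = FALSE] * 255
}

#' Write a binary mask as an 8-bit 0/255 PNG
#' @param mask logical matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}
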