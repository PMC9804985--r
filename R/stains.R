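#' Build a stain matrix of unit optical-density vectors
#'
#' Rows are stains, columns are (R, G, B) optical-density components.
#' Each vector is normalised to unit length; the matrix must be
#' well-conditioned (condition number < 1e6) so the unmixing inverse
#' exists.
#'
#' @param haematoxylin,dab,ap numeric length-3 OD vectors for the nuclear
#'   counterstain, the brown HRP chromogen, and the magenta AP chromogen.
#' @return a 3x3 matrix of class `stain_matrix` with rownames
#'   `haematoxylin`, `dab`, `ap`.
#' @export
stain_matrix <- function(haematoxylin, dab, ap) {
  m <- rbind(haematoxylin = haematoxylin, dab = dab, ap = ap)
  if (ncol(m) != 3 || any(!is.finite(m)) || any(m < 0))
    stop("stain vectors must be three finite non-negative RGB OD triples")
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) stop("stain vectors must be non-zero")
  m <- m / norms
  sv <- svd(m)$d
  if (sv[3] <= 0 || sv[1] / sv[3] >= 1e6)
    stop("stain matrix is near-singular (condition number >= 1e6); ",
         "stain vectors are not linearly independent")
  colnames(m) <- c("R", "G", "B")
  structure(m, class = c("stain_matrix", "matrix"))
}

#' Default haematoxylin / DAB / AP-magenta stain matrix
#'
#' Haematoxylin and DAB use the standard published brightfield unmixing
#' vectors; the AP-magenta vector is the fast-red-type chromogen vector
#' (strong green absorption). Real chromogen kits vary, so override with
#' [stain_matrix()] when calibrating to actual slides.
#' @export
default_stain_matrix <- function() {
  stain_matrix(
    haematoxylin = c(0.650, 0.704, 0.286),
    dab          = c(0.268, 0.570, 0.776),
    ap           = c(0.2159, 0.8012, 0.5581)
  )
}

#' Colour-deconvolve a brightfield RGB tile into per-stain optical density
#'
#' Transmitted intensities are converted to optical density with
#' `OD = -log10((I + 1) / 256)` per RGB channel (white glass, I = 255,
#' maps to OD 0) and unmixed by the inverse of the stain matrix
#' (Beer-Lambert: chromogen ODs add linearly). Negative unmixed values are
#' clipped to 0 unless `clip_negative = FALSE`.
#'
#' @param rgb numeric array `h x w x 3` of 8-bit-scale intensities in
#'   `[0, 255]`, or an `ihc_tile` object from [render_ihc_tile()].
#' @param stains a [stain_matrix()].
#' @param clip_negative clip negative unmixed OD to zero (default TRUE).
#' @return list of `h x w` OD matrices named `haematoxylin`, `dab`, `ap`.
#' @export
deconvolve_ihc <- function(rgb, stains = default_stain_matrix(),
                           clip_negative = TRUE) {
  if (inherits(rgb, "ihc_tile")) rgb <- rgb$rgb
  stopifnot(inherits(stains, "stain_matrix"))
  d <- dim(rgb)
  if (length(d) != 3 || d[3] != 3)
    stop("rgb must be an h x w x 3 array")
  if (max(rgb) <= 1 && max(rgb) > 0)
    rgb <- rgb * 255  # tolerate [0,1]-scaled input
  flat <- matrix(rgb, ncol = 3)
  od_rgb <- -log10((flat + 1) / 256)
  od_stain <- od_rgb %*% solve(unclass(stains))
  if (clip_negative) od_stain[od_stain < 0] <- 0
  out <- lapply(1:3, function(j) matrix(od_stain[, j], d[1], d[2]))
  names(out) <- rownames(stains)
  out
}

# Compose per-stain OD maps into transmitted RGB on the 0..255 float scale;
# exact inverse of the deconvolution transform (I = 256 * 10^-OD - 1).
compose_ihc_rgb <- function(od_list, stains) {
  d <- dim(od_list[[1]])
  od_stain <- vapply(od_list, as.vector, numeric(prod(d)))
  od_rgb <- od_stain %*% unclass(stains)
  rgb <- 256 * 10^(-od_rgb) - 1
  array(rgb, c(d, 3))
}
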