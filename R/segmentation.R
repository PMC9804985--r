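#' Segmentation configuration
#'
#' All spatial parameters are in micrometres (lengths) or square
#' micrometres (areas) and converted to pixels internally via the image's
#' pixel size, so one configuration transfers across magnifications.
#'
#' @param blur_sigma Gaussian pre-blur sigma (um) applied to the channel
#'   sum before tissue thresholding.
#' @param tissue_threshold_method `"triangle"` (default; robust when the
#'   histogram is dominated by the bare-glass peak), `"otsu"`, or
#'   `"fixed"`.
#' @param tissue_threshold fixed tissue threshold (intensity units), used
#'   only with method `"fixed"`.
#' @param islet_threshold_method `"otsu"` (default, computed within tissue
#'   pixels only so bare glass cannot bias it) or `"fixed"`.
#' @param islet_threshold fixed synaptophysin threshold.
#' @param insulin_threshold_method `"otsu"` (within islet pixels) or
#'   `"fixed"`.
#' @param insulin_threshold fixed insulin threshold.
#' @param closing_radius morphological closing radius (um) applied to the
#'   islet mask to bridge small gaps.
#' @param min_islet_area smallest retained islet component (um^2); rejects
#'   isolated positive cells -- islets are multicellular.
#' @param min_tissue_area smallest retained tissue component (um^2).
#' @param background_subtraction `"none"`, `"median"` (subtract the median
#'   synaptophysin intensity over tissue) or `"tophat"` (morphological
#'   white top-hat with `background_radius`).
#' @param background_radius structuring-element radius (um) for
#'   `"tophat"`.
#' @param min_class_separation minimum contrast, in background-standard-
#'   deviation units, between the pixel classes an automatic (Otsu)
#'   islet or insulin threshold produces. A split carved out of a single
#'   background mode scores ~2-3; real marker signal sits tens of sds
#'   above the autofluorescence background, so below the default 5 the
#'   field is declared marker-negative and the mask is empty.
#' @param dab_od_threshold optical-density threshold (OD units) for the
#'   DAB-positive mask of deconvolved brightfield tiles.
#' @param exclude_border_islets drop islet components touching the frame
#'   border (default FALSE: border islets are kept).
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(blur_sigma = 1,
                                tissue_threshold_method = c("triangle", "otsu", "fixed"),
                                tissue_threshold = NA_real_,
                                islet_threshold_method = c("otsu", "fixed"),
                                islet_threshold = NA_real_,
                                insulin_threshold_method = c("otsu", "fixed"),
                                insulin_threshold = NA_real_,
                                closing_radius = 2,
                                min_islet_area = 300,
                                min_tissue_area = 10000,
                                background_subtraction = c("none", "median", "tophat"),
                                background_radius = 50,
                                min_class_separation = 5,
                                dab_od_threshold = 0.3,
                                exclude_border_islets = FALSE) {
  cfg <- list(
    blur_sigma = blur_sigma,
    tissue_threshold_method = match.arg(tissue_threshold_method),
    tissue_threshold = tissue_threshold,
    islet_threshold_method = match.arg(islet_threshold_method),
    islet_threshold = islet_threshold,
    insulin_threshold_method = match.arg(insulin_threshold_method),
    insulin_threshold = insulin_threshold,
    closing_radius = closing_radius,
    min_islet_area = min_islet_area,
    min_tissue_area = min_tissue_area,
    background_subtraction = match.arg(background_subtraction),
    background_radius = background_radius,
    min_class_separation = min_class_separation,
    dab_od_threshold = dab_od_threshold,
    exclude_border_islets = isTRUE(exclude_border_islets)
  )
  stopifnot(cfg$blur_sigma >= 0, cfg$closing_radius >= 0,
            cfg$min_islet_area >= 0, cfg$min_tissue_area >= 0,
            cfg$background_radius >= 0, cfg$dab_od_threshold >= 0,
            cfg$min_class_separation >= 0)
  structure(cfg, class = "segmentation_config")
}

#' Segment the tissue footprint of a multichannel field
#'
#' Sums the channels, Gaussian-blurs at `blur_sigma`, thresholds
#' (triangle by default), fills holes, and removes components below
#' `min_tissue_area`. The result is the "pancreatic area examined" that
#' serves as the denominator of islet area fractions.
#'
#' @param img an `islet_image` (see [render_if_image()] / [read_if_image()]).
#' @param cfg a [segmentation_config()].
#' @return logical tissue mask.
#' @section Errors: an empty mask raises a condition of class
#'   `isletquant_no_tissue`; callers exclude the image and log it.
#' @export
compute_tissue_mask <- function(img, cfg = segmentation_config()) {
  stopifnot(inherits(img, "islet_image"), inherits(cfg, "segmentation_config"))
  total <- Reduce(`+`, img$channels)
  blurred <- ebi_blur(total, cfg$blur_sigma / img$pixel_size)
  # clip the top percentile (bright islets / nuclei) before histogramming:
  # the glass-vs-tissue threshold must not be stretched by the sparse
  # bright tail, which otherwise dominates the histogram range
  v <- as.vector(blurred)
  v <- pmin(v, stats::quantile(v, 0.99, names = FALSE))
  th <- threshold_values(v, cfg$tissue_threshold_method,
                         cfg$tissue_threshold)
  mask <- blurred > th
  mask <- ebi_fill_holes(mask)
  mask <- drop_small_components(mask, cfg$min_tissue_area / img$pixel_size^2)
  if (!any(mask)) {
    cond <- structure(
      class = c("isletquant_no_tissue", "error", "condition"),
      list(message = "no tissue detected in image (empty tissue mask)",
           call = sys.call(-1)))
    stop(cond)
  }
  mask
}

#' Segment synaptophysin-delineated islets within the tissue
#'
#' Optionally background-subtracts the synaptophysin channel, thresholds
#' it using only tissue pixels (Otsu by default), applies morphological
#' closing and hole filling, removes components below `min_islet_area`,
#' and intersects with the tissue mask. An empty result is valid (a field
#' with no islets reads 0% islet area).
#'
#' @inheritParams compute_tissue_mask
#' @param tissue logical tissue mask from [compute_tissue_mask()].
#' @return logical islet mask, a subset of `tissue`.
#' @export
compute_islet_mask <- function(img, tissue, cfg = segmentation_config()) {
  stopifnot(inherits(img, "islet_image"))
  if (!any(tissue)) stop("tissue mask is empty")
  syn <- img$channels$synaptophysin
  syn <- switch(cfg$background_subtraction,
    none = syn,
    median = pmax(syn - stats::median(syn[tissue]), 0),
    tophat = {
      size <- 2L * as.integer(ceiling(cfg$background_radius / img$pixel_size)) + 1L
      as.matrix(EBImage::whiteTopHat(syn, EBImage::makeBrush(size, "disc")))
    })
  th <- threshold_values(syn[tissue], cfg$islet_threshold_method,
                         cfg$islet_threshold)
  if (cfg$islet_threshold_method == "otsu" &&
      class_separation(syn[tissue], th) < cfg$min_class_separation) {
    # unimodal synaptophysin histogram: no islets in this field
    return(matrix(FALSE, nrow(tissue), ncol(tissue)))
  }
  mask <- syn > th & tissue
  mask <- ebi_close(mask, cfg$closing_radius / img$pixel_size)
  mask <- ebi_fill_holes(mask)
  mask <- drop_small_components(mask, cfg$min_islet_area / img$pixel_size^2)
  if (cfg$exclude_border_islets) mask <- drop_border_components(mask)
  mask & tissue
}

#' Segment insulin-positive (beta-cell) area within islets
#'
#' Thresholds the insulin channel using only islet pixels (Otsu by
#' default), so the threshold is independent of everything outside the
#' islet mask. The result is a subset of the islet mask. An empty islet
#' mask yields an empty result flagged with `attr(, "flag") = "empty_islet_mask"`.
#'
#' @inheritParams compute_islet_mask
#' @param islet logical islet mask from [compute_islet_mask()].
#' @return logical insulin-positive mask, a subset of `islet`.
#' @export
compute_insulin_mask <- function(img, islet, cfg = segmentation_config()) {
  stopifnot(inherits(img, "islet_image"))
  if (!any(islet)) {
    out <- matrix(FALSE, nrow(islet), ncol(islet))
    attr(out, "flag") <- "empty_islet_mask"
    return(out)
  }
  ins <- img$channels$insulin
  th <- threshold_values(ins[islet], cfg$insulin_threshold_method,
                         cfg$insulin_threshold)
  if (cfg$insulin_threshold_method == "otsu" &&
      class_separation(ins[islet], th) < cfg$min_class_separation) {
    # unimodal insulin histogram within the islets: no beta-cell signal
    return(matrix(FALSE, nrow(islet), ncol(islet)))
  }
  ins > th & islet
}

#' Threshold the DAB optical-density channel into a synaptophysin mask
#'
#' Applies the fixed OD threshold within tissue, then the same
#' morphological cleanup as the islet mask (closing, hole fill, minimum
#' area). Serves the brightfield route to the synaptophysin-positive
#' percentage of the pancreatic area examined.
#'
#' @param dab_od DAB OD matrix from [deconvolve_ihc()].
#' @param tissue logical tissue mask.
#' @param cfg a [segmentation_config()]; uses `dab_od_threshold`,
#'   `closing_radius`, `min_islet_area`.
#' @param pixel_size um/px of the tile.
#' @return logical DAB-positive mask, a subset of `tissue`.
#' @export
compute_dab_mask <- function(dab_od, tissue, cfg = segmentation_config(),
                             pixel_size = 0.25) {
  stopifnot(is.matrix(dab_od), all(dim(dab_od) == dim(tissue)))
  mask <- dab_od >= cfg$dab_od_threshold & tissue
  mask <- ebi_close(mask, cfg$closing_radius / pixel_size)
  mask <- ebi_fill_holes(mask)
  mask <- drop_small_components(mask, cfg$min_islet_area / pixel_size^2)
  mask & tissue
}

#' Run the full IF segmentation cascade
#'
#' Tissue, islet, and insulin-positive masks in one call; the nesting
#' insulin-positive within islet within tissue holds by construction.
#'
#' @inheritParams compute_tissue_mask
#' @return an object of class `mask_set`: list with logical matrices
#'   `tissue`, `islet`, `insulin_positive` and the `config_used`.
#' @export
segment_image <- function(img, cfg = segmentation_config()) {
  tissue <- compute_tissue_mask(img, cfg)
  islet <- compute_islet_mask(img, tissue, cfg)
  insulin <- compute_insulin_mask(img, islet, cfg)
  structure(list(tissue = tissue, islet = islet,
                 insulin_positive = insulin, config_used = cfg),
            class = "mask_set")
}

# drop components with any pixel on the frame border
drop_border_components <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  if (length(border)) mask[lab %in% border] <- FALSE
  mask
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of identical shape.
#' @return IoU in `[0, 1]`; 1 if both masks are empty.
#' @export
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
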