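#' Area of one mask as a percentage of a reference mask
#'
#' The islet-area read-out is this quantity with `mask` the islet (or
#' DAB-positive) mask and `reference` the tissue mask; the beta-cell
#' read-out uses the insulin-positive mask over the islet mask.
#'
#' @param mask logical matrix; must be a subset of `reference`.
#' @param reference logical matrix, non-empty.
#' @param pixel_size um/px (areas cancel in the ratio; kept for interface
#'   symmetry with the absolute-area fields).
#' @return percentage in `[0, 100]`.
#' @export
area_fraction <- function(mask, reference, pixel_size = 1) {
  if (!any(reference)) stop("reference mask is empty")
  if (!mask_is_subset(mask, reference))
    stop("mask is not a subset of the reference mask (upstream masking bug)")
  100 * sum(mask) / sum(reference)
}

#' Insulin signal statistics within the islet mask
#'
#' Integrates the anti-insulin fluorescence over the synaptophysin-derived
#' islet mask: `integrated` is the pixel sum, `mean` the per-pixel mean,
#' and `background` the median insulin intensity over tissue outside
#' islets. Background-subtracted variants subtract `background` per islet
#' pixel. An empty islet mask yields `NA` statistics and a flag -- never a
#' silent zero.
#'
#' @param img an `islet_image`.
#' @param islet logical islet mask.
#' @param tissue logical tissue mask (for the background region
#'   tissue-minus-islet); if NULL, background is `NA`.
#' @return list with `integrated`, `mean`, `background`,
#'   `integrated_bgsub`, `mean_bgsub`, `flag` (character or NA).
#' @export
insulin_intensity_in_islets <- function(img, islet, tissue = NULL) {
  stopifnot(inherits(img, "islet_image"))
  ins <- img$channels$insulin
  n <- sum(islet)
  if (n == 0) {
    return(list(integrated = NA_real_, mean = NA_real_,
                background = NA_real_, integrated_bgsub = NA_real_,
                mean_bgsub = NA_real_, flag = "empty_islet_mask"))
  }
  integrated <- sum(ins[islet])
  m <- integrated / n
  bg <- if (is.null(tissue)) NA_real_ else {
    outside <- tissue & !islet
    if (any(outside)) stats::median(ins[outside]) else NA_real_
  }
  list(integrated = integrated, mean = m, background = bg,
       integrated_bgsub = if (is.na(bg)) NA_real_ else integrated - bg * n,
       mean_bgsub = if (is.na(bg)) NA_real_ else m - bg,
       flag = NA_character_)
}

#' Per-image islet metrics
#'
#' Composes the area and intensity read-outs into one row: tissue and
#' islet areas (um^2), islet area as % of tissue, insulin-positive area as
#' % of islet, and raw plus background-subtracted insulin intensity
#' statistics. The identity `integrated = mean x islet pixel count` is
#' checked on construction.
#'
#' @param img an `islet_image`.
#' @param masks a `mask_set` from [segment_image()].
#' @param image_id identifier carried into the output row.
#' @return one-row data.frame (an `IsletMetrics` record).
#' @export
per_image_metrics <- function(img, masks, image_id = "image") {
  stopifnot(inherits(masks, "mask_set"))
  px_area <- img$pixel_size^2
  n_islet <- sum(masks$islet)
  intens <- insulin_intensity_in_islets(img, masks$islet, masks$tissue)
  if (!is.na(intens$integrated))
    stopifnot(abs(intens$integrated - intens$mean * n_islet) <
                1e-6 * max(1, abs(intens$integrated)))
  data.frame(
    image_id = image_id,
    tissue_area = sum(masks$tissue) * px_area,
    islet_area = n_islet * px_area,
    islet_area_pct_of_tissue =
      area_fraction(masks$islet, masks$tissue, img$pixel_size),
    insulin_pos_area_pct_of_islet = if (n_islet > 0)
      area_fraction(masks$insulin_positive, masks$islet, img$pixel_size)
      else NA_real_,
    insulin_integrated_intensity = intens$integrated,
    insulin_mean_intensity = intens$mean,
    insulin_mean_intensity_bgsub = intens$mean_bgsub,
    background_intensity = intens$background,
    flag = intens$flag,
    stringsAsFactors = FALSE
  )
}

#' Aggregate per-image metrics to one row per animal
#'
#' The one-dot-per-animal cohort table: each animal contributes the
#' tissue-area-weighted mean of every metric over its images (unweighted
#' by config). Animals whose every image lacked detectable islets keep
#' their area metrics but carry `NA` intensity metrics, with a warning;
#' animals with no analysable images at all are an error.
#'
#' @param metrics data.frame of [per_image_metrics()] rows.
#' @param manifest data.frame with columns `image_id`, `animal_id`,
#'   `group`.
#' @param weighting `"tissue_area"` (default) or `"none"`.
#' @return data.frame with one row per animal: `animal_id`, `group`,
#'   `n_images`, and the aggregated metric columns.
#' @export
aggregate_per_animal <- function(metrics, manifest,
                                 weighting = c("tissue_area", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("image_id", "animal_id", "group") %in% names(manifest)))
  unmatched <- setdiff(metrics$image_id, manifest$image_id)
  if (length(unmatched))
    stop("metrics rows with no manifest entry: ",
         paste(unmatched, collapse = ", "))
  df <- merge(metrics, manifest[, c("image_id", "animal_id", "group")],
              by = "image_id")
  animals <- manifest[!duplicated(manifest$animal_id),
                      c("animal_id", "group")]
  missing_animals <- setdiff(animals$animal_id, df$animal_id)
  if (length(missing_animals))
    stop("animal(s) with zero analysable images: ",
         paste(missing_animals, collapse = ", "))

  metric_cols <- c("tissue_area", "islet_area", "islet_area_pct_of_tissue",
                   "insulin_pos_area_pct_of_islet",
                   "insulin_integrated_intensity", "insulin_mean_intensity",
                   "insulin_mean_intensity_bgsub", "background_intensity")
  animals <- animals[order(animals$animal_id), ]
  out <- do.call(rbind, lapply(animals$animal_id, function(a) {
    sub <- df[df$animal_id == a, ]
    w <- if (weighting == "tissue_area") sub$tissue_area else
      rep(1, nrow(sub))
    agg <- vapply(metric_cols, function(col) {
      v <- sub[[col]]
      ok <- !is.na(v)
      if (!any(ok)) return(NA_real_)
      if (col %in% c("tissue_area", "islet_area")) return(mean(v[ok]))
      sum(v[ok] * w[ok]) / sum(w[ok])
    }, numeric(1))
    cbind(data.frame(animal_id = a, group = sub$group[1],
                     n_images = nrow(sub), stringsAsFactors = FALSE),
          as.data.frame(as.list(agg)))
  }))
  rownames(out) <- NULL
  no_islets <- out$animal_id[is.na(out$insulin_mean_intensity)]
  if (length(no_islets))
    warning("animal(s) without detectable islets in any image, excluded ",
            "from intensity comparisons: ",
            paste(no_islets, collapse = ", "))
  out
}
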