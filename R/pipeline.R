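#' Run the segment -> quantify -> compare workflow over a cohort manifest
#'
#' Reads every image listed in the manifest, segments it, computes
#' per-image metrics, aggregates them per animal, and runs the group
#' comparison against the control group. Each image is processed inside
#' an error barrier: an unreadable or tissue-free image is flagged and the
#' run continues. All outputs are written under `out_dir`:
#' `per_image_metrics.csv`, `per_animal_metrics.csv`,
#' `group_comparisons.csv`, `run_report.json` (provenance: config echo,
#' seed, package version, per-image status), and optionally QC overlay
#' PNGs. Two runs with identical inputs and configuration produce
#' byte-identical CSVs.
#'
#' @param manifest data.frame with columns `image_path`, `image_id`,
#'   `animal_id`, `group`, `modality`, `pixel_size` (as written by
#'   [generate_cohort()]), or the path of such a CSV.
#' @param out_dir output directory (created if needed).
#' @param control control group name; defaults to
#'   `attr(manifest, "control_group")`.
#' @param seg_config a [segmentation_config()].
#' @param metrics metric columns compared between groups.
#' @param alpha significance level.
#' @param zero_policy passed to [compare_cohort()].
#' @param weighting passed to [aggregate_per_animal()].
#' @param write_qc write one QC overlay PNG per successfully segmented IF
#'   image (default FALSE).
#' @param stains [stain_matrix()] used for IHC tiles in the manifest.
#' @return a `run_report` list: per-stage status, counts (processed /
#'   flagged / excluded summing to the manifest rows), the comparison
#'   results, and paths of the written outputs.
#' @export
run_pipeline <- function(manifest, out_dir,
                         control = NULL,
                         seg_config = segmentation_config(),
                         metrics = c("islet_area_pct_of_tissue",
                                     "insulin_pos_area_pct_of_islet",
                                     "insulin_mean_intensity_bgsub",
                                     "insulin_integrated_intensity"),
                         alpha = 0.05,
                         zero_policy = "exclude",
                         weighting = "tissue_area",
                         write_qc = FALSE,
                         stains = default_stain_matrix()) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("unreadable manifest: ", manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (nrow(manifest) == 0) stop("empty cohort: manifest has no rows")
  control <- control %||% attr(manifest, "control_group") %||%
    stop("no control group given and none recorded in the manifest")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  status <- character(nrow(manifest))
  rows <- list(); ihc_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    res <- tryCatch({
      if (rec$modality == "if") {
        img <- read_if_image(rec$image_path, rec$pixel_size)
        masks <- segment_image(img, seg_config)
        row <- per_image_metrics(img, masks, image_id = rec$image_id)
        if (write_qc) {
          write_ihc_png(render_qc_overlay(img, masks),
                        file.path(out_dir, paste0(rec$image_id, "_qc.png")))
        }
        rows[[length(rows) + 1]] <- row
        "processed"  # informational flags stay in the metrics CSV
      } else {
        tile <- read_ihc_png(rec$image_path)
        q <- quantify_ihc_tile(tile, stains, seg_config, rec$pixel_size)
        ihc_rows[[length(ihc_rows) + 1]] <-
          cbind(data.frame(image_id = rec$image_id,
                           animal_id = rec$animal_id, group = rec$group,
                           stringsAsFactors = FALSE), q)
        "processed"
      }
    }, isletquant_no_tissue = function(e) "excluded",
       error = function(e) {
      message("image ", rec$image_id, " flagged: ", conditionMessage(e))
      "flagged"
    })
    status[i] <- res
  }

  per_image <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(per_image)) stop("no IF image produced metrics; empty cohort?")
  utils::write.csv(per_image, file.path(out_dir, "per_image_metrics.csv"),
                   row.names = FALSE)
  per_animal <- aggregate_per_animal(
    per_image, manifest[manifest$image_id %in% per_image$image_id, ],
    weighting = weighting)
  utils::write.csv(per_animal, file.path(out_dir, "per_animal_metrics.csv"),
                   row.names = FALSE)
  if (length(ihc_rows)) {
    utils::write.csv(do.call(rbind, ihc_rows),
                     file.path(out_dir, "per_ihc_tile_metrics.csv"),
                     row.names = FALSE)
  }

  comparisons <- compare_cohort(per_animal, metrics = metrics,
                                control = control, alpha = alpha,
                                zero_policy = zero_policy)
  results <- comparison_table(comparisons)
  if (is.null(results)) results <- data.frame()
  utils::write.csv(results, file.path(out_dir, "group_comparisons.csv"),
                   row.names = FALSE)

  report <- list(
    stages = c(segment = "ok", quantify = "ok", stats = "ok"),
    n_images = nrow(manifest),
    processed = sum(status == "processed"),
    flagged = sum(status == "flagged"),
    excluded = sum(status == "excluded"),
    image_status = stats::setNames(status, manifest$image_id),
    control = control,
    alpha = alpha,
    config = unclass(seg_config),
    version = as.character(utils::packageVersion("isletquant")),
    outputs = file.path(out_dir, c("per_image_metrics.csv",
                                   "per_animal_metrics.csv",
                                   "group_comparisons.csv"))
  )
  jsonlite::write_json(report[setdiff(names(report), "comparisons")],
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  report$comparisons <- comparisons
  report$per_animal <- per_animal
  class(report) <- "run_report"
  report
}

#' Quantify a brightfield IHC tile
#'
#' Deconvolves the tile into per-stain OD, segments tissue from the total
#' OD and the DAB-positive area by OD threshold, and reports the
#' DAB-positive (synaptophysin) percentage of the tissue area examined.
#'
#' @param rgb `h x w x 3` array (0..255) or `ihc_tile`.
#' @param stains a [stain_matrix()].
#' @param cfg a [segmentation_config()].
#' @param pixel_size um/px.
#' @return one-row data.frame: `tissue_area` (um^2),
#'   `dab_area_pct_of_tissue`.
#' @export
quantify_ihc_tile <- function(rgb, stains = default_stain_matrix(),
                              cfg = segmentation_config(),
                              pixel_size = 0.25) {
  od <- deconvolve_ihc(rgb, stains)
  total_od <- Reduce(`+`, od)
  pseudo <- structure(list(channels = list(dapi = total_od,
                                           synaptophysin = total_od * 0,
                                           insulin = total_od * 0),
                           pixel_size = pixel_size, bit_depth = 8L),
                      class = "islet_image")
  tissue <- compute_tissue_mask(pseudo, cfg)
  dab <- compute_dab_mask(od$dab, tissue, cfg, pixel_size)
  data.frame(tissue_area = sum(tissue) * pixel_size^2,
             dab_area_pct_of_tissue = area_fraction(dab, tissue, pixel_size))
}

#' Compose a QC overlay of channels and mask outlines
#'
#' Builds an RGB composite (insulin -> red+green (gold), synaptophysin ->
#' magenta-ish red+blue, DAPI -> cyan-ish blue) and overdraws the
#' morphological boundary of the islet mask in yellow and of the
#' insulin-positive mask in white, for visual inspection of segmentation
#' quality.
#'
#' @param img an `islet_image`.
#' @param masks a `mask_set`.
#' @return `h x w x 3` array on the 0..255 scale.
#' @export
render_qc_overlay <- function(img, masks) {
  stopifnot(inherits(img, "islet_image"), inherits(masks, "mask_set"))
  maxval <- 2^img$bit_depth - 1
  norm <- function(x) pmin(x / maxval, 1) * 255
  ins <- norm(img$channels$insulin)
  syn <- norm(img$channels$synaptophysin)
  dapi <- norm(img$channels$dapi)
  r <- pmin(ins + 0.7 * syn, 255)
  g <- pmin(0.85 * ins + 0.4 * dapi, 255)
  b <- pmin(0.7 * syn + dapi, 255)
  islet_edge <- mask_boundary(masks$islet)
  ins_edge <- mask_boundary(masks$insulin_positive)
  r[islet_edge] <- 255; g[islet_edge] <- 255; b[islet_edge] <- 0
  r[ins_edge] <- 255; g[ins_edge] <- 255; b[ins_edge] <- 255
  out <- array(0, c(dim(r), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
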