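#' Specify a synthetic two-group (or multi-group) cohort
#'
#' @param groups list of group descriptors, each a list with `name`,
#'   `n_animals` (>= 2), `control` (logical; exactly one group TRUE), and
#'   optional generator-parameter overrides in `params` (named list passed
#'   to [update_params()]), plus optional `beta_fraction_sd` (per-animal
#'   spread of the insulin-positive fraction, percentage points / 100).
#' @param images_per_animal IF fields generated per animal.
#' @param ihc_tiles_per_animal brightfield IHC tiles per animal (default 0).
#' @param base_params shared [generator_params()] that group overrides
#'   modify.
#' @param between_animal_sdlog10 per-animal biological variation: each
#'   animal's islet-area-fraction target is jittered by
#'   `10^N(0, between_animal_sdlog10)` around its group value.
#' @param intensity_sdlog10 per-animal jitter of insulin and synaptophysin
#'   intensity, `10^N(0, intensity_sdlog10)`.
#' @param master_seed integer; per-animal seeds are derived from it by a
#'   label hash, so adding a group never perturbs existing animals.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups,
                        images_per_animal = 3L,
                        ihc_tiles_per_animal = 0L,
                        base_params = generator_params(),
                        between_animal_sdlog10 = 0.25,
                        intensity_sdlog10 = 0.05,
                        master_seed = 1L) {
  stopifnot(length(groups) >= 1, images_per_animal >= 1)
  ctrl <- vapply(groups, function(g) isTRUE(g$control), logical(1))
  if (sum(ctrl) != 1) stop("exactly one group must be flagged control = TRUE")
  for (g in groups) {
    if (is.null(g$name) || is.null(g$n_animals))
      stop("each group needs a name and n_animals")
    if (g$n_animals < 2) stop("each group needs n_animals >= 2")
  }
  structure(list(groups = groups,
                 images_per_animal = as.integer(images_per_animal),
                 ihc_tiles_per_animal = as.integer(ihc_tiles_per_animal),
                 base_params = base_params,
                 between_animal_sdlog10 = between_animal_sdlog10,
                 intensity_sdlog10 = intensity_sdlog10,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' The study-calibrated cohort: 10 non-diabetic controls vs 9 diabetic cats
#'
#' Group-level truths follow the study read-outs: control islet area 0.8%
#' of tissue with ~55% insulin-positive islet area; diabetic islet area
#' 0.3% with ~47% insulin-positive and insulin intensity halved
#' (glucotoxic loss of insulin expression). Per-animal spreads of the
#' insulin-positive fraction are sd 11 pp (control) and 21 pp (diabetic).
#'
#' @inheritParams cohort_spec
#' @param ... further arguments passed to [cohort_spec()].
#' @export
study_cohort_spec <- function(base_params = generator_params(),
                              images_per_animal = 3L, master_seed = 1L,
                              ...) {
  cohort_spec(
    groups = list(
      list(name = "non_diabetic", n_animals = 10L, control = TRUE,
           params = list(islet_area_fraction_target = 0.008,
                         beta_fraction = 0.55),
           beta_fraction_sd = 0.11),
      list(name = "diabetic", n_animals = 9L, control = FALSE,
           params = list(islet_area_fraction_target = 0.003,
                         beta_fraction = 0.47,
                         insulin_intensity =
                           0.5 * base_params$insulin_intensity),
           beta_fraction_sd = 0.21)
    ),
    images_per_animal = images_per_animal,
    base_params = base_params,
    master_seed = master_seed,
    ...
  )
}

# per-animal generator params: group overrides + animal-level biological
# jitter, all drawn from the animal's own seed stream
animal_params <- function(spec, group, animal_idx) {
  p <- spec$base_params
  if (!is.null(group$params)) p <- do.call(update_params, c(list(p), group$params))
  aseed <- seed_chain(spec$master_seed, group$name, animal_idx)
  withr::with_seed(aseed, {
    frac <- p$islet_area_fraction_target *
      10^stats::rnorm(1, sd = spec$between_animal_sdlog10)
    frac <- min(frac, 0.49)
    beta_sd <- group$beta_fraction_sd %||% 0
    beta <- min(max(p$beta_fraction + stats::rnorm(1, sd = beta_sd), 0.02), 0.98)
    gain <- 10^stats::rnorm(1, sd = spec$intensity_sdlog10)
    update_params(p,
                  islet_area_fraction_target = frac,
                  beta_fraction = beta,
                  insulin_intensity = p$insulin_intensity * gain,
                  synaptophysin_intensity = p$synaptophysin_intensity * gain,
                  seed = aseed)
  })
}

#' Generate a synthetic cohort on disk
#'
#' Writes, per animal and field, a three-channel IF image set (and
#' optionally IHC tiles), plus `manifest.csv` (`image_path, image_id,
#' animal_id, group, modality, pixel_size`) and `ground_truth.csv` (true
#' islet fraction, true insulin-positive fraction, true insulin intensity
#' per image). Per-animal and per-image seeds are derived from
#' `master_seed` by label hashing, so regeneration is byte-identical. On
#' failure, files already written are removed.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir writable output directory (created if needed).
#' @return the manifest data.frame, invisibly; written alongside the
#'   images. The ground-truth table is attached as
#'   `attr(manifest, "ground_truth")`.
#' @export
generate_cohort <- function(spec, out_dir) {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0) stop("out_dir not writable: ", out_dir)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written), add = TRUE)

  manifest <- list(); truth <- list()
  for (g in spec$groups) {
    for (i in seq_len(g$n_animals)) {
      animal_id <- sprintf("%s_%02d", g$name, i)
      p_animal <- animal_params(spec, g, i)
      for (j in seq_len(spec$images_per_animal)) {
        img_seed <- seed_chain(spec$master_seed, g$name, i, "if", j)
        image_id <- sprintf("%s_img%02d", animal_id, j)
        gt <- sample_islet_geometry(p_animal, seed = img_seed)
        img <- render_if_image(gt, p_animal, seed = img_seed)
        prefix <- file.path(out_dir, image_id)
        write_if_image(img, prefix)
        written <- c(written, paste0(prefix, unlist(CHANNEL_SUFFIX)))
        manifest[[length(manifest) + 1]] <- data.frame(
          image_path = prefix, image_id = image_id, animal_id = animal_id,
          group = g$name, modality = "if",
          pixel_size = p_animal$pixel_size, stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          image_id = image_id, animal_id = animal_id, group = g$name,
          true_islet_fraction = gt$true_islet_fraction,
          true_beta_fraction_of_islet = gt$true_beta_fraction_of_islet,
          true_mean_insulin_intensity = gt$true_mean_insulin_intensity,
          stringsAsFactors = FALSE)
      }
      for (j in seq_len(spec$ihc_tiles_per_animal)) {
        img_seed <- seed_chain(spec$master_seed, g$name, i, "ihc", j)
        image_id <- sprintf("%s_ihc%02d", animal_id, j)
        gt <- sample_islet_geometry(p_animal, seed = img_seed)
        tile <- render_ihc_tile(gt, p_animal, seed = img_seed)
        path <- file.path(out_dir, paste0(image_id, ".png"))
        write_ihc_png(tile, path)
        written <- c(written, path)
        manifest[[length(manifest) + 1]] <- data.frame(
          image_path = path, image_id = image_id, animal_id = animal_id,
          group = g$name, modality = "ihc",
          pixel_size = p_animal$pixel_size, stringsAsFactors = FALSE)
        truth[[length(truth) + 1]] <- data.frame(
          image_id = image_id, animal_id = animal_id, group = g$name,
          true_islet_fraction = gt$true_islet_fraction,
          true_beta_fraction_of_islet = gt$true_beta_fraction_of_islet,
          true_mean_insulin_intensity = gt$true_mean_insulin_intensity,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  written <- c(written, file.path(out_dir, c("manifest.csv",
                                             "ground_truth.csv")))
  ok <- TRUE
  attr(manifest, "ground_truth") <- truth
  attr(manifest, "control_group") <-
    vapply(spec$groups, function(g) g$name,
           character(1))[vapply(spec$groups, function(g) isTRUE(g$control),
                                logical(1))]
  invisible(manifest)
}

#' Simulate per-animal metric read-outs without rendering pixels
#'
#' Draws one read-out per animal from a lognormal measurement model:
#' `value = 10^(log10(group_mean) + N(0, sdlog10))`. This is the
#' metric-level view of the cohort generator -- the distribution the full
#' image pipeline produces for a well-segmented metric -- and is what the
#' type-I-error and power calibrations of the statistical workflow run on.
#'
#' @param group_means named numeric vector: true group-level metric means
#'   (first element taken as control unless `control` given).
#' @param n_animals named integer vector aligned with `group_means`.
#' @param sdlog10 between-animal sd on the log10 scale (default 0.25, the
#'   spread calibrated to the study's islet-area read-out).
#' @param seed integer seed.
#' @param control control group name (default: first of `group_means`).
#' @return data.frame with `animal_id`, `group`, `value`, plus the control
#'   group name as attribute `control_group`.
#' @export
simulate_cohort_metrics <- function(group_means, n_animals, sdlog10 = 0.25,
                                    seed = 1L,
                                    control = names(group_means)[1]) {
  stopifnot(length(group_means) == length(n_animals),
            !is.null(names(group_means)),
            identical(names(group_means), names(n_animals)),
            control %in% names(group_means))
  withr::with_seed(as.integer(seed), {
    rows <- lapply(names(group_means), function(g) {
      n <- n_animals[[g]]
      data.frame(
        animal_id = sprintf("%s_%02d", g, seq_len(n)),
        group = g,
        value = 10^(log10(group_means[[g]]) +
                      stats::rnorm(n, sd = sdlog10)),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "control_group") <- control
    out
  })
}
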