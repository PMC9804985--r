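#' Parameters of the synthetic microscopy image generator
#'
#' Bundles every knob of the synthetic islet-field generator. The defaults
#' describe a x40-scan-like field: a 2048 x 2048 px frame at 0.25 um/px
#' (~0.26 mm^2), sparse islets targeting 0.8% of tissue area with ~55% of
#' islet pixels insulin-positive, matching a healthy pancreas.
#'
#' @param image_shape integer (rows, cols) of the pixel grid.
#' @param pixel_size pixel edge length in micrometres.
#' @param islet_area_fraction_target fraction of tissue area to cover with
#'   islets, in `[0, 0.5)`. The placement loop stops within +/-10% relative
#'   of this target.
#' @param islet_radius_lognormal `c(mu, sigma)`: islet equivalent radii are
#'   drawn as `rlnorm(meanlog = log(mu), sdlog = sigma)` in micrometres,
#'   i.e. `mu` is the median radius. Draws are truncated below by
#'   `min_islet_radius` and above by the remaining area budget of the
#'   placement target.
#' @param min_islet_radius smallest generated islet equivalent radius
#'   (um). Islets are multicellular; the default 12.5 um (~490 um^2) stays
#'   above the segmentation default minimum islet area of 300 um^2.
#' @param beta_fraction fraction of islet pixels that are insulin-positive
#'   (beta cells), in `[0, 1]`.
#' @param insulin_intensity mean insulin-channel signal of insulin-positive
#'   pixels (arbitrary units on the sensor scale).
#' @param synaptophysin_intensity mean synaptophysin-channel signal of islet
#'   pixels.
#' @param background_level tissue autofluorescence added to every tissue
#'   pixel in each channel; bare glass outside the tissue reads ~0.
#' @param background_texture_sd log-scale sd of the smooth multiplicative
#'   texture modulating tissue autofluorescence (0 = perfectly uniform
#'   background; the default 0.2 gives the broad, structured background
#'   histogram real tissue shows, which peak-based thresholding assumes).
#' @param dapi_intensity peak signal of nuclear disks in the DAPI channel.
#' @param nuclear_radius nucleus disk radius, micrometres.
#' @param nuclear_density nuclei per mm^2 of tissue.
#' @param noise_model list with `poisson_gain` (photons per intensity unit;
#'   0 disables shot noise) and `gaussian_sd` (additive read noise sd on the
#'   sensor scale; 0 disables).
#' @param bit_depth sensor bit depth, 8 or 16; rendered values are clipped
#'   (never wrapped) to `[0, 2^bit_depth - 1]`.
#' @param beta_layout `"blob"` grows one connected beta-cell region per
#'   islet from a random interior seed (beta cells cluster in islet cores);
#'   `"bernoulli"` samples islet pixels independently instead.
#' @param max_placement_attempts cap on rejected islet placements before
#'   the generator gives up with an error.
#' @param ihc list of brightfield-rendering optical densities: `haem_tissue`
#'   (light haematoxylin tint of cytoplasm), `haem_nucleus`, `dab` (islet
#'   chromogen), `ap` (macrophage chromogen), `macrophage_density` per mm^2,
#'   `noise_cv` multiplicative noise coefficient of variation.
#' @param seed integer seed; identical parameters and seed reproduce every
#'   output pixel-for-pixel.
#'
#' @return an object of class `generator_params` (a validated list).
#' @export
#' @examples
#' p <- generator_params(image_shape = c(256, 256), pixel_size = 2)
#' gt <- sample_islet_geometry(p)
#' gt$true_islet_fraction
generator_params <- function(image_shape = c(2048L, 2048L),
                             pixel_size = 0.25,
                             islet_area_fraction_target = 0.008,
                             islet_radius_lognormal = c(40, 0.5),
                             min_islet_radius = 12.5,
                             beta_fraction = 0.55,
                             insulin_intensity = 160,
                             synaptophysin_intensity = 120,
                             background_level = 10,
                             background_texture_sd = 0.2,
                             dapi_intensity = 140,
                             nuclear_radius = 3.5,
                             nuclear_density = 2000,
                             noise_model = list(poisson_gain = 1,
                                                gaussian_sd = 2),
                             bit_depth = 8L,
                             beta_layout = c("blob", "bernoulli"),
                             max_placement_attempts = 2000L,
                             ihc = list(haem_tissue = 0.15,
                                        haem_nucleus = 0.8,
                                        dab = 0.9, ap = 0.7,
                                        macrophage_density = 50,
                                        noise_cv = 0.02),
                             seed = 1L) {
  beta_layout <- match.arg(beta_layout)
  p <- list(
    image_shape = as.integer(image_shape),
    pixel_size = pixel_size,
    islet_area_fraction_target = islet_area_fraction_target,
    islet_radius_lognormal = islet_radius_lognormal,
    min_islet_radius = min_islet_radius,
    beta_fraction = beta_fraction,
    insulin_intensity = insulin_intensity,
    synaptophysin_intensity = synaptophysin_intensity,
    background_level = background_level,
    background_texture_sd = background_texture_sd,
    dapi_intensity = dapi_intensity,
    nuclear_radius = nuclear_radius,
    nuclear_density = nuclear_density,
    noise_model = noise_model,
    bit_depth = as.integer(bit_depth),
    beta_layout = beta_layout,
    max_placement_attempts = as.integer(max_placement_attempts),
    ihc = ihc,
    seed = as.integer(seed)
  )
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  stopifnot(
    length(p$image_shape) == 2, all(p$image_shape >= 16),
    p$pixel_size > 0,
    p$islet_area_fraction_target >= 0, p$islet_area_fraction_target < 0.5,
    length(p$islet_radius_lognormal) == 2, p$islet_radius_lognormal[1] > 0,
    p$islet_radius_lognormal[2] >= 0,
    p$min_islet_radius >= 0,
    p$beta_fraction >= 0, p$beta_fraction <= 1,
    p$insulin_intensity >= 0, p$synaptophysin_intensity >= 0,
    p$background_level >= 0, p$background_texture_sd >= 0,
    p$dapi_intensity >= 0,
    p$noise_model$poisson_gain >= 0, p$noise_model$gaussian_sd >= 0,
    p$bit_depth %in% c(8L, 16L)
  )
  invisible(p)
}

#' Update generator parameters
#'
#' Returns a copy of `params` with the named fields replaced, revalidated.
#' Used for per-group and per-animal overrides when building cohorts.
#'
#' @param params a [generator_params()] object.
#' @param ... named fields to replace.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "generator_params"))
  dots <- list(...)
  bad <- setdiff(names(dots), names(unclass(params)))
  if (length(bad)) stop("unknown generator parameter(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(dots)) params[[nm]] <- dots[[nm]]
  if (!is.null(dots$beta_layout))
    params$beta_layout <- match.arg(dots$beta_layout, c("blob", "bernoulli"))
  validate_generator_params(params)
  params
}
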