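#' Render a three-channel immunofluorescence image from ground truth
#'
#' Produces the dapi / synaptophysin / insulin channels of a synthetic
#' field: synaptophysin at `synaptophysin_intensity` on islet pixels,
#' insulin at `insulin_intensity` on beta-cell pixels, tissue
#' autofluorescence (`background_level`) on all other tissue pixels, ~0 on
#' bare glass, and DAPI disks at random nuclear centres throughout the
#' tissue. Each channel is then passed through Poisson shot noise
#' (`noise_model$poisson_gain` photons per intensity unit; 0 disables) and
#' additive Gaussian read noise (`noise_model$gaussian_sd`; 0 disables),
#' and clipped -- never wrapped -- to the sensor range
#' `[0, 2^bit_depth - 1]`. With both noise terms disabled the channels are
#' exact deterministic functions of the ground truth.
#'
#' @param gt an `islet_ground_truth` from [sample_islet_geometry()].
#' @param params the [generator_params()] that produced `gt`.
#' @param seed optional integer overriding `params$seed` for the noise and
#'   nucleus stream.
#' @return an object of class `islet_image`: list with `channels` (named
#'   list of matrices `dapi`, `synaptophysin`, `insulin`), `pixel_size`
#'   (um/px) and `bit_depth`.
#' @export
render_if_image <- function(gt, params, seed = NULL) {
  stopifnot(inherits(gt, "islet_ground_truth"))
  validate_generator_params(params)
  if (!all(dim(gt$tissue_mask) == params$image_shape))
    stop("ground truth and params disagree on image shape")
  seed <- as.integer(seed %||% params$seed)
  withr::with_seed(seed_chain(seed, "render_if"), {
    islet <- gt$islet_label_map > 0L
    tissue <- gt$tissue_mask
    bg <- params$background_level * background_texture(tissue, params)

    syn <- matrix(0, nrow(tissue), ncol(tissue))
    syn[tissue] <- bg[tissue]
    syn[islet] <- params$synaptophysin_intensity

    ins <- matrix(0, nrow(tissue), ncol(tissue))
    ins[tissue] <- bg[tissue]
    ins[gt$beta_mask] <- params$insulin_intensity

    dapi <- matrix(0, nrow(tissue), ncol(tissue))
    dapi[tissue] <- bg[tissue]
    nuc <- sample_nucleus_mask(tissue, params)
    dapi[nuc] <- params$dapi_intensity

    maxval <- 2^params$bit_depth - 1
    channels <- lapply(list(dapi = dapi, synaptophysin = syn, insulin = ins),
                       apply_sensor_noise, params$noise_model, maxval)
    structure(list(channels = channels,
                   pixel_size = params$pixel_size,
                   bit_depth = params$bit_depth),
              class = "islet_image")
  })
}

# Smooth multiplicative autofluorescence texture, exp(G) with G a heavily
# blurred Gaussian field rescaled to sd background_texture_sd. Gives the
# tissue background histogram the broad structured hump real slides show
# (bare glass stays a sharp peak). Returns a matrix of 1s when disabled.
background_texture <- function(tissue, params) {
  sd <- params$background_texture_sd
  nr <- nrow(tissue); nc <- ncol(tissue)
  if (sd <= 0) return(matrix(1, nr, nc))
  g <- matrix(stats::rnorm(nr * nc), nr, nc)
  g <- ebi_blur(g, sigma_px = min(nr, nc) / 25)
  g <- g / stats::sd(g) * sd
  exp(g - sd^2 / 2)  # unit-mean lognormal field
}

# nuclei as disks of nuclear_radius at Poisson-count random centres in tissue
sample_nucleus_mask <- function(tissue, params) {
  nr <- nrow(tissue); nc <- ncol(tissue)
  area_mm2 <- sum(tissue) * (params$pixel_size / 1000)^2
  n <- stats::rpois(1, params$nuclear_density * area_mm2)
  nuc <- matrix(FALSE, nr, nc)
  if (n == 0 || params$dapi_intensity == 0) return(nuc)
  centres <- sample(which(tissue), min(n, sum(tissue)))
  r_px <- params$nuclear_radius / params$pixel_size
  half <- ceiling(r_px)
  offs <- expand.grid(dr = -half:half, dc = -half:half)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r_px^2, ]
  rr0 <- ((centres - 1) %% nr) + 1
  cc0 <- ((centres - 1) %/% nr) + 1
  for (k in seq_len(nrow(offs))) {
    rr <- rr0 + offs$dr[k]; cc <- cc0 + offs$dc[k]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    nuc[(cc[ok] - 1L) * nr + rr[ok]] <- TRUE
  }
  nuc
}

apply_sensor_noise <- function(x, noise_model, maxval) {
  gain <- noise_model$poisson_gain
  sd <- noise_model$gaussian_sd
  if (gain > 0) x <- matrix(stats::rpois(length(x), x * gain) / gain,
                            nrow(x), ncol(x))
  if (sd > 0) x <- x + matrix(stats::rnorm(length(x), sd = sd),
                              nrow(x), ncol(x))
  x[x < 0] <- 0
  x[x > maxval] <- maxval
  x
}

#' Render a brightfield double-stain immunohistochemistry tile
#'
#' Emulates a synaptophysin IHC slide: haematoxylin counterstain (a light
#' cytoplasmic tint over all tissue, strong at nuclei), brown DAB chromogen
#' on islet pixels, and optional sparse magenta AP dots standing in for
#' macrophages. Per-pixel optical densities are composed through the stain
#' matrix and converted to transmitted RGB by the Beer-Lambert relation
#' (the exact inverse of [deconvolve_ihc()]'s OD transform, so the
#' noise-free render/deconvolve round trip is lossless); multiplicative
#' sensor noise with coefficient of variation `params$ihc$noise_cv` is then
#' applied and the result clipped to `[0, 255]`.
#'
#' @inheritParams render_if_image
#' @param stains a [stain_matrix()].
#' @return an object of class `ihc_tile`: list with `rgb` (`h x w x 3`
#'   float array on the 0..255 scale), `od` (the ground-truth per-stain OD
#'   maps), `stains`, and `pixel_size`.
#' @export
render_ihc_tile <- function(gt, params, stains = default_stain_matrix(),
                            seed = NULL) {
  stopifnot(inherits(gt, "islet_ground_truth"),
            inherits(stains, "stain_matrix"))
  validate_generator_params(params)
  seed <- as.integer(seed %||% params$seed)
  withr::with_seed(seed_chain(seed, "render_ihc"), {
    tissue <- gt$tissue_mask
    islet <- gt$islet_label_map > 0L
    cfg <- params$ihc

    tex <- background_texture(tissue, params)
    od_h <- matrix(0, nrow(tissue), ncol(tissue))
    od_h[tissue] <- cfg$haem_tissue * tex[tissue]
    nuc <- sample_nucleus_mask(tissue, params)
    od_h[nuc] <- cfg$haem_nucleus

    od_dab <- matrix(0, nrow(tissue), ncol(tissue))
    od_dab[islet] <- cfg$dab

    od_ap <- matrix(0, nrow(tissue), ncol(tissue))
    if (cfg$macrophage_density > 0 && cfg$ap > 0) {
      area_mm2 <- sum(tissue) * (params$pixel_size / 1000)^2
      n <- stats::rpois(1, cfg$macrophage_density * area_mm2)
      if (n > 0) {
        mac <- sample_disk_mask(tissue, n, 2 / params$pixel_size)
        od_ap[mac] <- cfg$ap
      }
    }

    od <- list(haematoxylin = od_h, dab = od_dab, ap = od_ap)
    rgb <- compose_ihc_rgb(od, stains)
    if (cfg$noise_cv > 0) {
      rgb <- rgb * (1 + array(stats::rnorm(length(rgb), sd = cfg$noise_cv),
                              dim(rgb)))
      rgb[rgb < 0] <- 0
      rgb[rgb > 255] <- 255
    }
    structure(list(rgb = rgb, od = od, stains = stains,
                   pixel_size = params$pixel_size),
              class = "ihc_tile")
  })
}

# n disks of radius r_px at random tissue centres
sample_disk_mask <- function(tissue, n, r_px) {
  nr <- nrow(tissue); nc <- ncol(tissue)
  out <- matrix(FALSE, nr, nc)
  centres <- sample(which(tissue), min(n, sum(tissue)))
  half <- ceiling(r_px)
  offs <- expand.grid(dr = -half:half, dc = -half:half)
  offs <- offs[offs$dr^2 + offs$dc^2 <= r_px^2, ]
  rr0 <- ((centres - 1) %% nr) + 1
  cc0 <- ((centres - 1) %/% nr) + 1
  for (k in seq_len(nrow(offs))) {
    rr <- rr0 + offs$dr[k]; cc <- cc0 + offs$dc[k]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out[(cc[ok] - 1L) * nr + rr[ok]] <- TRUE
  }
  out
}
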