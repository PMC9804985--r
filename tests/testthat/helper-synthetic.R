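# Shared fixtures: small fast generator configurations. Frames are 256 px
# at 2 um/px (a 512 x 512 um field, the same physical size as the default
# 2048 px / 0.25 um frame) so tests run quickly at identical geometry.

small_params <- function(..., noise_free = FALSE) {
  noise <- if (noise_free) list(poisson_gain = 0, gaussian_sd = 0)
           else list(poisson_gain = 1, gaussian_sd = 2)
  args <- utils::modifyList(
    list(image_shape = c(256L, 256L), pixel_size = 2,
         noise_model = noise, seed = 1L),
    list(...))
  do.call(generator_params, args)
}

# medium frame for accuracy-sensitive checks (same field, finer grid)
medium_params <- function(..., noise_free = FALSE) {
  noise <- if (noise_free) list(poisson_gain = 0, gaussian_sd = 0)
           else list(poisson_gain = 1, gaussian_sd = 2)
  args <- utils::modifyList(
    list(image_shape = c(512L, 512L), pixel_size = 1,
         noise_model = noise, seed = 1L),
    list(...))
  do.call(generator_params, args)
}

# a tiny synthetic multichannel image built directly from matrices
make_image <- function(dapi, synaptophysin, insulin, pixel_size = 1,
                       bit_depth = 8L) {
  structure(list(channels = list(dapi = dapi, synaptophysin = synaptophysin,
                                 insulin = insulin),
                 pixel_size = pixel_size, bit_depth = bit_depth),
            class = "islet_image")
}

# Two-group plumbing fixture. The diabetic group keeps the control islet
# target by default so small test frames reliably contain islets; effect
# recovery is exercised by the larger acceptance cohorts instead.
two_group_spec <- function(n_animals = 2L, images_per_animal = 3L,
                           master_seed = 5L, frame = 256L, pixel_size = 2,
                           diabetic_params = list(
                             islet_area_fraction_target = 0.008,
                             beta_fraction = 0.47,
                             insulin_intensity = 80),
                           between_animal_sdlog10 = 0.1,
                           ...) {
  base <- generator_params(image_shape = c(frame, frame),
                           pixel_size = pixel_size)
  cohort_spec(
    groups = list(
      list(name = "non_diabetic", n_animals = n_animals, control = TRUE,
           params = list(islet_area_fraction_target = 0.008,
                         beta_fraction = 0.55)),
      list(name = "diabetic", n_animals = n_animals, control = FALSE,
           params = diabetic_params)),
    images_per_animal = images_per_animal,
    base_params = base, master_seed = master_seed,
    between_animal_sdlog10 = between_animal_sdlog10, ...)
}
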