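test_that("zero islet target yields an empty label map", {
  p <- small_params(islet_area_fraction_target = 0)
  gt <- sample_islet_geometry(p)
  expect_true(all(gt$islet_label_map == 0L))
  expect_identical(gt$true_islet_fraction, 0)
  expect_false(any(gt$beta_mask))
})

test_that("geometry is deterministic under a fixed seed", {
  p <- small_params(seed = 42L)
  a <- sample_islet_geometry(p)
  b <- sample_islet_geometry(p)
  expect_identical(a$islet_label_map, b$islet_label_map)
  expect_identical(a$tissue_mask, b$tissue_mask)
  expect_identical(a$beta_mask, b$beta_mask)
})

test_that("achieved islet fraction lands within 10% of the target", {
  for (s in 1:5) {
    p <- medium_params(islet_area_fraction_target = 0.01, seed = s)
    gt <- sample_islet_geometry(p)
    # oracle: recount pixels in the returned label map
    frac <- 100 * sum(gt$islet_label_map > 0) / sum(gt$tissue_mask)
    expect_equal(frac, gt$true_islet_fraction, tolerance = 1e-12)
    expect_gte(frac, 0.9)
    expect_lte(frac, 1.1)
  }
})

test_that("ground-truth masks nest: beta within islet within tissue", {
  for (s in 1:5) {
    p <- small_params(islet_area_fraction_target = runif(1, 0.002, 0.02),
                      beta_fraction = runif(1, 0.2, 0.9), seed = s)
    gt <- sample_islet_geometry(p)
    islet <- gt$islet_label_map > 0L
    expect_true(all(!gt$beta_mask | islet))
    expect_true(all(!islet | gt$tissue_mask))
    expect_gte(sum(gt$tissue_mask) / prod(p$image_shape), 0.6)
  }
})

test_that("beta fraction of islet pixels honours the request", {
  for (layout in c("blob", "bernoulli")) {
    p <- small_params(beta_fraction = 0.47, beta_layout = layout, seed = 3L)
    gt <- sample_islet_geometry(p)
    expect_lt(abs(gt$true_beta_fraction_of_islet - 47), 2)
  }
})

test_that("exhausted placement fails naming achieved vs requested", {
  p <- small_params(islet_area_fraction_target = 0.01,
                    max_placement_attempts = 0L)
  expect_error(sample_islet_geometry(p), "achieved fraction.*requested")
})

test_that("sub-islet targets draw zero or one minimum-size islet", {
  # target area below one minimum islet: expect mostly empty fields whose
  # expected fraction is unbiased for the target
  fracs <- vapply(1:30, function(s) {
    p <- small_params(islet_area_fraction_target = 0.0005, seed = s)
    gt <- sample_islet_geometry(p)
    n_islets <- max(gt$islet_label_map)
    stopifnot(n_islets <= 1)
    gt$true_islet_fraction
  }, numeric(1))
  expect_true(any(fracs == 0))
  expect_lt(abs(mean(fracs) - 0.05), 0.06)  # mean tracks 0.05% loosely
})

test_that("noise-free channels are exact functions of the ground truth", {
  p <- small_params(noise_free = TRUE, background_level = 0,
                    background_texture_sd = 0, insulin_intensity = 100)
  gt <- sample_islet_geometry(p)
  img <- render_if_image(gt, p)
  islet <- gt$islet_label_map > 0L
  expect_equal(mean(img$channels$insulin[gt$beta_mask]),
               p$insulin_intensity)
  expect_true(all(img$channels$synaptophysin[islet] ==
                    p$synaptophysin_intensity))
  # doubling the insulin intensity doubles the islet-pixel channel sum
  p2 <- update_params(p, insulin_intensity = 2 * p$insulin_intensity)
  img2 <- render_if_image(gt, p2)
  expect_equal(sum(img2$channels$insulin[islet]),
               2 * sum(img$channels$insulin[islet]))
})

test_that("all-zero intensities with no noise render all-zero channels", {
  p <- small_params(noise_free = TRUE, insulin_intensity = 0,
                    synaptophysin_intensity = 0, background_level = 0,
                    dapi_intensity = 0)
  gt <- sample_islet_geometry(p)
  img <- render_if_image(gt, p)
  for (ch in img$channels) expect_true(all(ch == 0))
})

test_that("rendered intensities clip to the bit depth, never wrap", {
  p <- small_params(insulin_intensity = 400, synaptophysin_intensity = 400,
                    dapi_intensity = 300, bit_depth = 8L)
  gt <- sample_islet_geometry(p)
  img <- render_if_image(gt, p)
  for (ch in img$channels) {
    expect_lte(max(ch), 255)
    expect_gte(min(ch), 0)
  }
  expect_true(any(img$channels$insulin == 255))
})

test_that("rendering is deterministic under a fixed seed", {
  p <- small_params(seed = 9L)
  gt <- sample_islet_geometry(p)
  expect_identical(render_if_image(gt, p), render_if_image(gt, p))
})
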