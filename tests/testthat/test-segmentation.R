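test_that("a uniformly zero image raises the no-tissue condition", {
  z <- matrix(0, 64, 64)
  img <- make_image(z, z, z)
  expect_error(compute_tissue_mask(img), class = "isletquant_no_tissue")
})

test_that("noise-free tissue mask covers the ground truth at IoU >= 0.98", {
  for (s in 1:3) {
    p <- medium_params(noise_free = TRUE, seed = s)
    gt <- sample_islet_geometry(p)
    img <- render_if_image(gt, p)
    tissue <- compute_tissue_mask(img)
    expect_true(all(tissue | !gt$tissue_mask))  # superset of truth
    expect_gte(mask_iou(tissue, gt$tissue_mask), 0.98)
  }
})

test_that("triangle tissue threshold is invariant to a small offset", {
  p <- medium_params(noise_free = TRUE, seed = 2L)
  gt <- sample_islet_geometry(p)
  img <- render_if_image(gt, p)
  shifted <- img
  shifted$channels <- lapply(img$channels, function(ch) ch + 3)
  expect_identical(compute_tissue_mask(img), compute_tissue_mask(shifted))
})

test_that("noise-free islet area fraction is recovered within 0.05 pp", {
  for (s in 1:3) {
    p <- medium_params(noise_free = TRUE, seed = s)
    gt <- sample_islet_geometry(p)
    img <- render_if_image(gt, p)
    masks <- segment_image(img)
    est <- area_fraction(masks$islet, masks$tissue)
    expect_lt(abs(est - gt$true_islet_fraction), 0.05)
  }
})

test_that("islet masks at default noise overlap truth at IoU >= 0.9", {
  for (s in 1:3) {
    p <- medium_params(seed = s)
    gt <- sample_islet_geometry(p)
    img <- render_if_image(gt, p)
    masks <- segment_image(img)
    expect_gte(mask_iou(masks$islet, gt$islet_label_map > 0), 0.9)
  }
})

test_that("a synaptophysin channel at pure background yields no islets", {
  p <- medium_params(islet_area_fraction_target = 0, seed = 3L)
  gt <- sample_islet_geometry(p)
  img <- render_if_image(gt, p)
  tissue <- compute_tissue_mask(img)
  islet <- compute_islet_mask(img, tissue)
  expect_false(any(islet))
})

test_that("insulin mask logic: null channel, nesting, flagged empty islet", {
  p <- medium_params(seed = 4L)
  gt <- sample_islet_geometry(p)
  img <- render_if_image(gt, p)
  masks <- segment_image(img)
  expect_true(all(!masks$insulin_positive | masks$islet))
  expect_true(all(!masks$islet | masks$tissue))

  img0 <- img
  img0$channels$insulin <- matrix(0, nrow(masks$islet), ncol(masks$islet))
  expect_false(any(compute_insulin_mask(img0, masks$islet)))

  empty <- matrix(FALSE, nrow(masks$islet), ncol(masks$islet))
  res <- compute_insulin_mask(img, empty)
  expect_false(any(res))
  expect_identical(attr(res, "flag"), "empty_islet_mask")
})

test_that("insulin threshold depends only on islet pixels", {
  p <- medium_params(noise_free = TRUE, seed = 5L)
  gt <- sample_islet_geometry(p)
  img <- render_if_image(gt, p)
  masks <- segment_image(img)
  scrambled <- img
  outside <- !masks$islet
  set.seed(1)
  vals <- scrambled$channels$insulin[outside]
  scrambled$channels$insulin[outside] <- sample(vals)
  expect_identical(compute_insulin_mask(scrambled, masks$islet),
                   compute_insulin_mask(img, masks$islet))
})

test_that("raising fixed thresholds always shrinks the masks", {
  p <- medium_params(seed = 6L)
  gt <- sample_islet_geometry(p)
  img <- render_if_image(gt, p)
  tissue <- compute_tissue_mask(img)
  prev <- NULL
  for (th in c(30, 60, 90, 110)) {
    cfg <- segmentation_config(islet_threshold_method = "fixed",
                               islet_threshold = th)
    m <- compute_islet_mask(img, tissue, cfg)
    if (!is.null(prev)) expect_true(all(!m | prev))
    prev <- m
  }
})

test_that("DAB mask thresholds OD monotonically and handles the zero tile", {
  p <- medium_params(seed = 7L)
  gt <- sample_islet_geometry(p)
  tile <- render_ihc_tile(gt, p)
  od <- deconvolve_ihc(tile)
  tissue <- gt$tissue_mask
  prev <- NULL
  for (th in c(0.2, 0.4, 0.6)) {
    cfg <- segmentation_config(dab_od_threshold = th)
    m <- compute_dab_mask(od$dab, tissue, cfg, pixel_size = p$pixel_size)
    expect_true(all(!m | tissue))
    if (!is.null(prev)) expect_true(all(!m | prev))
    prev <- m
  }
  zero <- matrix(0, nrow(tissue), ncol(tissue))
  expect_false(any(compute_dab_mask(zero, tissue,
                                    pixel_size = p$pixel_size)))
})

test_that("noise-free DAB-positive percentage matches the islet truth", {
  p <- medium_params(seed = 8L, islet_area_fraction_target = 0.008)
  p$ihc$noise_cv <- 0
  gt <- sample_islet_geometry(p)
  tile <- render_ihc_tile(gt, p)
  q <- quantify_ihc_tile(tile, pixel_size = p$pixel_size)
  expect_lt(abs(q$dab_area_pct_of_tissue - gt$true_islet_fraction), 0.1)
})
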