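test_that("area_fraction handles the boundary cases and hand count", {
  ref <- matrix(TRUE, 10, 10)
  none <- matrix(FALSE, 10, 10)
  expect_equal(area_fraction(none, ref), 0)
  expect_equal(area_fraction(ref, ref), 100)
  quarter <- none; quarter[1:5, 1:5] <- TRUE  # 25 of 100 pixels
  expect_equal(area_fraction(quarter, ref), 25)
  expect_error(area_fraction(quarter, none), "empty")
  expect_error(area_fraction(ref, quarter), "subset")
})

test_that("insulin statistics: constant, hand-computed, and scaled cases", {
  islet <- matrix(FALSE, 5, 5); islet[2:4, 2:4] <- TRUE
  vals <- matrix(0, 5, 5); vals[2:4, 2:4] <- matrix(1:9, 3, 3)
  img <- make_image(vals * 0, vals * 0, vals)
  res <- insulin_intensity_in_islets(img, islet)
  expect_equal(res$integrated, 45)  # sum(1..9)
  expect_equal(res$mean, 5)

  img_c <- make_image(vals * 0, vals * 0, islet * 7)
  res_c <- insulin_intensity_in_islets(img_c, islet)
  expect_equal(res_c$mean, 7)
  expect_equal(res_c$integrated, 7 * sum(islet))

  img_k <- make_image(vals * 0, vals * 0, vals * 3)
  res_k <- insulin_intensity_in_islets(img_k, islet)
  expect_equal(res_k$integrated, 3 * res$integrated)
  expect_equal(res_k$mean, 3 * res$mean)
})

test_that("an empty islet mask flags missing intensity, never silent zero", {
  img <- make_image(matrix(0, 4, 4), matrix(0, 4, 4), matrix(5, 4, 4))
  res <- insulin_intensity_in_islets(img, matrix(FALSE, 4, 4))
  expect_true(is.na(res$integrated))
  expect_true(is.na(res$mean))
  expect_identical(res$flag, "empty_islet_mask")
})

test_that("per-image metrics are deterministic and background-subtracted", {
  p <- small_params(seed = 11L)
  gt <- sample_islet_geometry(p)
  img <- render_if_image(gt, p)
  masks <- segment_image(img)
  a <- per_image_metrics(img, masks, "im")
  b <- per_image_metrics(img, masks, "im")
  expect_identical(a, b)
  expect_equal(a$insulin_mean_intensity_bgsub,
               a$insulin_mean_intensity - a$background_intensity)
  expect_gte(a$islet_area_pct_of_tissue, 0)
  expect_lte(a$insulin_pos_area_pct_of_islet, 100)
})

test_that("per-image metrics on an islet-free field report 0% and NAs", {
  p <- small_params(islet_area_fraction_target = 0, seed = 12L)
  gt <- sample_islet_geometry(p)
  img <- render_if_image(gt, p)
  masks <- segment_image(img)
  m <- per_image_metrics(img, masks, "empty")
  expect_equal(m$islet_area_pct_of_tissue, 0)
  expect_true(is.na(m$insulin_mean_intensity))
  expect_identical(m$flag, "empty_islet_mask")
})

test_that("per-animal aggregation weights by tissue area", {
  metrics <- data.frame(
    image_id = c("a1", "a2", "b1"),
    tissue_area = c(1, 3, 2),
    islet_area = c(0, 0.12, 0.05),
    islet_area_pct_of_tissue = c(0, 4, 2.5),
    insulin_pos_area_pct_of_islet = c(NA, 50, 40),
    insulin_integrated_intensity = c(NA, 10, 5),
    insulin_mean_intensity = c(NA, 2, 1),
    insulin_mean_intensity_bgsub = c(NA, 1.5, 0.8),
    background_intensity = c(0.5, 0.5, 0.2),
    flag = c("empty_islet_mask", NA, NA),
    stringsAsFactors = FALSE)
  manifest <- data.frame(image_id = c("a1", "a2", "b1"),
                         animal_id = c("A", "A", "B"),
                         group = c("g", "g", "h"),
                         stringsAsFactors = FALSE)
  out <- aggregate_per_animal(metrics, manifest)
  # weighted mean of 0 (w=1) and 4 (w=3) is 3.0
  expect_equal(out$islet_area_pct_of_tissue[out$animal_id == "A"], 3)
  # single-image animal aggregates to its own row
  expect_equal(out$islet_area_pct_of_tissue[out$animal_id == "B"], 2.5)
  expect_equal(out$n_images, c(2L, 1L))

  # shuffling row order leaves the table unchanged
  shuffled <- aggregate_per_animal(metrics[c(3, 1, 2), ],
                                   manifest[c(2, 3, 1), ])
  expect_equal(out, shuffled)
})

test_that("aggregation errors on unmapped rows and islet-free animals", {
  metrics <- data.frame(
    image_id = "x1", tissue_area = 1, islet_area = 0,
    islet_area_pct_of_tissue = 0,
    insulin_pos_area_pct_of_islet = NA_real_,
    insulin_integrated_intensity = NA_real_,
    insulin_mean_intensity = NA_real_,
    insulin_mean_intensity_bgsub = NA_real_,
    background_intensity = 1, flag = "empty_islet_mask",
    stringsAsFactors = FALSE)
  manifest <- data.frame(image_id = c("x1", "y1"),
                         animal_id = c("X", "Y"), group = "g",
                         stringsAsFactors = FALSE)
  expect_error(aggregate_per_animal(metrics, manifest), "zero analysable")
  expect_error(
    aggregate_per_animal(transform(metrics, image_id = "zz"),
                         manifest[1, ]), "no manifest entry")
  expect_warning(aggregate_per_animal(metrics, manifest[1, ]),
                 "without detectable islets")
})
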