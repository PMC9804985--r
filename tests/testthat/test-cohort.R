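test_that("cohort specs validate their group structure", {
  expect_error(cohort_spec(list(list(name = "a", n_animals = 2L))),
               "control")
  expect_error(cohort_spec(list(
    list(name = "a", n_animals = 1L, control = TRUE),
    list(name = "b", n_animals = 2L))), "n_animals >= 2")
})

test_that("a 2-group x 2-animal x 3-image cohort writes 12 manifest rows", {
  out <- withr::local_tempdir()
  spec <- two_group_spec(n_animals = 2L, images_per_animal = 3L)
  man <- generate_cohort(spec, out)
  expect_equal(nrow(man), 12L)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  expect_true(file.exists(file.path(out, "ground_truth.csv")))
  expect_true(all(file.exists(paste0(man$image_path, "_syn.tif"))))
  gt <- read.csv(file.path(out, "ground_truth.csv"))
  expect_equal(nrow(gt), 12L)
  expect_identical(attr(man, "control_group"), "non_diabetic")
})

test_that("regenerating with the same master seed is byte-identical", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  spec <- two_group_spec(n_animals = 2L, images_per_animal = 2L)
  generate_cohort(spec, out1)
  generate_cohort(spec, out2)
  for (f in c("ground_truth.csv")) {
    expect_identical(readBin(file.path(out1, f), "raw", 1e6),
                     readBin(file.path(out2, f), "raw", 1e6))
  }
  a <- list.files(out1, pattern = "_syn.tif$", full.names = TRUE)[1]
  b <- file.path(out2, basename(a))
  expect_identical(readBin(a, "raw", 1e7), readBin(b, "raw", 1e7))
})

test_that("appending a group never perturbs previously generated animals", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  base <- generator_params(image_shape = c(256L, 256L), pixel_size = 2)
  g1 <- list(name = "non_diabetic", n_animals = 2L, control = TRUE)
  g2 <- list(name = "diabetic", n_animals = 2L, control = FALSE)
  g3 <- list(name = "extra", n_animals = 2L, control = FALSE)
  generate_cohort(cohort_spec(list(g1, g2), images_per_animal = 1L,
                              base_params = base, master_seed = 3L), out1)
  generate_cohort(cohort_spec(list(g1, g2, g3), images_per_animal = 1L,
                              base_params = base, master_seed = 3L), out2)
  t1 <- read.csv(file.path(out1, "ground_truth.csv"))
  t2 <- read.csv(file.path(out2, "ground_truth.csv"))
  shared <- t2[t2$group %in% c("non_diabetic", "diabetic"), ]
  rownames(shared) <- NULL
  expect_equal(t1, shared)
})

test_that("control-group mean true islet fraction tracks the 0.8% target", {
  out <- withr::local_tempdir()
  base <- generator_params(image_shape = c(256L, 256L), pixel_size = 2)
  spec <- cohort_spec(
    groups = list(
      list(name = "control", n_animals = 10L, control = TRUE,
           params = list(islet_area_fraction_target = 0.008)),
      list(name = "other", n_animals = 2L, control = FALSE,
           params = list(islet_area_fraction_target = 0.008))),
    images_per_animal = 1L, base_params = base, master_seed = 17L)
  man <- generate_cohort(spec, out)
  gt <- read.csv(file.path(out, "ground_truth.csv"))
  per_animal <- tapply(gt$true_islet_fraction[gt$group == "control"],
                       gt$animal_id[gt$group == "control"], mean)
  expect_gte(mean(per_animal), 0.6)
  expect_lte(mean(per_animal), 1.0)
})

test_that("metric-level simulation has the declared lognormal structure", {
  cm <- simulate_cohort_metrics(c(c0 = 0.8, c1 = 0.3),
                                c(c0 = 500L, c1 = 500L),
                                sdlog10 = 0.25, seed = 5L)
  expect_identical(cm, simulate_cohort_metrics(
    c(c0 = 0.8, c1 = 0.3), c(c0 = 500L, c1 = 500L),
    sdlog10 = 0.25, seed = 5L))
  lg <- log10(cm$value[cm$group == "c0"])
  expect_lt(abs(mean(lg) - log10(0.8)), 0.04)
  expect_lt(abs(sd(lg) - 0.25), 0.03)
  expect_identical(attr(cm, "control_group"), "c0")
})
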