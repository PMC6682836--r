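test_that("phantom generation is bit-exactly reproducible", {
  p <- phantom_params(n_spicules = 5, spicule_depth = 10, speckle_cv = 0.1,
                      margin_blur_sigma = 1.5, shadow_strength = 30, seed = 42)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  # a different seed changes the speckle but not the mask
  c <- generate_phantom(phantom_params(n_spicules = 5, spicule_depth = 10,
                                       speckle_cv = 0.1,
                                       margin_blur_sigma = 1.5,
                                       shadow_strength = 30, seed = 43))
  expect_identical(a$mask, c$mask)
  expect_false(identical(a$image, c$image))
})

test_that("a noiseless convex phantom has textbook feature values", {
  ph <- generate_phantom(phantom_params(seed = 1))
  fv <- extract_features(ph$image, ph$mask)
  expect_equal(unname(fv["num_peaks"]), 0)
  expect_lt(abs(fv["adch"]), 0.05)
  expect_lt(abs(fv["adee"] - 1), 0.05)
  expect_equal(unname(fv["entropy"]), 0)
  expect_equal(unname(fv["echogenicity"]), 120 - 50)
})

test_that("the mask is the noiseless generating shape", {
  p <- phantom_params(n_spicules = 6, spicule_depth = 12, speckle_cv = 0.1,
                      seed = 8)
  ph <- generate_phantom(p)
  # recount the radial-modulation rule by brute force
  n <- 0L
  for (r in seq_len(p$image_rows)) for (c in seq_len(p$image_cols)) {
    dr <- r - p$centre[1]; dc <- c - p$centre[2]
    phi <- atan2(dr, dc)
    base <- 1 / sqrt((cos(phi) / p$semi_axis_lateral)^2 +
                     (sin(phi) / p$semi_axis_depth)^2)
    bound <- base + p$spicule_depth / 2 * cos(p$n_spicules * phi)
    if (sqrt(dr^2 + dc^2) <= bound) n <- n + 1L
  }
  expect_equal(compute_size(ph$mask), n)
  # spicule count recovered from the mask alone
  prof <- compute_convex_profile(ph$mask)
  expect_equal(compute_margin_shape_features(prof, n)$num_peaks, 6L)
})

test_that("phantoms that leave the image are rejected", {
  expect_error(generate_phantom(phantom_params(centre = c(30, 128),
                                               semi_axis_depth = 40)),
               "phantom out of bounds")
  expect_error(generate_phantom(phantom_params(image_rows = 64, image_cols = 64,
                                               centre = c(32, 32),
                                               semi_axis_depth = 30,
                                               semi_axis_lateral = 40)),
               "phantom out of bounds")
})

test_that("cohort generation respects counts, labels, and the seed", {
  expect_identical(generate_dataset(0, 0), list())
  cases <- generate_dataset(6, 4, seed = 5)
  expect_length(cases, 10)
  expect_equal(sum(vapply(cases, function(x) x$label, "") == "benign"), 6)
  expect_equal(sum(vapply(cases, function(x) x$label, "") == "malignant"), 4)
  expect_equal(anyDuplicated(vapply(cases, function(x) x$lesion_id, "")), 0L)
  cases2 <- generate_dataset(6, 4, seed = 5)
  expect_identical(phantom_truth(cases), phantom_truth(cases2))
  expect_identical(cases[[3]]$image, cases2[[3]]$image)
  cases3 <- generate_dataset(6, 4, seed = 6)
  expect_false(identical(phantom_truth(cases), phantom_truth(cases3)))
  # class ranges drive the ground truth
  tr <- phantom_truth(cases)
  expect_true(all(tr$axis_ratio[tr$label == "benign"] <= 0.8 + 1e-9))
  expect_true(all(tr$axis_ratio[tr$label == "malignant"] >= 0.9 - 1e-9))
  expect_true(all(tr$n_spicules[tr$label == "malignant"] >= 4))
})

test_that("a phantom cohort round-trips through PNG files", {
  dir <- withr::local_tempdir()
  cases <- generate_dataset(2, 2, seed = 3)
  write_phantom_dataset(cases, dir)
  man <- load_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 4)
  img <- read_grey_image(man$image_path[1])
  msk <- read_mask(man$mask_path[1])
  expect_identical(img, cases[[1]]$image)
  expect_identical(msk, cases[[1]]$mask)
})
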