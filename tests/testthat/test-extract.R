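test_that("the feature vector equals the per-feature operations", {
  ph <- generate_phantom(phantom_params(n_spicules = 5, spicule_depth = 10,
                                        speckle_cv = 0.08,
                                        margin_blur_sigma = 1, seed = 9))
  cfg <- feature_config()
  fv <- extract_features(ph$image, ph$mask, cfg)
  expect_named(fv, feature_names())
  expect_equal(unname(fv["adee"]), compute_adee(ph$mask)$adee)
  expect_equal(unname(fv["orientation"]), compute_orientation(ph$mask))
  band <- compute_margin_band(ph$image, ph$mask, cfg$band_halfwidth)
  expect_equal(unname(fv["avg_diff"]), compute_avg_diff(band))
  prof <- compute_convex_profile(ph$mask)
  msf <- compute_margin_shape_features(prof, compute_size(ph$mask),
                                       cfg$peak_prominence)
  expect_equal(unname(fv["num_peaks"]), as.numeric(msf$num_peaks))
  expect_equal(unname(fv["avg_distance"]), msf$avg_distance)
  expect_equal(unname(fv["adch"]), msf$adch)
  st <- compute_region_stats(ph$image, ph$mask, cfg$surround_scale)
  expect_equal(unname(fv["echogenicity"]), compute_echogenicity(st))
  expect_equal(unname(fv["shadow"]), compute_shadow(st))
  expect_equal(unname(fv["entropy"]), compute_entropy(ph$image, ph$mask)$entropy)
  expect_equal(unname(fv["size"]), as.numeric(compute_size(ph$mask)))
})

test_that("extraction is deterministic", {
  ph <- generate_phantom(phantom_params(n_spicules = 4, spicule_depth = 9,
                                        speckle_cv = 0.1, seed = 3))
  expect_identical(extract_features(ph$image, ph$mask),
                   extract_features(ph$image, ph$mask))
})

test_that("all ten features are translation invariant", {
  base <- generate_phantom(phantom_params(image_rows = 200, image_cols = 200,
                                          centre = c(85, 90),
                                          semi_axis_depth = 26,
                                          semi_axis_lateral = 32,
                                          n_spicules = 4, spicule_depth = 9,
                                          speckle_cv = 0.08, seed = 11))
  dr <- 6L; dc <- 9L
  shift <- function(m, fill) {
    out <- matrix(fill, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  img2 <- shift(base$image, base$image[1, 1])
  mask2 <- shift(base$mask, FALSE)
  fv1 <- extract_features(base$image, base$mask)
  fv2 <- extract_features(img2, mask2)
  expect_equal(fv2, fv1, tolerance = 1e-12)
})

test_that("sub-operation failures carry the feature name", {
  # lesion touching the bottom edge: no posterior region
  img <- matrix(100, 100, 150)
  mask <- mask_rect(100, 150, 40, 100, 40, 110)
  expect_error(extract_features(img, mask), "echogenicity/shadow")
  # lesion smaller than the margin band
  expect_error(extract_features(matrix(100, 80, 80),
                                mask_disc(80, 80, 40, 40, 8)),
               "avg_diff")
})
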