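test_that("equivalent-ellipse raster of an elliptical mask reproduces it", {
  ph <- generate_phantom(phantom_params(seed = 2))
  res <- compute_adee(ph$mask)
  expect_lt(abs(res$adee - 1), 0.05)
  # a mask equal to its own equivalent-ellipse raster has ADEE ~ 1
  raster <- res$ellipse$raster
  expect_lt(abs(compute_adee(raster)$adee - 1), 0.05)
  expect_gte(res$ellipse$semi_major, res$ellipse$semi_minor)
})

test_that("ADEE matches the brute-force pixel-count oracle", {
  rect <- mask_rect(64, 64, 10, 49, 15, 34)
  expect_equal(compute_adee(rect)$adee, oracle_adee(rect)$adee)
  for (mask in oracle_mask_pool()[c(2, 5, 7, 13)]) {
    res <- compute_adee(mask)
    orc <- oracle_adee(mask)
    expect_equal(sum(res$ellipse$raster), orc$a_e)
    expect_equal(sum(res$ellipse$raster & mask), orc$a_int)
    expect_equal(res$adee, orc$adee)
  }
})

test_that("ADEE grows with shape irregularity and never drops below 1", {
  star <- mask_star(64, 64, 32, 32, 12, 6, 10)
  disc <- mask_disc(64, 64, 32, 32, 12)
  expect_gt(compute_adee(star)$adee, compute_adee(disc)$adee)
  for (mask in oracle_mask_pool()) {
    expect_gte(compute_adee(mask)$adee, 1 - 0.05)
  }
})

test_that("orientation is the bounding-box height/width ratio", {
  expect_equal(compute_orientation(mask_rect(40, 40, 5, 20, 5, 20)), 1.0)
  expect_equal(compute_orientation(mask_rect(40, 40, 3, 32, 5, 19)), 2.0)
  expect_equal(compute_orientation(mask_rect(40, 40, 5, 19, 3, 32)), 0.5)
  # transposition inverts the ratio exactly
  for (mask in oracle_mask_pool()[c(1, 8, 15)]) {
    expect_identical(compute_orientation(t(mask)),
                     1 / compute_orientation(mask))
  }
})

test_that("degenerate shapes are rejected", {
  row_mask <- matrix(FALSE, 10, 10); row_mask[5, 2:9] <- TRUE
  expect_error(compute_adee(row_mask), "degenerate")
  expect_error(compute_convex_profile(row_mask), "degenerate")
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_error(compute_adee(one), "degenerate")
})

test_that("convex masks yield a flat hull profile", {
  rect <- mask_rect(50, 50, 10, 35, 12, 40)
  prof <- compute_convex_profile(rect)
  expect_true(all(prof$v_convex <= 1 + 1e-9))
  msf <- compute_margin_shape_features(prof, compute_size(rect))
  expect_equal(msf$num_peaks, 0L)
  expect_lt(msf$avg_distance, 1)
  expect_lt(abs(msf$adch), 0.05)
})

test_that("hull area dominates mask area and matches the counting oracle", {
  for (mask in oracle_mask_pool()) {
    prof <- compute_convex_profile(mask)
    expect_gte(prof$hull_area, sum(mask))
    expect_equal(prof$hull_area, oracle_hull_area(mask))
  }
})

test_that("spiculated shapes yield one profile peak per spicule valley", {
  star5 <- mask_star(64, 64, 32, 32, 12, 5, 10)
  prof <- compute_convex_profile(star5)
  msf <- compute_margin_shape_features(prof, compute_size(star5))
  expect_equal(msf$num_peaks, 5L)
  expect_gt(msf$avg_distance, 1)
  expect_gt(msf$adch, 0.05)
})

test_that("circular peak counting honours prominence and plateaus", {
  fake_profile <- function(v) list(v_convex = v, hull_area = 10)
  # hand-enumerated: peaks at 3 and 5, average 8/5
  msf <- compute_margin_shape_features(fake_profile(c(0, 3, 0, 5, 0)), 10)
  expect_equal(msf$num_peaks, 2L)
  expect_equal(msf$avg_distance, 1.6)
  expect_equal(msf$adch, 0)
  # plateau counted once
  expect_equal(compute_margin_shape_features(
    fake_profile(c(0, 4, 4, 4, 0, 0)), 10)$num_peaks, 1L)
  # sub-prominence ripple suppressed
  expect_equal(compute_margin_shape_features(
    fake_profile(c(0, 1, 0.5, 1, 0, 5, 0)), 10)$num_peaks, 1L)
  # constant profile: no peaks
  expect_equal(compute_margin_shape_features(
    fake_profile(rep(2, 8)), 10)$num_peaks, 0L)
  # wrap-around plateau across the circular seam counted once
  expect_equal(compute_margin_shape_features(
    fake_profile(c(4, 0, 0, 0, 4)), 10)$num_peaks, 1L)
  expect_error(compute_margin_shape_features(fake_profile(numeric(0)), 10),
               "degenerate profile")
})
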