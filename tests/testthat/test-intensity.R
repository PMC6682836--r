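test_that("regional means on constant and two-level images are exact", {
  img <- matrix(77, 100, 100)
  mask <- mask_rect(100, 100, 30, 49, 40, 59)
  st <- compute_region_stats(img, mask)
  expect_equal(st$mean_tumour, 77)
  expect_equal(st$mean_surrounding, 77)
  expect_equal(st$mean_posterior, 77)

  img2 <- matrix(90, 100, 100)
  img2[mask] <- 30
  st2 <- compute_region_stats(img2, mask)
  expect_equal(st2$mean_tumour, 30)
  expect_equal(st2$mean_surrounding, 90)
  expect_equal(st2$mean_posterior, 90)
})

test_that("the posterior rectangle is clipped at the bottom edge", {
  # bounding box of 10 rows ending 4 rows above the image bottom
  mask <- mask_rect(40, 60, 27, 36, 20, 34)
  st <- compute_region_stats(matrix(50, 40, 60), mask)
  expect_equal(unname(st$posterior_rect["r1"] - st$posterior_rect["r0"]), 4)
  expect_equal(st$n_posterior, 4L * 15L)
  # lesion touching the bottom edge has no posterior region
  expect_error(
    compute_region_stats(matrix(50, 40, 60), mask_rect(40, 60, 31, 40, 20, 34)),
    "no posterior region")
})

test_that("echogenicity and shadow are signed regional contrasts", {
  img <- matrix(90, 100, 100)
  mask <- mask_rect(100, 100, 30, 49, 40, 59)
  img[mask] <- 30
  st <- compute_region_stats(img, mask)
  expect_equal(compute_echogenicity(st), 60)
  expect_equal(compute_shadow(st), 60)
  # swapping the two intensities flips the sign
  img_sw <- matrix(30, 100, 100)
  img_sw[mask] <- 90
  st_sw <- compute_region_stats(img_sw, mask)
  expect_equal(compute_echogenicity(st_sw), -60)
  expect_equal(compute_shadow(st_sw), -60)
  # darker posterior region flags a shadow
  img_sh <- matrix(90, 100, 100)
  img_sh[mask] <- 50
  img_sh[50:100, ] <- 20
  expect_lt(compute_shadow(compute_region_stats(img_sh, mask)), 0)
})

test_that("surrounding/posterior pixel counts match the counting oracle", {
  img <- matrix(10, 64, 64)
  for (mask in oracle_mask_pool()[c(1, 4, 9, 14)]) {
    st <- compute_region_stats(img, mask)
    orc <- oracle_region_counts(mask)
    expect_equal(st$n_surrounding, orc$n_surr)
    expect_equal(st$n_posterior, orc$n_post)
  }
})

test_that("difference entropy behaves like an information measure", {
  mask <- mask_rect(20, 20, 5, 12, 5, 12)
  # constant interior: a single difference value, zero bits
  expect_equal(compute_entropy(matrix(42, 20, 20), mask)$entropy, 0)
  # even two-value checkerboard: differences split evenly, one bit
  img <- matrix(0, 20, 20)
  img[] <- (row(img) + col(img)) %% 2 * 10 + 100
  res <- compute_entropy(img, mask)
  expect_equal(res$entropy, 1.0)
  expect_equal(sum(res$hist), 1.0)
  # bounded by the log of the difference alphabet
  set.seed(5)
  img_r <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  res_r <- compute_entropy(img_r, mask)
  expect_lte(res_r$entropy, log2(length(res_r$hist)))
  # invariant under a constant intensity shift
  shifted <- img_r - min(img_r)
  expect_equal(compute_entropy(shifted, mask)$entropy, res_r$entropy)
  # a 1-pixel mask has no interior pair
  one <- matrix(FALSE, 20, 20); one[5, 5] <- TRUE
  expect_error(compute_entropy(img, one), "lesion too small for entropy")
})

test_that("size is the true-pixel count", {
  one <- matrix(FALSE, 9, 9); one[4, 5] <- TRUE
  expect_equal(compute_size(one), 1L)
  expect_equal(compute_size(mask_rect(30, 30, 6, 25, 11, 20)), 200L)
  disc <- mask_disc(40, 40, 20, 20, 10)
  n <- 0L
  for (r in 1:40) for (c in 1:40)
    if ((r - 20)^2 + (c - 20)^2 <= 100) n <- n + 1L
  expect_equal(compute_size(disc), n)
})
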