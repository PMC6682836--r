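# Intensity features: regional means, echogenicity, shadow, entropy, size.

#' Regional intensity statistics around a lesion
#'
#' Computes the three regional mean intensities used by the echo-pattern and
#' posterior-feature descriptors:
#' * `mean_tumour` over the lesion pixels;
#' * `mean_surrounding` over a rectangle concentric with the lesion
#'   bounding box and `surround_scale` times its height and width, excluding
#'   lesion pixels and the posterior rectangle (the geometric shadow proxy);
#' * `mean_posterior` over the rectangle directly below the bounding box
#'   (same columns, same height, clipped at the bottom edge).
#'
#' @inheritParams compute_margin_band
#' @param surround_scale Linear scale of the surrounding rectangle relative
#'   to the lesion bounding box.
#' @return Object of class `region_stats`: list with `mean_tumour`,
#'   `mean_surrounding`, `mean_posterior`, the averaged pixel counts
#'   `n_surrounding`, `n_posterior`, and the two rectangles
#'   `surrounding_rect`, `posterior_rect` as `c(r0, r1, c0, c1)` (1-based,
#'   half-open on `r1`/`c1`).
#' @export
compute_region_stats <- function(image, mask, surround_scale = 2.0) {
  assert_image(image)
  assert_mask(mask, image)
  nr <- nrow(image); nc <- ncol(image)
  bb <- mask_bbox(mask)
  h <- bb$r1 - bb$r0 + 1L; w <- bb$c1 - bb$c0 + 1L
  cr <- (bb$r0 + bb$r1) / 2; cc <- (bb$c0 + bb$c1) / 2
  sr0 <- max(1L, ceiling(cr - surround_scale * h / 2))
  sr1 <- min(nr, floor(cr + surround_scale * h / 2))
  sc0 <- max(1L, ceiling(cc - surround_scale * w / 2))
  sc1 <- min(nc, floor(cc + surround_scale * w / 2))
  pr0 <- bb$r1 + 1L
  pr1 <- min(nr, bb$r1 + h)
  if (pr0 > nr)
    stop("no posterior region: lesion touches the bottom edge", call. = FALSE)
  post_sel <- matrix(FALSE, nr, nc)
  post_sel[pr0:pr1, bb$c0:bb$c1] <- TRUE
  surr_sel <- matrix(FALSE, nr, nc)
  surr_sel[sr0:sr1, sc0:sc1] <- TRUE
  surr_sel <- surr_sel & !mask & !post_sel
  if (!any(surr_sel))
    stop("no surrounding region: nothing left after exclusions", call. = FALSE)
  structure(list(mean_tumour = mean(image[mask]),
                 mean_surrounding = mean(image[surr_sel]),
                 mean_posterior = mean(image[post_sel]),
                 n_surrounding = sum(surr_sel),
                 n_posterior = sum(post_sel),
                 surrounding_rect = c(r0 = sr0, r1 = sr1 + 1L,
                                      c0 = sc0, c1 = sc1 + 1L),
                 posterior_rect = c(r0 = pr0, r1 = pr1 + 1L,
                                    c0 = bb$c0, c1 = bb$c1 + 1L)),
            class = "region_stats")
}

#' Echogenicity (surrounding minus tumour mean intensity)
#'
#' \deqn{Echogenicity = \bar I_{surrounding} - \bar I_{tumour}.}
#' Computed exactly as printed; note that with this sign a hypoechoic
#' (darker-than-surroundings) lesion yields a positive value.
#'
#' @param stats Result of [compute_region_stats()].
#' @return Signed scalar, intensity units.
#' @export
compute_echogenicity <- function(stats) {
  stats$mean_surrounding - stats$mean_tumour
}

#' Posterior acoustic shadow indicator
#'
#' \deqn{Shadow = \bar I_{post} - \bar I_{tumour}.}
#' A negative difference indicates the presence of posterior shadowing
#' (dark region beneath the lesion); a positive difference its absence.
#'
#' @inheritParams compute_echogenicity
#' @return Signed scalar, intensity units.
#' @export
compute_shadow <- function(stats) {
  stats$mean_posterior - stats$mean_tumour
}

#' Intensity-difference entropy of the lesion interior
#'
#' Texture-heterogeneity feature.  All 4-neighbour pixel pairs fully inside
#' the mask contribute a signed intensity difference (right minus left, down
#' minus up); with \eqn{P_i} the empirical probability of difference value
#' \eqn{i},
#' \deqn{Entropy = -\sum_i P_i \log_2 P_i}
#' in bits, with \eqn{0 \log 0 \equiv 0}.  A constant interior gives 0; a
#' heterogeneous echo pattern gives large values.
#'
#' @inheritParams compute_margin_band
#' @return List with `entropy` (bits) and `hist` (named numeric vector of
#'   difference probabilities; names are the signed difference values).
#' @export
compute_entropy <- function(image, mask) {
  assert_image(image)
  assert_mask(mask, image)
  nr <- nrow(mask); nc <- ncol(mask)
  diffs <- numeric(0)
  if (nc >= 2L) {
    both <- mask[, -nc, drop = FALSE] & mask[, -1L, drop = FALSE]
    d <- image[, -1L, drop = FALSE] - image[, -nc, drop = FALSE]
    diffs <- c(diffs, d[both])
  }
  if (nr >= 2L) {
    both <- mask[-nr, , drop = FALSE] & mask[-1L, , drop = FALSE]
    d <- image[-1L, , drop = FALSE] - image[-nr, , drop = FALSE]
    diffs <- c(diffs, d[both])
  }
  if (length(diffs) == 0L)
    stop("lesion too small for entropy: no interior adjacent pixel pair",
         call. = FALSE)
  tab <- table(diffs)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  list(entropy = -sum(p * log2(p)), hist = p)
}

#' Lesion size in pixels
#'
#' The number of pixels within the lesion contour, i.e. the count of true
#' mask pixels.
#'
#' @inheritParams equivalent_ellipse
#' @return Integer pixel count.
#' @export
compute_size <- function(mask) {
  assert_mask(mask)
  sum(mask)
}
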