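# Margin sharpness: intensity difference profile across the lesion boundary.

#' Margin band and intensity difference vector
#'
#' Quantifies margin (in)distinctness.  The lesion mask is dilated and
#' eroded by a disk of radius `band_halfwidth`, giving an outside and an
#' inside contour running parallel to the lesion boundary.  Each outside
#' contour pixel `i` is paired with its nearest inside contour pixel `j`
#' (Euclidean distance, ties broken by smallest (row, col)); the straight
#' segment from `i` to `j` is rasterized and
#' \deqn{Diff(i) = \bar I_{out}(i) - \bar I_{in}(j),}
#' the mean intensity of the outer half of the segment minus the mean of
#' the inner half (the middle pixel of an odd-length segment joins the
#' inner half).  Segments leaving the image are dropped.
#'
#' @param image Numeric matrix of intensities in \[0, 255\].
#' @param mask Logical lesion mask, same dimensions as `image`.
#' @param band_halfwidth Band half-width in pixels (disk radius for the
#'   morphological offset contours).
#' @return Object of class `margin_band`: list with `outer_contour` and
#'   `inner_contour` (ordered (row, col) chains; outside-contour pixels may
#'   lie outside the image and are reported in the image frame), `diff`
#'   (numeric vector of valid intensity differences), `n_valid`, and
#'   `band_halfwidth`.
#' @export
compute_margin_band <- function(image, mask, band_halfwidth = 20) {
  assert_image(image)
  assert_mask(mask, image)
  if (band_halfwidth <= 0) stop("band_halfwidth must be > 0", call. = FALSE)
  bh <- as.integer(round(band_halfwidth))
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- bh + 2L
  padded <- matrix(FALSE, nr + 2L * pad, nc + 2L * pad)
  padded[pad + seq_len(nr), pad + seq_len(nc)] <- mask
  brush <- EBImage::makeBrush(2L * bh + 1L, shape = "disc")
  dil <- EBImage::dilate(padded, brush) > 0
  ero <- EBImage::erode(padded, brush) > 0
  if (!any(ero))
    stop("lesion too small for band: erosion emptied the mask", call. = FALSE)
  if (!is_single_region(ero))
    stop("lesion too small for band: erosion disconnected the mask",
         call. = FALSE)
  outer_chain <- trace_contour(dil)
  inner_chain <- trace_contour(ero)
  inner_pts <- unique(inner_chain)
  # order ties by (row, col) so which.min picks the smallest pair
  o <- order(inner_pts[, 1L], inner_pts[, 2L])
  inner_pts <- inner_pts[o, , drop = FALSE]
  d2 <- outer(outer_chain[, 1L], inner_pts[, 1L], "-")^2 +
        outer(outer_chain[, 2L], inner_pts[, 2L], "-")^2
  nearest <- apply(d2, 1L, which.min)
  diffs <- rep(NA_real_, nrow(outer_chain))
  for (i in seq_len(nrow(outer_chain))) {
    j <- nearest[i]
    seg <- line_pixels(outer_chain[i, 1L], outer_chain[i, 2L],
                       inner_pts[j, 1L], inner_pts[j, 2L])
    # back to image coordinates; drop segments that exit the image
    sr <- seg[, 1L] - pad; sc <- seg[, 2L] - pad
    if (any(sr < 1L | sr > nr | sc < 1L | sc > nc)) next
    len <- length(sr)
    if (len < 2L) next
    n_out <- len %/% 2L  # middle pixel of an odd segment joins the inner half
    vals <- image[cbind(sr, sc)]
    diffs[i] <- mean(vals[seq_len(n_out)]) - mean(vals[(n_out + 1L):len])
  }
  valid <- !is.na(diffs)
  if (!any(valid))
    stop("band outside image: no margin segment fits the image", call. = FALSE)
  structure(list(outer_contour = cbind(row = outer_chain[, 1L] - pad,
                                       col = outer_chain[, 2L] - pad),
                 inner_contour = cbind(row = inner_chain[, 1L] - pad,
                                       col = inner_chain[, 2L] - pad),
                 diff = diffs[valid],
                 n_valid = sum(valid),
                 band_halfwidth = bh),
            class = "margin_band")
}

#' Average margin intensity difference (AvgDiff)
#'
#' Mean of the valid entries of the margin-band difference vector.  Large
#' positive values indicate a sharp demarcation between a (hypoechoic)
#' lesion and brighter surrounding tissue; values near zero indicate an
#' indistinct margin.
#'
#' @param band Result of [compute_margin_band()].
#' @return Scalar, intensity units.
#' @export
compute_avg_diff <- function(band) {
  if (is.null(band$n_valid) || band$n_valid < 1L)
    stop("band outside image: no valid margin segments", call. = FALSE)
  mean(band$diff)
}
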