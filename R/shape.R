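# Shape descriptors: equivalent ellipse, orientation, convex-hull profile.

#' Equivalent ellipse of a lesion mask
#'
#' The ellipse sharing the centroid and second central moments of the mask's
#' true-pixel set (the standard image-moments construction).  Semi-axis
#' lengths are \eqn{2\sqrt{\lambda}} for the eigenvalues \eqn{\lambda} of the
#' pixel-coordinate covariance matrix, which reproduces a filled ellipse's
#' own axes.  The ellipse is rasterized by pixel-centre inclusion on the
#' mask's grid.
#'
#' @param mask Logical matrix (one 8-connected region of `TRUE` pixels).
#' @return List with `centre` (row, col), `semi_major`, `semi_minor`
#'   (pixels), `angle` (radians, major axis vs. the column axis, Cartesian
#'   y-up convention), and `raster` (logical matrix, same dimensions as
#'   `mask`).
#' @export
equivalent_ellipse <- function(mask) {
  assert_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1L]; c <- idx[, 2L]
  mr <- mean(r); mc <- mean(c)
  n <- length(r)
  # covariance in (x = col, y = row) axes
  vxx <- sum((c - mc)^2) / n
  vyy <- sum((r - mr)^2) / n
  vxy <- sum((c - mc) * (r - mr)) / n
  e <- eigen(matrix(c(vxx, vxy, vxy, vyy), 2L, 2L), symmetric = TRUE)
  if (e$values[2L] <= 1e-12)
    stop("degenerate shape: mask pixels are collinear", call. = FALSE)
  a <- 2 * sqrt(e$values[1L])  # semi-major
  b <- 2 * sqrt(e$values[2L])  # semi-minor
  ang <- atan2(e$vectors[2L, 1L], e$vectors[1L, 1L])
  nr <- nrow(mask); nc <- ncol(mask)
  dx <- matrix(rep(seq_len(nc), each = nr), nr, nc) - mc
  dy <- matrix(rep(seq_len(nr), times = nc), nr, nc) - mr
  u <- dx * cos(ang) + dy * sin(ang)
  v <- -dx * sin(ang) + dy * cos(ang)
  raster <- (u / a)^2 + (v / b)^2 <= 1
  list(centre = c(row = mr, col = mc), semi_major = a, semi_minor = b,
       angle = ang, raster = raster)
}

#' Area difference with the equivalent ellipse (ADEE)
#'
#' Shape-irregularity feature: the union of the lesion and its equivalent
#' ellipse, normalized by the lesion area,
#' \deqn{ADEE = (A_E + A_T - A_{E \cap T}) / A_T,}
#' where \eqn{A_E} is the ellipse raster pixel count, \eqn{A_T} the lesion
#' pixel count, and \eqn{A_{E \cap T}} their intersection.  A perfectly
#' elliptical lesion gives ADEE close to 1; the more irregular the shape,
#' the larger the value.
#'
#' @inheritParams equivalent_ellipse
#' @return List with `adee` (dimensionless, >= 1 up to rasterization
#'   tolerance) and `ellipse` (see [equivalent_ellipse()]).
#' @export
compute_adee <- function(mask) {
  ell <- equivalent_ellipse(mask)
  a_e <- sum(ell$raster)
  a_t <- sum(mask)
  a_int <- sum(ell$raster & mask)
  list(adee = (a_e + a_t - a_int) / a_t, ellipse = ell)
}

#' Lesion orientation (height / width)
#'
#' Ratio of the axis-aligned bounding-box row extent (depth direction; the
#' skin is at row 1) to its column extent.  Values above 1 encode a
#' taller-than-wide lesion, i.e. a long axis perpendicular to the skin
#' layer; values below 1 a wider-than-tall lesion.
#'
#' @inheritParams equivalent_ellipse
#' @return Positive scalar.
#' @export
compute_orientation <- function(mask) {
  assert_mask(mask)
  bb <- mask_bbox(mask)
  (bb$r1 - bb$r0 + 1) / (bb$c1 - bb$c0 + 1)
}

#' Convex-hull distance profile of a lesion
#'
#' Builds the convex hull of the lesion pixels, densifies its boundary to a
#' pixel chain, and records for every hull-chain pixel the Euclidean
#' distance to the nearest pixel of the lesion contour (the distance vector
#' \eqn{V_{convex}}).  Valleys of the lesion contour between spicules or
#' lobules appear as peaks of the profile.
#'
#' @inheritParams equivalent_ellipse
#' @return List with `hull_chain` (ordered (row, col) pixel chain of the
#'   hull boundary), `v_convex` (numeric distances, one per hull-chain
#'   pixel), and `hull_area` (pixel count inside the hull, always >= the
#'   mask area).
#' @export
compute_convex_profile <- function(mask) {
  assert_mask(mask)
  contour <- trace_contour(mask)
  cpts <- unique(contour)
  hull_idx <- grDevices::chull(cpts[, "col"], cpts[, "row"])
  verts <- cpts[hull_idx, , drop = FALSE]
  if (nrow(verts) < 3L)
    stop("degenerate shape: convex hull has no area", call. = FALSE)
  # densify hull edges to an 8-connected pixel chain
  chain <- NULL
  nv <- nrow(verts)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    seg <- line_pixels(verts[i, 1L], verts[i, 2L], verts[j, 1L], verts[j, 2L])
    chain <- rbind(chain, seg[-nrow(seg), , drop = FALSE])
  }
  colnames(chain) <- c("row", "col")
  # distances hull chain -> lesion contour (min over contour pixels)
  d2 <- outer(chain[, 1L], cpts[, 1L], "-")^2 +
        outer(chain[, 2L], cpts[, 2L], "-")^2
  v <- sqrt(apply(d2, 1L, min))
  # hull area: pixel centres inside (or on) the convex polygon
  hull_area <- sum(in_convex_polygon(verts, nrow(mask), ncol(mask)))
  list(hull_chain = chain, v_convex = v, hull_area = hull_area)
}

# Logical matrix of pixel centres inside or on the convex polygon `verts`
# ((row, col) vertices in hull order).
in_convex_polygon <- function(verts, nr, nc) {
  nv <- nrow(verts)
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  # orientation sign of the polygon
  area2 <- 0
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    area2 <- area2 + verts[i, 2L] * verts[j, 1L] - verts[j, 2L] * verts[i, 1L]
  }
  s <- if (area2 >= 0) 1 else -1
  inside <- matrix(TRUE, nr, nc)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    cross <- (verts[j, 2L] - verts[i, 2L]) * (y - verts[i, 1L]) -
             (verts[j, 1L] - verts[i, 1L]) * (x - verts[i, 2L])
    inside <- inside & (s * cross >= -1e-9)
  }
  inside
}

# Number of local maxima of a circular sequence, counting each plateau once
# and requiring topographic prominence >= `prominence`.
circular_peaks <- function(v, prominence = 2) {
  n <- length(v)
  if (n == 0L) stop("degenerate profile: empty distance vector", call. = FALSE)
  r <- rle(v)
  vals <- r$values
  m <- length(vals)
  if (m == 1L) return(0L)  # constant sequence: no peaks
  # merge circular wrap-around of equal first/last runs
  wrap <- vals[1L] == vals[m]
  if (wrap) {
    vals <- vals[-m]
    m <- m - 1L
    if (m == 1L) return(0L)
  }
  nxt <- function(i) if (i == m) 1L else i + 1L
  prv <- function(i) if (i == 1L) m else i - 1L
  vmax <- max(vals); vmin <- min(v)
  peaks <- 0L
  for (i in seq_len(m)) {
    if (vals[i] <= vals[prv(i)] || vals[i] <= vals[nxt(i)]) next
    h <- vals[i]
    if (h == vmax) {
      prom <- h - vmin
    } else {
      # walk each way until strictly higher ground; track the minimum
      min_l <- h; j <- prv(i)
      while (vals[j] <= h) { min_l <- min(min_l, vals[j]); j <- prv(j) }
      min_r <- h; j <- nxt(i)
      while (vals[j] <= h) { min_r <- min(min_r, vals[j]); j <- nxt(j) }
      prom <- h - max(min_l, min_r)
    }
    if (prom >= prominence) peaks <- peaks + 1L
  }
  peaks
}

#' Margin shape features from the convex-hull profile
#'
#' Summarizes the distance vector of [compute_convex_profile()] into the
#' three margin descriptors: `num_peaks`, the number of prominent local
#' maxima of the circular profile (spiculation/lobulation count);
#' `avg_distance`, its mean (overall deviation from convexity, pixels); and
#' `adch`, the relative area excess of the convex hull,
#' \eqn{(A_c - A_T)/A_T}.
#'
#' @param profile Result of [compute_convex_profile()].
#' @param mask_area Lesion pixel count \eqn{A_T} (see [compute_size()]).
#' @param peak_prominence Minimum topographic prominence (pixels) for a
#'   profile maximum to count as a peak; suppresses rasterization jitter.
#' @return List with `num_peaks` (integer), `avg_distance` (pixels), and
#'   `adch` (dimensionless, >= 0 up to rasterization tolerance).
#' @export
compute_margin_shape_features <- function(profile, mask_area,
                                          peak_prominence = 2.0) {
  if (length(profile$v_convex) == 0L)
    stop("degenerate profile: empty distance vector", call. = FALSE)
  if (mask_area < 1) stop("mask_area must be >= 1", call. = FALSE)
  list(num_peaks = circular_peaks(profile$v_convex, peak_prominence),
       avg_distance = mean(profile$v_convex),
       adch = (profile$hull_area - mask_area) / mask_area)
}
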