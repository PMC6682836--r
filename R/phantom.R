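# Synthetic B-mode-like lesion phantoms with known ground truth.

#' Phantom generating parameters
#'
#' Parameters of a synthetic lesion phantom.  The lesion shape is an ellipse
#' (semi-axes along the depth/row and lateral/column directions) whose
#' boundary radius is modulated by `n_spicules` cosine lobes of amplitude
#' `spicule_depth`.  The image fills the lesion with `tumour_mean`, the
#' background with `background_mean`, applies multiplicative speckle with
#' coefficient of variation `speckle_cv`, blurs the whole image with a
#' Gaussian of `margin_blur_sigma`, and darkens the rows below the lesion
#' (within its column span) by `shadow_strength`.
#'
#' @param image_rows,image_cols Image dimensions in pixels.
#' @param centre Lesion centre `c(row, col)`.
#' @param semi_axis_depth,semi_axis_lateral Ellipse semi-axes (pixels,
#'   both >= 3).
#' @param n_spicules Number of cosine spicule lobes (0 = smooth ellipse).
#' @param spicule_depth Radial lobe amplitude (pixels).
#' @param margin_blur_sigma Gaussian blur sigma (pixels; 0 = sharp margin).
#' @param tumour_mean,background_mean Mean intensities in \[0, 255\].
#' @param shadow_strength Intensity drop below the lesion (>= 0).
#' @param speckle_cv Speckle coefficient of variation (>= 0).
#' @param seed Integer seed making the speckle reproducible.
#' @return Object of class `phantom_params` (named list).
#' @export
phantom_params <- function(image_rows = 256, image_cols = 256,
                           centre = c(110, 128),
                           semi_axis_depth = 30, semi_axis_lateral = 45,
                           n_spicules = 0, spicule_depth = 0,
                           margin_blur_sigma = 0,
                           tumour_mean = 50, background_mean = 120,
                           shadow_strength = 0, speckle_cv = 0, seed = 1) {
  stopifnot(image_rows >= 1, image_cols >= 1,
            semi_axis_depth >= 3, semi_axis_lateral >= 3,
            n_spicules >= 0, spicule_depth >= 0,
            margin_blur_sigma >= 0, shadow_strength >= 0, speckle_cv >= 0,
            tumour_mean >= 0, tumour_mean <= 255,
            background_mean >= 0, background_mean <= 255)
  structure(list(image_rows = as.integer(image_rows),
                 image_cols = as.integer(image_cols),
                 centre = as.numeric(centre),
                 semi_axis_depth = semi_axis_depth,
                 semi_axis_lateral = semi_axis_lateral,
                 n_spicules = as.integer(n_spicules),
                 spicule_depth = spicule_depth,
                 margin_blur_sigma = margin_blur_sigma,
                 tumour_mean = tumour_mean,
                 background_mean = background_mean,
                 shadow_strength = shadow_strength,
                 speckle_cv = speckle_cv,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Rasterize the noiseless phantom shape: pixel centres with polar radius
# below the modulated ellipse boundary radius.
phantom_shape <- function(params) {
  nr <- params$image_rows; nc <- params$image_cols
  r0 <- params$centre[1L]; c0 <- params$centre[2L]
  ad <- params$semi_axis_depth; al <- params$semi_axis_lateral
  dr <- matrix(rep(seq_len(nr), times = nc), nr, nc) - r0
  dc <- matrix(rep(seq_len(nc), each = nr), nr, nc) - c0
  dist <- sqrt(dr^2 + dc^2)
  phi <- atan2(dr, dc)
  base <- 1 / sqrt((cos(phi) / al)^2 + (sin(phi) / ad)^2)
  bound <- base
  if (params$n_spicules > 0L && params$spicule_depth > 0) {
    # symmetric modulation: tips protrude by half the spicule depth, valleys
    # are carved inward by the other half (peak-to-valley = spicule_depth)
    bound <- base +
      params$spicule_depth / 2 * cos(params$n_spicules * phi)
  }
  dist <= bound
}

#' Parameters of a well-resolved spiculated phantom
#'
#' Convenience constructor for phantoms whose hull-profile peak count is the
#' spicule count by construction.  The number of peaks of the convex-hull
#' distance profile equals the number of spicules only when the carved
#' valleys dominate the sag of the hull chord between adjacent tips;
#' otherwise the base ellipse itself supports the hull inside a gap and
#' splits it into several peaks.  On a near-circular base of radius
#' \eqn{R} with peak-to-valley depth \eqn{A} and tip spacing
#' \eqn{\theta = \pi/k} this clearance condition reads
#' \eqn{R \le (A/2)(1+\cos\theta)/(1-\cos\theta)}.  This constructor draws
#' the base radius at a safety fraction of that bound (with mild
#' ellipticity), so the ground-truth spicule count is geometrically
#' well-defined.
#'
#' @param n_spicules Spicule count (>= 1).
#' @param spicule_depth Peak-to-valley spicule depth in pixels.
#' @param axis_jitter Relative half-range of the random depth/lateral
#'   ellipticity around 1.
#' @param safety Fraction of the clearance bound used for the base radius.
#' @param seed Integer seed (drives the radius/ellipticity draw and the
#'   phantom speckle).
#' @param ... Passed on to [phantom_params()] (e.g. `speckle_cv`).
#' @return A [phantom_params()] object.
#' @export
spiculated_params <- function(n_spicules, spicule_depth = 12,
                              axis_jitter = 0.15, safety = 0.7, seed = 1,
                              ...) {
  stopifnot(n_spicules >= 1, spicule_depth > 0)
  th <- pi / n_spicules
  r_max <- spicule_depth / 2 * (1 + cos(th)) / (1 - cos(th))
  with_seed(seed, {
    r0 <- stats::runif(1, 0.6, 1) * safety * r_max
    r0 <- min(max(r0, 8), 45)
    ecc <- stats::runif(1, 1 - axis_jitter, 1 + axis_jitter)
    phantom_params(semi_axis_depth = max(3, r0 * ecc),
                   semi_axis_lateral = max(3, r0 / ecc),
                   n_spicules = n_spicules, spicule_depth = spicule_depth,
                   seed = seed, ...)
  })
}

#' Generate one lesion phantom
#'
#' Builds the noiseless ground-truth mask from the shape parameters and a
#' B-mode-like greyscale image on top of it (speckle, margin blur, posterior
#' shadow).  Bit-exactly reproducible from the parameters, including `seed`.
#'
#' @param params A [phantom_params()] object.
#' @return Object of class `phantom_case`: list with `image` (integer
#'   matrix, \[0, 255\]), `mask` (logical matrix, the noiseless shape),
#'   `params`, and `label` (`NA` until assigned by [generate_dataset()]).
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  mask <- phantom_shape(params)
  if (!any(mask)) stop("phantom out of bounds: empty shape", call. = FALSE)
  nr <- params$image_rows; nc <- params$image_cols
  bb <- mask_bbox(mask)
  margin <- min(bb$r0 - 1L, nr - bb$r1, bb$c0 - 1L, nc - bb$c1)
  if (margin < 1L || bb$r1 >= nr)
    stop("phantom out of bounds: lesion touches the image border",
         call. = FALSE)
  img <- matrix(params$background_mean, nr, nc)
  img[mask] <- params$tumour_mean
  if (params$speckle_cv > 0) {
    shape <- 1 / params$speckle_cv^2
    noise <- with_seed(params$seed,
                       matrix(stats::rgamma(nr * nc, shape = shape,
                                            rate = shape), nr, nc))
    img <- img * noise
  }
  if (params$margin_blur_sigma > 0) {
    img <- EBImage::gblur(img, sigma = params$margin_blur_sigma)
  }
  if (params$shadow_strength > 0 && bb$r1 < nr) {
    rows <- (bb$r1 + 1L):nr
    img[rows, bb$c0:bb$c1] <- img[rows, bb$c0:bb$c1] - params$shadow_strength
  }
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), nr, nc)
  structure(list(image = img, mask = mask, params = params, label = NA_character_),
            class = "phantom_case")
}

#' Default phantom parameter ranges for the benign class
#'
#' Benign lesions emulate the classic sonographic profile: wider than tall
#' (depth/lateral axis ratio 0.4--0.8), smooth or singly-lobulated margin,
#' little or no posterior shadowing, moderately blurred but distinct margin.
#'
#' @return Named list of ranges consumed by [generate_dataset()].
#' @export
benign_ranges <- function() {
  list(orientation = c(0.4, 0.8), n_spicules = 0:1,
       spicule_depth = c(3, 6), shadow_strength = c(0, 10),
       semi_minor = c(25, 35), tumour_mean = c(40, 70),
       background_mean = c(110, 140), margin_blur_sigma = c(0.5, 1.5),
       speckle_cv = c(0.06, 0.1))
}

#' Default phantom parameter ranges for the malignant class
#'
#' Malignant lesions emulate the suspicious profile: taller than wide or
#' round (axis ratio 0.9--1.6), 4--9 deep spicules, marked posterior
#' shadowing, more indistinct (blurred) margins, darker echo pattern.
#'
#' @return Named list of ranges consumed by [generate_dataset()].
#' @export
malignant_ranges <- function() {
  list(orientation = c(0.9, 1.6), n_spicules = 4:9,
       spicule_depth = c(8, 16), shadow_strength = c(20, 60),
       semi_minor = c(32, 42), tumour_mean = c(30, 60),
       background_mean = c(110, 140), margin_blur_sigma = c(2, 4),
       speckle_cv = c(0.06, 0.1))
}

# Draw one phantom_params from a class range list (assumes an active RNG).
draw_params <- function(ranges, seed) {
  ratio <- stats::runif(1, ranges$orientation[1L], ranges$orientation[2L])
  m <- stats::runif(1, ranges$semi_minor[1L], ranges$semi_minor[2L])
  if (ratio <= 1) { depth <- m; lateral <- m / ratio }
  else            { lateral <- m; depth <- m * ratio }
  nsp <- if (length(ranges$n_spicules) == 1L) ranges$n_spicules
         else sample(ranges$n_spicules, 1L)
  phantom_params(
    image_rows = 256, image_cols = 256,
    centre = c(stats::runif(1, 100, 118), stats::runif(1, 122, 134)),
    semi_axis_depth = depth, semi_axis_lateral = lateral,
    n_spicules = nsp,
    spicule_depth = if (nsp > 0L)
      stats::runif(1, ranges$spicule_depth[1L], ranges$spicule_depth[2L])
      else 0,
    margin_blur_sigma = stats::runif(1, ranges$margin_blur_sigma[1L],
                                     ranges$margin_blur_sigma[2L]),
    tumour_mean = stats::runif(1, ranges$tumour_mean[1L],
                               ranges$tumour_mean[2L]),
    background_mean = stats::runif(1, ranges$background_mean[1L],
                                   ranges$background_mean[2L]),
    shadow_strength = stats::runif(1, ranges$shadow_strength[1L],
                                   ranges$shadow_strength[2L]),
    speckle_cv = stats::runif(1, ranges$speckle_cv[1L], ranges$speckle_cv[2L]),
    seed = seed)
}

#' Generate a labelled phantom cohort
#'
#' Draws per-lesion parameters uniformly from the class ranges and generates
#' the corresponding phantoms.  With the defaults
#' (`n_benign = 144`, `n_malignant = 62`) the cohort reproduces the class
#' balance of a typical consecutive biopsy-proven series of 206 solid
#' lesions.  Fully reproducible from `seed`.
#'
#' @param n_benign,n_malignant Class sizes (>= 0).
#' @param benign,malignant Class parameter ranges
#'   (see [benign_ranges()], [malignant_ranges()]).
#' @param seed Integer seed for all parameter draws and per-phantom speckle.
#' @return List of `phantom_case` objects with `label` set
#'   (`"benign"`/`"malignant"`) and an attached `lesion_id`
#'   (`B001...`, `M001...`).
#' @export
generate_dataset <- function(n_benign = 144, n_malignant = 62,
                             benign = benign_ranges(),
                             malignant = malignant_ranges(),
                             seed = 1) {
  stopifnot(n_benign >= 0, n_malignant >= 0)
  n <- n_benign + n_malignant
  if (n == 0L) return(list())
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    cases <- vector("list", n)
    for (i in seq_len(n)) {
      benign_case <- i <= n_benign
      ranges <- if (benign_case) benign else malignant
      p <- draw_params(ranges, seeds[i])
      ph <- generate_phantom(p)
      ph$label <- if (benign_case) "benign" else "malignant"
      ph$lesion_id <- if (benign_case) sprintf("B%03d", i)
                      else sprintf("M%03d", i - n_benign)
      cases[[i]] <- ph
    }
    cases
  })
}

#' Feature table of a phantom cohort
#'
#' Extracts the ten features of every phantom in a cohort and assembles the
#' labelled feature table consumed by [cross_validate()] and
#' [forward_select()].
#'
#' @param cases List of `phantom_case` objects (see [generate_dataset()]).
#' @param config A [feature_config()].
#' @return `data.frame` with columns `lesion_id`, `label`, and the ten
#'   features.
#' @export
features_from_cases <- function(cases, config = feature_config()) {
  rows <- lapply(cases, function(ph) {
    fv <- extract_features(ph$image, ph$mask, config)
    cbind(data.frame(lesion_id = ph$lesion_id, label = ph$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}

#' Ground-truth parameter table of a phantom cohort
#'
#' @inheritParams features_from_cases
#' @return `data.frame` with one row per phantom: `lesion_id`, `label`, and
#'   the generating parameters.
#' @export
phantom_truth <- function(cases) {
  do.call(rbind, lapply(cases, function(ph) {
    p <- ph$params
    data.frame(lesion_id = ph$lesion_id, label = ph$label,
               centre_row = p$centre[1L], centre_col = p$centre[2L],
               semi_axis_depth = p$semi_axis_depth,
               semi_axis_lateral = p$semi_axis_lateral,
               axis_ratio = p$semi_axis_depth / p$semi_axis_lateral,
               n_spicules = p$n_spicules, spicule_depth = p$spicule_depth,
               margin_blur_sigma = p$margin_blur_sigma,
               tumour_mean = p$tumour_mean,
               background_mean = p$background_mean,
               shadow_strength = p$shadow_strength,
               speckle_cv = p$speckle_cv, seed = p$seed,
               stringsAsFactors = FALSE)
  }))
}

#' Write a phantom cohort to disk
#'
#' Writes each phantom as an 8-bit greyscale PNG image/mask pair plus
#' `manifest.csv` (`lesion_id,image_path,mask_path,label`) and `truth.csv`
#' (generating parameters).
#'
#' @inheritParams features_from_cases
#' @param out_dir Output directory (created if missing).
#' @return The manifest `data.frame`, invisibly.
#' @export
write_phantom_dataset <- function(cases, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cases, function(ph) {
    img_path <- file.path(out_dir, paste0(ph$lesion_id, "_image.png"))
    mask_path <- file.path(out_dir, paste0(ph$lesion_id, "_mask.png"))
    write_grey_png(ph$image, img_path)
    write_grey_png(ifelse(ph$mask, 255L, 0L), mask_path)
    data.frame(lesion_id = ph$lesion_id, image_path = img_path,
               mask_path = mask_path, label = ph$label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, entries)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(phantom_truth(cases), file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
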