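# Composition of the ten features into one vector.

#' Feature extraction configuration
#'
#' Tunable parameters of the feature extractor, with the package defaults.
#'
#' @param band_halfwidth Margin band half-width in pixels
#'   (see [compute_margin_band()]).
#' @param surround_scale Surrounding-rectangle scale
#'   (see [compute_region_stats()]).
#' @param peak_prominence Minimum peak prominence in pixels
#'   (see [compute_margin_shape_features()]).
#' @return Object of class `feature_config` (named list).
#' @export
feature_config <- function(band_halfwidth = 20, surround_scale = 2.0,
                           peak_prominence = 2.0) {
  stopifnot(band_halfwidth > 0, surround_scale > 0, peak_prominence >= 0)
  structure(list(band_halfwidth = band_halfwidth,
                 surround_scale = surround_scale,
                 peak_prominence = peak_prominence),
            class = "feature_config")
}

#' Extract the ten BI-RADS radiomic features of one lesion
#'
#' Runs all per-feature operations on an image/mask pair and returns the ten
#' features in canonical order ([feature_names()]).  The computation is
#' fully deterministic.  An error in any sub-operation is re-signalled with
#' the affected feature name(s) attached.
#'
#' @inheritParams compute_margin_band
#' @param config A [feature_config()].
#' @return Named numeric vector of length 10.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_params(seed = 7))
#' extract_features(ph$image, ph$mask)
extract_features <- function(image, mask, config = feature_config()) {
  assert_image(image)
  assert_mask(mask, image)
  step <- function(feature, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("feature '%s': %s", feature, conditionMessage(e)),
           call. = FALSE)
    })
  }
  adee <- step("adee", compute_adee(mask)$adee)
  orientation <- step("orientation", compute_orientation(mask))
  band <- step("avg_diff",
               compute_margin_band(image, mask, config$band_halfwidth))
  avg_diff <- step("avg_diff", compute_avg_diff(band))
  profile <- step("num_peaks/avg_distance/adch", compute_convex_profile(mask))
  size <- step("size", compute_size(mask))
  msf <- step("num_peaks/avg_distance/adch",
              compute_margin_shape_features(profile, size,
                                            config$peak_prominence))
  stats <- step("echogenicity/shadow",
                compute_region_stats(image, mask, config$surround_scale))
  echo <- step("echogenicity", compute_echogenicity(stats))
  shadow <- step("shadow", compute_shadow(stats))
  entropy <- step("entropy", compute_entropy(image, mask)$entropy)
  c(adee = adee, orientation = orientation, avg_diff = avg_diff,
    num_peaks = as.numeric(msf$num_peaks), avg_distance = msf$avg_distance,
    adch = msf$adch, echogenicity = echo, entropy = entropy,
    shadow = shadow, size = as.numeric(size))
}
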