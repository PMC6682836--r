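# Raster image and mask input/output.

#' Read a greyscale ultrasound image
#'
#' Reads an 8-bit PNG or TIFF into an integer intensity matrix in
#' \[0, 255\].  Colour inputs are converted by the Rec. 601 luminance
#' (0.299 R + 0.587 G + 0.114 B) with a warning; an alpha channel is
#' ignored.
#'
#' @param path Path to a `.png`, `.tif`, or `.tiff` file.
#' @return Integer matrix (rows = depth axis, row 1 at the skin side).
#' @export
read_grey_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] >= 3L) {
      warning("colour image converted to greyscale by luminance: ", path)
      arr <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr))
}

#' Write a greyscale matrix as 8-bit PNG
#'
#' @param image Numeric matrix with values in \[0, 255\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grey_png <- function(image, path) {
  scaled <- matrix(pmin(1, pmax(0, image / 255)), nrow(image), ncol(image))
  png::writePNG(scaled, path)
  invisible(path)
}

#' Read a lesion mask
#'
#' Reads a lesion delineation either from a binary mask image (PNG/TIFF;
#' any nonzero pixel is lesion) or from an ordered contour-point CSV with
#' header `row,col` describing a closed polygon, filled by the even-odd
#' rule (contour pixels themselves included).
#'
#' @param path Path to the mask image or contour CSV.
#' @param dim For a contour CSV: the image dimensions `c(rows, cols)` the
#'   mask must match.  Ignored for mask images.
#' @return Logical matrix.
#' @export
read_mask <- function(path, dim = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "tif", "tiff")) {
    return(read_grey_image(path) > 0L)
  }
  if (ext != "csv") stop("unsupported mask format: .", ext, call. = FALSE)
  if (is.null(dim))
    stop("image dimensions required to fill a contour CSV", call. = FALSE)
  pts <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(pts)))
    stop("contour CSV must have columns 'row' and 'col'", call. = FALSE)
  poly <- cbind(pts$row, pts$col)
  mask <- fill_polygon(poly, dim[1L], dim[2L])
  # include the polygon trace itself
  nv <- nrow(poly)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    seg <- line_pixels(poly[i, 1L], poly[i, 2L], poly[j, 1L], poly[j, 2L])
    keep <- seg[, 1L] >= 1L & seg[, 1L] <= dim[1L] &
            seg[, 2L] >= 1L & seg[, 2L] <= dim[2L]
    mask[seg[keep, , drop = FALSE]] <- TRUE
  }
  mask
}
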