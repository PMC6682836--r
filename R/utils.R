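# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  Keeps package randomness reproducible
# without clobbering the user's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

assert_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(image) < 1L || ncol(image) < 1L)
    stop("image must have at least one row and column", call. = FALSE)
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop("image intensities must lie in [0, 255]", call. = FALSE)
  invisible(image)
}

assert_mask <- function(mask, image = NULL, check_connected = TRUE) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (!is.null(image) && !identical(dim(mask), dim(image)))
    stop("mask and image dimensions differ", call. = FALSE)
  if (check_connected && !is_single_region(mask))
    stop("disconnected mask: true pixels must form one 8-connected region",
         call. = FALSE)
  invisible(mask)
}

# TRUE iff the true pixels of `mask` form a single 8-connected component.
# bwlabel gives 4-connected components; labels touching diagonally are then
# merged by equivalence closure.
is_single_region <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nl <- max(lab)
  if (nl <= 1L) return(nl == 1L)
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2L || nc < 2L) return(FALSE)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # NW-SE diagonal neighbours
  a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]   # NE-SW
  s1 <- a1 > 0 & b1 > 0 & a1 != b1
  s2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- unique(rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2])))
  comp <- seq_len(nl)
  if (nrow(pairs)) {
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(pairs))) {
        a <- comp[pairs[i, 1L]]; b <- comp[pairs[i, 2L]]
        if (a != b) {
          comp[comp == max(a, b)] <- min(a, b)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  length(unique(comp)) == 1L
}

# Bounding box of true pixels: list(r0, r1, c0, c1), 1-based inclusive.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  list(r0 = min(idx[, 1L]), r1 = max(idx[, 1L]),
       c0 = min(idx[, 2L]), c1 = max(idx[, 2L]))
}
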