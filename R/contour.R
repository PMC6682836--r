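# Boundary extraction and digital-line geometry.

#' Boundary pixels of a lesion mask
#'
#' Returns the true pixels of `mask` that touch the background through a
#' 4-neighbour (or lie on the image edge), i.e. the discrete lesion contour
#' as an unordered pixel set.
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return Integer matrix with columns `row`, `col`, one row per boundary
#'   pixel, in column-major scan order.
#' @seealso [trace_contour()] for the ordered closed chain.
#' @export
boundary_pixels <- function(mask) {
  assert_mask(mask, check_connected = FALSE)
  nr <- nrow(mask); nc <- ncol(mask)
  # a true pixel is boundary if any 4-neighbour is false or out of bounds
  up    <- rbind(FALSE, mask[-nr, , drop = FALSE])
  down  <- rbind(mask[-1L, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, mask[, -nc, drop = FALSE])
  right <- cbind(mask[, -1L, drop = FALSE], FALSE)
  b <- mask & !(up & down & left & right)
  out <- which(b, arr.ind = TRUE)
  colnames(out) <- c("row", "col")
  out
}

# Moore neighbourhood offsets in clockwise screen order (row grows downward),
# starting north.
.moore <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                   1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                 ncol = 2L, byrow = TRUE)

#' Trace the closed contour chain of a lesion mask
#'
#' Moore-neighbour boundary tracing.  The chain starts at the
#' topmost-then-leftmost boundary pixel and proceeds counter-clockwise in
#' Cartesian convention (clockwise on screen, where the row index grows with
#' depth); consecutive chain pixels are 8-adjacent and the last pixel is
#' 8-adjacent to the first.
#'
#' @param mask Logical matrix; the true pixels must form one 8-connected
#'   region.
#' @return Integer matrix with columns `row`, `col`: the ordered closed
#'   boundary chain.  A single-pixel mask yields a one-row chain.
#' @export
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
#' trace_contour(m)
trace_contour <- function(mask) {
  assert_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  if (sum(mask) == 1L) {
    out <- which(mask, arr.ind = TRUE)
    colnames(out) <- c("row", "col")
    return(out)
  }
  # pad with one false ring so neighbour access never needs bounds checks
  M <- matrix(FALSE, nr + 2L, nc + 2L)
  M[2:(nr + 1L), 2:(nc + 1L)] <- mask
  mr <- .moore[, 1L]; mc <- .moore[, 2L]
  # direction index of offset (dr, dc) in the Moore order
  dirmap <- matrix(0L, 3L, 3L)
  for (k in 1:8) dirmap[mr[k] + 2L, mc[k] + 2L] <- k
  # start: topmost row, then leftmost column within it (padded coords)
  idx <- which(M, arr.ind = TRUE)
  r0 <- min(idx[, 1L])
  c0 <- min(idx[idx[, 1L] == r0, 2L])
  back0 <- 7L  # index of W in .moore: west of start is background
  limit <- 8L * sum(mask) + 16L
  chain_r <- integer(limit); chain_c <- integer(limit)
  # first chain index at which each (pixel, backtrack) state was visited;
  # the trace is a deterministic walk on these states, so the first repeated
  # state closes the boundary cycle
  seen <- array(0L, dim = c(nr + 2L, nc + 2L, 8L))
  n_chain <- 0L
  i0 <- 1L
  cur_r <- r0; cur_c <- c0; back <- back0
  repeat {
    if (seen[cur_r, cur_c, back] > 0L) {
      i0 <- seen[cur_r, cur_c, back]
      break
    }
    n_chain <- n_chain + 1L
    if (n_chain > limit)
      stop("contour tracing failed to close", call. = FALSE)
    seen[cur_r, cur_c, back] <- n_chain
    chain_r[n_chain] <- cur_r; chain_c[n_chain] <- cur_c
    found <- FALSE
    for (s in 1:8) {
      k <- ((back + s - 1L) %% 8L) + 1L  # scan clockwise after the backtrack
      rr <- cur_r + mr[k]; cc <- cur_c + mc[k]
      if (M[rr, cc]) {
        # new backtrack: the neighbour scanned just before the hit, as seen
        # from the new pixel
        prev_k <- ((back + s - 2L) %% 8L) + 1L
        back <- dirmap[cur_r + mr[prev_k] - rr + 2L,
                       cur_c + mc[prev_k] - cc + 2L]
        cur_r <- rr; cur_c <- cc
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel (cannot happen: handled above)
  }
  cyc <- seq.int(i0, n_chain)
  rs <- chain_r[cyc]; cs <- chain_c[cyc]
  # rotate the cycle so it starts at the topmost-then-leftmost pixel
  pos <- which(rs == r0 & cs == c0)
  if (length(pos) && pos[1L] > 1L) {
    ord <- c(pos[1L]:length(cyc), 1L:(pos[1L] - 1L))
    rs <- rs[ord]; cs <- cs[ord]
  }
  cbind(row = rs - 1L, col = cs - 1L)
}

# Rasterize the straight segment (r0,c0)->(r1,c1) as an 8-connected digital
# line (DDA with half-up rounding, which keeps the line translation
# invariant), endpoints included, ordered from the first point.
line_pixels <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  cbind(row = as.integer(floor(seq(r0, r1, length.out = n) + 0.5)),
        col = as.integer(floor(seq(c0, c1, length.out = n) + 0.5)))
}

# Even-odd (crossing-number) polygon fill over the pixel grid.  `poly` is a
# matrix of (row, col) vertices of a closed polygon; returns a logical
# nr x nc matrix of pixel centres inside.
fill_polygon <- function(poly, nr, nc) {
  py <- poly[, 1L]; px <- poly[, 2L]
  m <- length(py)
  inside <- matrix(FALSE, nr, nc)
  # horizontal scanline per pixel row through pixel centres
  for (r in seq_len(nr)) {
    xs <- numeric(0)
    j <- m
    for (i in seq_len(m)) {
      yi <- py[i]; yj <- py[j]
      if ((yi > r) != (yj > r)) {
        xs <- c(xs, px[i] + (r - yi) / (yj - yi) * (px[j] - px[i]))
      }
      j <- i
    }
    if (length(xs)) {
      xs <- sort(xs)
      for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        a <- ceiling(xs[k] - 1e-9); b <- floor(xs[k + 1L] + 1e-9)
        if (b >= a) inside[r, max(1L, a):min(nc, b)] <- TRUE
      }
    }
  }
  inside
}
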