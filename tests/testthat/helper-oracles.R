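# Independent brute-force oracles and small mask builders used across tests.
# All oracles use plain scalar loops so they share no code path with the
# package implementation.

mask_rect <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, c0:c1] <- TRUE
  m
}

mask_disc <- function(nr, nc, cr, cc, rad) {
  m <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if ((r - cr)^2 + (c - cc)^2 <= rad^2) m[r, c] <- TRUE
  m
}

# star with k spicules: radial cosine-lobe boundary around a disc
mask_star <- function(nr, nc, cr, cc, rad, k, amp) {
  m <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    d <- sqrt((r - cr)^2 + (c - cc)^2)
    phi <- atan2(r - cr, c - cc)
    if (d <= rad + amp * (1 + cos(k * phi)) / 2) m[r, c] <- TRUE
  }
  m
}

# count of true pixels with at least one false 4-neighbour (or image edge)
oracle_boundary_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  cnt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    edge <- r == 1L || r == nr || c == 1L || c == nc
    if (edge || !mask[r - 1L, c] || !mask[r + 1L, c] ||
        !mask[r, c - 1L] || !mask[r, c + 1L]) cnt <- cnt + 1L
  }
  cnt
}

# moment-ellipse pixel counts recomputed from scratch: returns A_E, A_int,
# and the implied adee
oracle_adee <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  rs <- c(); cs <- c()
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if (mask[r, c]) { rs <- c(rs, r); cs <- c(cs, c) }
  n <- length(rs)
  mr <- sum(rs) / n; mc <- sum(cs) / n
  vxx <- sum((cs - mc)^2) / n
  vyy <- sum((rs - mr)^2) / n
  vxy <- sum((cs - mc) * (rs - mr)) / n
  e <- eigen(matrix(c(vxx, vxy, vxy, vyy), 2, 2), symmetric = TRUE)
  a <- 2 * sqrt(e$values[1]); b <- 2 * sqrt(e$values[2])
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1])
  a_e <- 0L; a_int <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    u <- (c - mc) * cos(ang) + (r - mr) * sin(ang)
    v <- -(c - mc) * sin(ang) + (r - mr) * cos(ang)
    if ((u / a)^2 + (v / b)^2 <= 1) {
      a_e <- a_e + 1L
      if (mask[r, c]) a_int <- a_int + 1L
    }
  }
  list(a_e = a_e, a_int = a_int, adee = (a_e + n - a_int) / n)
}

# convex-hull pixel count: test every pixel centre against all hull
# half-planes (hull vertices from chull on the true pixels)
oracle_hull_area <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  h <- grDevices::chull(idx[, 2], idx[, 1])
  vx <- idx[h, 2]; vy <- idx[h, 1]
  nv <- length(h)
  a2 <- 0
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1 else i + 1
    a2 <- a2 + vx[i] * vy[j] - vx[j] * vy[i]
  }
  s <- if (a2 >= 0) 1 else -1
  cnt <- 0L
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask))) {
    inside <- TRUE
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1 else i + 1
      cr <- (vx[j] - vx[i]) * (r - vy[i]) - (vy[j] - vy[i]) * (c - vx[i])
      if (s * cr < -1e-9) { inside <- FALSE; break }
    }
    if (inside) cnt <- cnt + 1L
  }
  cnt
}

# Mann-Whitney AUC by exhaustive positive-negative pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# region-rectangle pixel counts recomputed from the descriptor definitions
oracle_region_counts <- function(mask, surround_scale = 2) {
  nr <- nrow(mask); nc <- ncol(mask)
  rs <- which(mask, arr.ind = TRUE)
  r0 <- min(rs[, 1]); r1 <- max(rs[, 1]); c0 <- min(rs[, 2]); c1 <- max(rs[, 2])
  h <- r1 - r0 + 1; w <- c1 - c0 + 1
  cr <- (r0 + r1) / 2; cc <- (c0 + c1) / 2
  n_surr <- 0L; n_post <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    in_post <- r > r1 && r <= r1 + h && c >= c0 && c <= c1
    if (in_post) n_post <- n_post + 1L
    in_surr <- abs(r - cr) <= surround_scale * h / 2 &&
               abs(c - cc) <= surround_scale * w / 2
    if (in_surr && !mask[r, c] && !in_post) n_surr <- n_surr + 1L
  }
  list(n_surr = n_surr, n_post = n_post)
}

# a small deterministic pool of test masks (all within 64x64)
oracle_mask_pool <- function() {
  pool <- list(
    mask_rect(64, 64, 10, 40, 8, 28),
    mask_rect(64, 64, 5, 14, 5, 54),
    mask_rect(30, 50, 3, 22, 4, 45),
    mask_disc(64, 64, 32, 32, 12),
    mask_disc(64, 64, 25, 30, 18),
    mask_disc(48, 40, 22, 20, 9),
    mask_star(64, 64, 32, 32, 12, 5, 8),
    mask_star(64, 64, 30, 34, 10, 3, 10),
    mask_star(64, 64, 33, 31, 14, 7, 6),
    mask_star(64, 64, 32, 32, 11, 4, 9),
    mask_star(64, 64, 28, 30, 13, 6, 7))
  # unions of two discs (blobby, asymmetric)
  for (s in 1:9) {
    set.seed(100 + s)
    a <- mask_disc(64, 64, 20 + s, 25, 10)
    b <- mask_disc(64, 64, 30, 28 + s, 8)
    pool[[length(pool) + 1]] <- a | b
  }
  pool
}
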