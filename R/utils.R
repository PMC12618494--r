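# Internal numerical utilities shared across modules.

# Deterministic per-stage seed derived from one global seed. Keeps results
# reproducible while decorrelating stages; always below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Separable Gaussian blur of an [ny, nx] matrix or [ny, nx, nf] array, sigma
# in pixels, reflective edges. Implemented as two banded matrix products so a
# whole time-lapse is filtered in one BLAS call per axis.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  nd <- length(d)
  ny <- d[1]; nx <- d[2]
  Ky <- gauss_band(ny, sigma)
  Kx <- gauss_band(nx, sigma)
  xm <- matrix(x, nrow = ny)            # ny x (nx * nf)
  xm <- Ky %*% xm
  nf <- if (nd == 3L) d[3] else 1L
  # blur along columns: permute so nx is leading
  a <- array(xm, c(ny, nx, nf))
  a <- aperm(a, c(2, 1, 3))
  am <- Kx %*% matrix(a, nrow = nx)
  a <- array(am, c(nx, ny, nf))
  a <- aperm(a, c(2, 1, 3))
  if (nd == 2L) dim(a) <- d else dim(a) <- d
  a
}

# Dense 1-D Gaussian convolution matrix with reflective boundary folding.
gauss_band <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- j + (-r:r)
    idx <- reflect_index(idx, n)
    for (m in seq_along(idx)) K[idx[m], j] <- K[idx[m], j] + k[m]
  }
  t(K)
}

reflect_index <- function(idx, n) {
  idx <- abs(idx - 1)
  p <- 2 * (n - 1)
  if (p == 0) return(rep(1L, length(idx)))
  idx <- idx %% p
  idx <- ifelse(idx >= n, p - idx, idx)
  as.integer(idx + 1)
}

# 1-D Gaussian smoothing of a series with reflective edges (kernel-normalized).
smooth_series <- function(x, sigma) {
  if (sigma <= 0 || length(x) < 2) return(x)
  n <- length(x)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  idx <- outer(seq_len(n), -r:r, "+")
  idx[] <- reflect_index(as.vector(idx), n)
  drop(matrix(x[idx], nrow = n) %*% k)
}

# 8-connected labeling of a logical matrix by iterative label propagation.
# Returns an integer matrix with labels 1..k (0 = background).
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  lab[mask] <- seq_len(sum(mask))
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  repeat {
    new <- lab
    for (s in shifts) {
      sh <- shift_matrix(lab, s[1], s[2])
      new <- pmax(new, sh)
    }
    new[!mask] <- 0L
    if (identical(new, lab)) break
    lab <- new
  }
  u <- sort(unique(lab[lab > 0]))
  if (length(u)) lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}

# Shift a matrix by (dy, dx), zero-filling exposed edges.
shift_matrix <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0L, ny, nx)
  ys <- max(1, 1 + dy):min(ny, ny + dy)
  xs <- max(1, 1 + dx):min(nx, nx + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Even-odd-rule point-in-polygon; strictly interior points only (points on an
# edge or vertex are classified outside, per the strict filtering contract).
points_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]; xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py))
    xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
    inside <- xor(inside, crosses & (px < xint))
    # boundary test: collinear and within the segment's bounding box
    d <- abs((xj - xi) * (py - yi) - (px - xi) * (yj - yi))
    seg2 <- (xj - xi)^2 + (yj - yi)^2
    onseg <- d^2 <= 1e-18 * max(1, seg2) &
      px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
      py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12
    on_edge <- on_edge | onseg
    j <- i
  }
  inside & !on_edge
}

# TRUE when any two non-adjacent polygon edges intersect.
polygon_self_intersects <- function(poly_x, poly_y) {
  n <- length(poly_x)
  if (n < 4) return(FALSE)
  seg <- cbind(poly_x, poly_y, c(poly_x[-1], poly_x[1]), c(poly_y[-1], poly_y[1]))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next
      if (segments_intersect(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_intersect <- function(a, b) {
  d1 <- cross2(b[3] - b[1], b[4] - b[2], a[1] - b[1], a[2] - b[2])
  d2 <- cross2(b[3] - b[1], b[4] - b[2], a[3] - b[1], a[4] - b[2])
  d3 <- cross2(a[3] - a[1], a[4] - a[2], b[1] - a[1], b[2] - a[2])
  d4 <- cross2(a[3] - a[1], a[4] - a[2], b[3] - a[1], b[4] - a[2])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

`%||%` <- function(a, b) if (is.null(a)) b else a
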