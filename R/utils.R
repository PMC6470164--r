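# Internal numeric utilities shared across modules.

# Shift a matrix by (dr, dc), replicating edge values.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Separable convolution with a 1D kernel applied along rows then columns,
# edge-replicated. Kernel must be odd-length and centred.
sep_conv <- function(m, kernel) {
  w <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(kernel)) out <- out + kernel[k] * shift_mat(m, k - 1L - w, 0L)
  res <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(kernel)) res <- res + kernel[k] * shift_mat(out, 0L, k - 1L - w)
  res
}

gauss_kernel <- function(sigma, half_width = max(1L, ceiling(3 * sigma))) {
  x <- seq(-half_width, half_width)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

box_kernel <- function(half_width) rep(1 / (2 * half_width + 1), 2 * half_width + 1)

# Grayscale box maximum filter of half-width w (separable running max).
max_filter <- function(m, w) {
  out <- m
  for (d in seq_len(w)) out <- pmax(out, shift_mat(m, -d, 0L), shift_mat(m, d, 0L))
  res <- out
  for (d in seq_len(w)) res <- pmax(res, shift_mat(out, 0L, -d), shift_mat(out, 0L, d))
  res
}

# 3x3 (8-neighbour) grayscale dilation used by geodesic reconstruction.
dilate8 <- function(m) {
  res <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- pmax(res, shift_mat(m, dr, dc))
  }
  res
}

# Connected-component labelling of a logical 2D or 3D array.
# connectivity: 2D 4 or 8; 3D 6 or 26. Returns integer array, 0 = background.
label_components <- function(mask, connectivity = NULL) {
  d <- dim(mask)
  nd <- length(d)
  if (is.null(connectivity)) connectivity <- if (nd == 2L) 4L else 6L
  offs <- neighbour_offsets(nd, connectivity)
  # pad with one background cell on every side so linear-index shifts are safe
  pd <- d + 2L
  pad <- array(FALSE, pd)
  if (nd == 2L) {
    pad[2:(d[1] + 1L), 2:(d[2] + 1L)] <- mask
  } else {
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  }
  strides <- cumprod(c(1L, pd[-nd]))
  lin_offs <- as.integer(offs %*% strides)
  labels <- array(0L, pd)
  todo <- which(pad)
  lab <- 0L
  seen <- rep(FALSE, length(pad))
  for (seed in todo) {
    if (seen[seed]) next
    lab <- lab + 1L
    frontier <- seed
    seen[seed] <- TRUE
    labels[seed] <- lab
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, lin_offs, `+`)))
      nb <- nb[pad[nb] & !seen[nb]]
      seen[nb] <- TRUE
      labels[nb] <- lab
      frontier <- nb
    }
  }
  out <- if (nd == 2L) labels[2:(d[1] + 1L), 2:(d[2] + 1L), drop = FALSE]
         else labels[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
  array(out, d)
}

neighbour_offsets <- function(nd, connectivity) {
  grid <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  face <- grid[rowSums(abs(grid)) == 1, , drop = FALSE]
  if (nd == 2L) {
    if (connectivity == 4) face else if (connectivity == 8) grid
    else stop("2D connectivity must be 4 or 8")
  } else if (nd == 3L) {
    if (connectivity == 6) face else if (connectivity == 26) grid
    else stop("3D connectivity must be 6 or 26")
  } else stop("only 2D and 3D supported")
}

# Otsu threshold of a numeric vector (256-bin between-class variance).
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# Signed area of a closed polygon given as a matrix with columns (row, col).
# Positive sign corresponds to clockwise traversal as drawn on screen
# (row axis pointing down).
polygon_signed_area <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Points-in-polygon test; pts and poly are matrices with columns (row, col).
points_in_polygon <- function(pts, poly) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd[, c(2, 1), drop = FALSE], pts[, c(2, 1), drop = FALSE])
}
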