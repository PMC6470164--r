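#' Convert trajectories to instantaneous velocity samples
#'
#' One velocity sample per gap-free consecutive pair of track points:
#' the displacement converted to physical units and divided by the frame
#' interval, positioned at the pair midpoint (in pixels). Links that
#' bridge occlusion gaps (frame difference > 1) are skipped, since their
#' displacement mixes an unknown number of steps.
#'
#' @param tracks a `track_set` from [link_tracks()].
#' @param geometry a [pixel_geometry()].
#' @return Data frame with columns `row`, `col` (px midpoint), `v_row`,
#'   `v_col` (um/s).
#' @export
tracks_to_velocities <- function(tracks, geometry) {
  stopifnot(inherits(geometry, "pixel_geometry"))
  if (!nrow(tracks))
    return(data.frame(row = numeric(0), col = numeric(0),
                      v_row = numeric(0), v_col = numeric(0)))
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  n <- nrow(tracks)
  same <- tracks$track_id[-1] == tracks$track_id[-n]
  gapfree <- same & (tracks$frame[-1] - tracks$frame[-n] == 1)
  i <- which(gapfree)
  dt <- geometry$frame_interval_s
  data.frame(
    row = (tracks$row[i] + tracks$row[i + 1]) / 2,
    col = (tracks$col[i] + tracks$col[i + 1]) / 2,
    v_row = (tracks$row[i + 1] - tracks$row[i]) * geometry$pixel_height_um / dt,
    v_col = (tracks$col[i + 1] - tracks$col[i]) * geometry$pixel_width_um / dt)
}

#' Bounding box of an ROI mask in pixel coordinates
#'
#' @param mask a [roi_mask()].
#' @return Integer vector `(row_min, row_max, col_min, col_max)`.
#' @export
roi_bbox <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  idx <- which(mask$mask, arr.ind = TRUE)
  c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2]))
}

#' Average velocity samples on a fixed spatial grid
#'
#' The ROI bounding box is tiled with non-overlapping square windows of
#' `window_px` pixels (the last row/column of cells may overhang the
#' box). Every sample is assigned to exactly one cell and each cell
#' records the component-wise mean velocity and the sample count.
#'
#' @param samples velocity samples from [tracks_to_velocities()].
#' @param window_px window size in pixels (default 10).
#' @param roi_bbox `(row_min, row_max, col_min, col_max)` in px, e.g.
#'   from [roi_bbox()].
#' @param geometry a [pixel_geometry()] (isotropic after
#'   [remove_anisotropy()]; kept for unit conversions downstream).
#' @return An object of class `flow_grid`: matrices `v_row`, `v_col`
#'   (um/s, `NA` where empty), `n`, logical `outlier`, plus `window_px`,
#'   `bbox`, `geometry`.
#' @export
window_average <- function(samples, window_px = 10, roi_bbox, geometry) {
  if (window_px < 1) stop("window_px must be >= 1")
  nr <- ceiling((roi_bbox[2] - roi_bbox[1] + 1) / window_px)
  nc <- ceiling((roi_bbox[4] - roi_bbox[3] + 1) / window_px)
  v_row <- v_col <- matrix(NA_real_, nr, nc)
  n <- matrix(0L, nr, nc)
  if (nrow(samples)) {
    ri <- pmin(pmax(floor((samples$row - roi_bbox[1]) / window_px) + 1, 1), nr)
    ci <- pmin(pmax(floor((samples$col - roi_bbox[3]) / window_px) + 1, 1), nc)
    cell <- (ci - 1L) * nr + ri
    n_vec <- tabulate(cell, nr * nc)
    sum_r <- rep(0, nr * nc); sum_c <- rep(0, nr * nc)
    agg_r <- tapply(samples$v_row, cell, sum)
    agg_c <- tapply(samples$v_col, cell, sum)
    idx <- as.integer(names(agg_r))
    sum_r[idx] <- agg_r; sum_c[idx] <- agg_c
    nz <- n_vec > 0
    v_row[nz] <- sum_r[nz] / n_vec[nz]
    v_col[nz] <- sum_c[nz] / n_vec[nz]
    n <- matrix(n_vec, nr, nc)
  }
  structure(list(v_row = v_row, v_col = v_col, n = n,
                 outlier = matrix(FALSE, nr, nc),
                 window_px = window_px, bbox = roi_bbox, geometry = geometry),
            class = "flow_grid")
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf("flow_grid: %d x %d cells of %d px, %d non-empty (%d outlier)\n",
              nrow(x$n), ncol(x$n), x$window_px, sum(x$n > 0), sum(x$outlier)))
  invisible(x)
}

# physical (row, col) um positions of cell centres
grid_cell_centers_um <- function(grid) {
  nr <- nrow(grid$n); nc <- ncol(grid$n)
  rpx <- grid$bbox[1] + (seq_len(nr) - 0.5) * grid$window_px - 0.5
  cpx <- grid$bbox[3] + (seq_len(nc) - 0.5) * grid$window_px - 0.5
  list(row_um = (rpx - 0.5) * grid$geometry$pixel_height_um,
       col_um = (cpx - 0.5) * grid$geometry$pixel_width_um)
}

#' Flag outlier cells by the nearest-rank magnitude percentile
#'
#' Cell-vector magnitudes above the given percentile are attributed to
#' tracking errors and flagged as outliers, excluding them from all
#' downstream statistics. The percentile uses the nearest-rank
#' convention (the value at index `ceiling(p/100 * N)` of the sorted
#' magnitudes); cells strictly above that value are flagged, so at most
#' `(100 - p)%` of non-empty cells (plus rounding) are ever removed and
#' an all-equal grid loses nothing.
#'
#' @param grid a `flow_grid`.
#' @param percentile the cutoff percentile (default 97).
#' @return The `flow_grid` with its `outlier` matrix updated.
#' @export
remove_outliers <- function(grid, percentile = 97) {
  stopifnot(inherits(grid, "flow_grid"))
  valid <- grid$n > 0
  if (!any(valid)) stop("flow grid has no non-empty cells")
  mag <- sqrt(grid$v_row^2 + grid$v_col^2)
  mags <- mag[valid]
  cutoff <- sort(mags)[ceiling(percentile / 100 * length(mags))]
  grid$outlier <- valid & !is.na(mag) & mag > cutoff
  grid
}

#' Spatial particle-density heatmap
#'
#' Bins in-ROI detections on a square grid over the ROI bounding box,
#' averages counts over frames and divides by the physical bin area,
#' yielding particles per mm^2. Bins containing no ROI pixel are `NA`.
#'
#' @param detections data frame with columns `frame`, `row`, `col`.
#' @param mask a [roi_mask()].
#' @param bin_px bin size in pixels (default 10, matching the flow-grid
#'   window for visual registration).
#' @param n_frames number of frames averaged over (default: largest
#'   frame index present).
#' @return An object of class `density_heatmap`: `values` (per-mm^2
#'   matrix), `bin_px`, `bbox`, `n_frames`, `bin_area_mm2`, `geometry`.
#' @export
density_heatmap <- function(detections, mask, bin_px = 10, n_frames = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  if (bin_px < 1) stop("bin_px must be >= 1")
  if (is.null(n_frames))
    n_frames <- if (nrow(detections)) max(detections$frame) else 1L
  bbox <- roi_bbox(mask)
  nr <- ceiling((bbox[2] - bbox[1] + 1) / bin_px)
  nc <- ceiling((bbox[4] - bbox[3] + 1) / bin_px)
  g <- mask$geometry
  bin_area_mm2 <- (bin_px * g$pixel_height_um) * (bin_px * g$pixel_width_um) / 1e6
  # restrict to in-mask detections
  H <- nrow(mask$mask); W <- ncol(mask$mask)
  counts <- rep(0L, nr * nc)
  if (nrow(detections)) {
    ri <- round(detections$row); ci <- round(detections$col)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    ok[ok] <- mask$mask[cbind(ri[ok], ci[ok])]
    d <- detections[ok, , drop = FALSE]
    if (nrow(d)) {
      bi <- pmin(pmax(floor((d$row - bbox[1]) / bin_px) + 1, 1), nr)
      bj <- pmin(pmax(floor((d$col - bbox[3]) / bin_px) + 1, 1), nc)
      counts <- tabulate((bj - 1L) * nr + bi, nr * nc)
    }
  }
  values <- matrix(counts / n_frames / bin_area_mm2, nr, nc)
  # mask bins with no ROI pixel
  pix <- which(mask$mask, arr.ind = TRUE)
  bi <- pmin(pmax(floor((pix[, 1] - bbox[1]) / bin_px) + 1, 1), nr)
  bj <- pmin(pmax(floor((pix[, 2] - bbox[3]) / bin_px) + 1, 1), nc)
  in_roi <- matrix(FALSE, nr, nc)
  in_roi[cbind(bi, bj)] <- TRUE
  values[!in_roi] <- NA
  structure(list(values = values, bin_px = bin_px, bbox = bbox,
                 n_frames = n_frames, bin_area_mm2 = bin_area_mm2,
                 geometry = g),
            class = "density_heatmap")
}

#' @export
print.density_heatmap <- function(x, ...) {
  cat(sprintf("density_heatmap: %d x %d bins of %d px, mean %.3g / mm^2\n",
              nrow(x$values), ncol(x$values), x$bin_px,
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

# Discrete curl of the grid vector field, 1/s. Central differences on
# interior cells (both neighbours along each axis valid); NA elsewhere.
# Cells hugging the ROI boundary are deliberately excluded: one-sided
# estimates there mostly measure the unresolved near-wall boundary
# layer, not the free-stream vorticity.
grid_curl <- function(grid) {
  valid <- grid$n > 0 & !grid$outlier
  vr <- grid$v_row; vc <- grid$v_col
  vr[!valid] <- NA; vc[!valid] <- NA
  h_row <- grid$window_px * grid$geometry$pixel_height_um
  h_col <- grid$window_px * grid$geometry$pixel_width_um
  dvr_dc <- (shift_na(vr, 0L, -1L) - shift_na(vr, 0L, 1L)) / (2 * h_col)
  dvc_dr <- (shift_na(vc, -1L, 0L) - shift_na(vc, 1L, 0L)) / (2 * h_row)
  curl <- dvr_dc - dvc_dr
  curl[!valid] <- NA
  curl
}

# matrix shift filling with NA instead of edge replication
shift_na <- function(m, dr, dc) {
  out <- matrix(NA_real_, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)) - dr
  cs <- seq_len(ncol(m)) - dc
  okr <- rs >= 1 & rs <= nrow(m)
  okc <- cs >= 1 & cs <= ncol(m)
  out[okr, okc] <- m[rs[okr], cs[okc], drop = FALSE]
  out
}

#' Segment coherent vortical flow regions with polarity
#'
#' Computes the discrete curl of the windowed velocity field (central
#' differences on interior cells only) and groups 4-connected cells of
#' equal curl sign into candidate regions. A region of `k` cells is
#' reported as a flow field when its absolute circulation (sum of cell
#' curl times cell area) reaches `sqrt(k)` times the significance
#' threshold -- the null circulation of a homogeneous patch grows as the
#' square root of its size -- and it spans at least `min_cells` cells.
#' Fields are numbered FF1, FF2, ... from anterior (low column) to
#' posterior. Polarity is CCW for positive circulation and CW for
#' negative (row axis pointing down).
#'
#' When no threshold is supplied it is self-calibrated against a
#' permutation null: the cell vectors are shuffled among the non-empty
#' cells `n_shuffles` times and the threshold is twice the median
#' absolute circulation of single-cell regions in the shuffled fields.
#'
#' @param grid a `flow_grid` (after [remove_outliers()]).
#' @param circulation_threshold minimum `|circulation|` in um^2/s, or
#'   `NULL` to self-calibrate.
#' @param min_cells minimum region size in cells (default 4: a vortex
#'   resolved by fewer windows cannot carry a meaningful polarity).
#' @param n_shuffles permutations for the null calibration (default 1000).
#' @param null_seed seed for the permutation null (default 1).
#' @return A data frame of class `flow_regions` with columns `label`,
#'   `polarity` ("CW"/"CCW"), `mean_speed_um_s`, `n_cells`,
#'   `circulation_um2_s`, `centroid_row_px`, `centroid_col_px`; the cell
#'   membership matrix (integer region index per cell, 0 = none) is
#'   attached as attribute `membership`.
#' @export
segment_flow_regions <- function(grid, circulation_threshold = NULL,
                                 min_cells = 4, n_shuffles = 1000,
                                 null_seed = 1L) {
  stopifnot(inherits(grid, "flow_grid"))
  valid <- grid$n > 0 & !grid$outlier
  empty <- data.frame(label = character(0), polarity = character(0),
                      mean_speed_um_s = numeric(0), n_cells = integer(0),
                      circulation_um2_s = numeric(0),
                      centroid_row_px = numeric(0), centroid_col_px = numeric(0))
  class(empty) <- c("flow_regions", "data.frame")
  if (sum(valid) < 4) {
    warning("flow grid too sparse to segment (< 4 usable cells)")
    return(empty)
  }
  cell_area <- grid$window_px^2 * grid$geometry$pixel_height_um *
    grid$geometry$pixel_width_um
  curl <- grid_curl(grid)
  if (is.null(circulation_threshold))
    circulation_threshold <- null_circulation_threshold(grid, cell_area,
                                                        n_shuffles, null_seed)
  regs <- curl_regions(curl, cell_area)
  # the null threshold is calibrated on single cells; a k-cell noise
  # region's circulation random-walks as sqrt(k), so the significance
  # bar scales accordingly
  keep <- abs(regs$circ) >= circulation_threshold * sqrt(pmax(regs$size, 1)) &
    regs$size >= min_cells
  membership <- regs$membership
  membership[!(membership %in% which(keep))] <- 0L
  if (!any(keep)) {
    attr(empty, "membership") <- membership
    attr(empty, "threshold") <- circulation_threshold
    return(empty)
  }
  sel <- which(keep)
  mag <- sqrt(grid$v_row^2 + grid$v_col^2)
  stats <- lapply(sel, function(k) {
    cells <- which(regs$membership == k, arr.ind = TRUE)
    data.frame(polarity = if (regs$circ[k] > 0) "CCW" else "CW",
               mean_speed_um_s = mean(mag[regs$membership == k], na.rm = TRUE),
               n_cells = nrow(cells),
               circulation_um2_s = regs$circ[k],
               centroid_row_px = grid$bbox[1] +
                 (mean(cells[, 1]) - 0.5) * grid$window_px - 0.5,
               centroid_col_px = grid$bbox[3] +
                 (mean(cells[, 2]) - 0.5) * grid$window_px - 0.5)
  })
  out <- do.call(rbind, stats)
  o <- order(out$centroid_col_px)
  out <- out[o, , drop = FALSE]
  out <- cbind(label = paste0("FF", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  # renumber membership anterior -> posterior
  remap <- integer(max(regs$membership))
  remap[sel[o]] <- seq_along(sel)
  membership[membership > 0] <- remap[membership[membership > 0]]
  class(out) <- c("flow_regions", "data.frame")
  attr(out, "membership") <- membership
  attr(out, "threshold") <- circulation_threshold
  out
}

# label 4-connected same-sign curl regions; returns membership matrix,
# per-region circulation and size
curl_regions <- function(curl, cell_area) {
  pos <- !is.na(curl) & curl > 0
  neg <- !is.na(curl) & curl < 0
  lp <- label_components(pos, 4)
  ln <- label_components(neg, 4)
  np <- max(lp)
  membership <- lp
  membership[neg] <- ln[neg] + np
  n_reg <- np + max(ln)
  circ <- size <- numeric(n_reg)
  if (n_reg > 0) {
    f <- membership[membership > 0]
    circ_t <- tapply(curl[membership > 0] * cell_area, f, sum)
    size_t <- tapply(curl[membership > 0], f, length)
    circ[as.integer(names(circ_t))] <- circ_t
    size[as.integer(names(size_t))] <- size_t
  }
  list(membership = membership, circ = circ, size = size)
}

null_circulation_threshold <- function(grid, cell_area, n_shuffles, null_seed) {
  valid <- grid$n > 0 & !grid$outlier
  idx <- which(valid)
  vr0 <- grid$v_row[idx]; vc0 <- grid$v_col[idx]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(null_seed)
  singles <- numeric(0)
  g <- grid
  for (s in seq_len(n_shuffles)) {
    p <- sample(length(idx))
    g$v_row[idx] <- vr0[p]; g$v_col[idx] <- vc0[p]
    curl <- grid_curl(g)
    regs <- curl_regions(curl, cell_area)
    one <- regs$size == 1
    if (any(one)) singles <- c(singles, abs(regs$circ[one]))
  }
  if (!length(singles)) return(0)
  2 * stats::median(singles)
}

#' Estimate the angular velocity of a vortical flow field
#'
#' Count-weighted least-squares fit of the tangential cell speed against
#' radius through the origin (`v_t = omega * r`), about a known vortex
#' centre. The sign of the estimate gives the polarity (positive = CCW
#' in this package's convention).
#'
#' @param grid a `flow_grid`.
#' @param center_um vortex centre (row, col) in micrometres.
#' @param max_radius_um only cells within this radius contribute
#'   (default: the core radius is unknown, use all cells).
#' @return A list: `omega_rad_s`, `polarity`, `n_cells`.
#' @export
estimate_angular_velocity <- function(grid, center_um, max_radius_um = Inf) {
  stopifnot(inherits(grid, "flow_grid"))
  valid <- grid$n > 0 & !grid$outlier
  ctr <- grid_cell_centers_um(grid)
  nr <- nrow(grid$n); nc <- ncol(grid$n)
  R <- matrix(ctr$row_um, nr, nc) - center_um[1]
  C <- matrix(ctr$col_um, nr, nc, byrow = TRUE) - center_um[2]
  r <- sqrt(R^2 + C^2)
  use <- valid & r > 0 & r <= max_radius_um
  if (!any(use)) stop("no usable cells within max_radius_um")
  # tangential unit vector for positive omega: (dc, -dr) / r
  vt <- (grid$v_row[use] * C[use] - grid$v_col[use] * R[use]) / r[use]
  wgt <- grid$n[use]
  omega <- sum(wgt * vt * r[use]) / sum(wgt * r[use]^2)
  list(omega_rad_s = omega, polarity = if (omega >= 0) "CCW" else "CW",
       n_cells = sum(use))
}

#' Write / read a flow grid as delimited text
#'
#' One row per cell: cell indices, centre pixel position, mean velocity,
#' sample count and outlier flag; grid metadata in a YAML sidecar.
#'
#' @param grid a `flow_grid`.
#' @param path output path (CSV; sidecar `<stem>.yml`).
#' @return [read_flow_grid()] returns the `flow_grid`.
#' @export
write_flow_grid <- function(grid, path) {
  nr <- nrow(grid$n); nc <- ncol(grid$n)
  cells <- expand.grid(cell_row = seq_len(nr), cell_col = seq_len(nc))
  df <- data.frame(cells,
                   v_row = as.vector(grid$v_row),
                   v_col = as.vector(grid$v_col),
                   n = as.vector(grid$n),
                   outlier = as.vector(grid$outlier))
  utils::write.csv(df, path, row.names = FALSE)
  yaml::write_yaml(list(window_px = grid$window_px,
                        bbox = as.integer(grid$bbox),
                        n_rows = nr, n_cols = nc,
                        pixel_height_um = grid$geometry$pixel_height_um,
                        pixel_width_um = grid$geometry$pixel_width_um,
                        frame_interval_s = grid$geometry$frame_interval_s),
                   paste0(sub("\\.csv$", "", path), ".yml"))
  invisible(path)
}

#' @rdname write_flow_grid
#' @export
read_flow_grid <- function(path) {
  meta <- yaml::read_yaml(paste0(sub("\\.csv$", "", path), ".yml"))
  df <- utils::read.csv(path)
  nr <- meta$n_rows; nc <- meta$n_cols
  lin <- (df$cell_col - 1L) * nr + df$cell_row
  v_row <- v_col <- matrix(NA_real_, nr, nc)
  n <- matrix(0L, nr, nc); outlier <- matrix(FALSE, nr, nc)
  v_row[lin] <- df$v_row; v_col[lin] <- df$v_col
  n[lin] <- df$n; outlier[lin] <- df$outlier
  structure(list(v_row = v_row, v_col = v_col, n = n, outlier = outlier,
                 window_px = meta$window_px, bbox = meta$bbox,
                 geometry = pixel_geometry(meta$pixel_height_um,
                                           meta$pixel_width_um,
                                           meta$frame_interval_s)),
            class = "flow_grid")
}

#' Quiver plot of a flow grid
#'
#' @param x a `flow_grid`.
#' @param scale arrow length scale in px per (um/s).
#' @param ... passed to [graphics::plot()].
#' @export
plot.flow_grid <- function(x, scale = NULL, ...) {
  valid <- x$n > 0 & !x$outlier
  idx <- which(valid, arr.ind = TRUE)
  cx <- x$bbox[3] + (idx[, 2] - 0.5) * x$window_px - 0.5
  cy <- x$bbox[1] + (idx[, 1] - 0.5) * x$window_px - 0.5
  vr <- x$v_row[valid]; vc <- x$v_col[valid]
  if (is.null(scale)) {
    vmax <- max(sqrt(vr^2 + vc^2), na.rm = TRUE)
    scale <- if (vmax > 0) x$window_px / vmax else 1
  }
  graphics::plot(cx, cy, type = "n", xlab = "col (px)", ylab = "row (px)",
                 ylim = rev(range(cy) + c(-1, 1) * x$window_px), ...)
  graphics::arrows(cx, cy, cx + vc * scale, cy + vr * scale,
                   length = 0.04, col = "steelblue")
  invisible(x)
}
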