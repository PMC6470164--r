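#' Resample an outline to equally spaced points
#'
#' Procrustes alignment needs point correspondence, which raw manual
#' outlines do not provide. This resamples the closed polygon to
#' `n_points` points equally spaced by arc length, starting at the
#' anterior-most vertex (smallest column, ties broken by smallest row)
#' and proceeding clockwise (positive signed area with the row axis
#' pointing down).
#'
#' @param outline a [roi_outline()].
#' @param n_points number of points (>= 3).
#' @return An `n_points` x 2 matrix (row, col) in the outline's units.
#' @export
resample_outline <- function(outline, n_points = 100) {
  stopifnot(inherits(outline, "roi_outline"))
  if (n_points < 3) stop("n_points must be >= 3")
  P <- unclass(outline)
  # drop a duplicated closing vertex if present
  if (nrow(P) > 1 && all(P[1, ] == P[nrow(P), ])) P <- P[-nrow(P), , drop = FALSE]
  if (polygon_signed_area(P) < 0) P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
  start <- order(P[, 2], P[, 1])[1]
  P <- P[c(start:nrow(P), seq_len(start - 1L)), , drop = FALSE]
  Pc <- rbind(P, P[1, ])
  seg <- sqrt(rowSums(diff(Pc)^2))
  per <- sum(seg)
  if (per <= 0) stop("degenerate (zero-length) outline")
  cum <- c(0, cumsum(seg))
  s <- (seq_len(n_points) - 1) * per / n_points
  j <- findInterval(s, cum, rightmost.closed = TRUE)
  frac <- (s - cum[j]) / pmax(seg[j], .Machine$double.eps)
  out <- Pc[j, , drop = FALSE] + frac * (Pc[j + 1, , drop = FALSE] -
                                           Pc[j, , drop = FALSE])
  colnames(out) <- c("row", "col")
  out
}

#' Least-squares similarity alignment of corresponding point sets
#'
#' Finds the rotation, isotropic scale and translation that map the
#' `moving` points onto the `reference` points with minimal sum of
#' squared errors (orthogonal Procrustes with scaling). Reflections are
#' excluded (`det(rotation) = +1`): left-right anatomy must never be
#' mirrored, so the rotation is restricted to the special orthogonal
#' group even when a reflected fit would score lower.
#'
#' @param reference n x 2 matrix (row, col) of reference points.
#' @param moving n x 2 matrix in correspondence with `reference`.
#' @return An object of class `similarity_transform`: `rotation` (2 x 2,
#'   det +1), `scale` (> 0), `translation` (length 2), `sse`.
#' @export
procrustes_align <- function(reference, moving) {
  reference <- as.matrix(reference); moving <- as.matrix(moving)
  if (!all(dim(reference) == dim(moving)) || ncol(reference) != 2 ||
      nrow(reference) < 3)
    stop("point sets must be equal-sized n x 2 with n >= 3")
  mu_r <- colMeans(reference); mu_m <- colMeans(moving)
  X <- sweep(reference, 2, mu_r); Y <- sweep(moving, 2, mu_m)
  ssY <- sum(Y^2)
  if (ssY <= .Machine$double.eps) stop("moving points are all coincident")
  A <- crossprod(X, Y)
  sv <- svd(A)
  d <- sign(det(sv$u) * det(sv$v))
  S <- diag(c(1, d))
  R <- sv$u %*% S %*% t(sv$v)
  s <- sum(sv$d * diag(S)) / ssY
  if (s <= 0) stop("degenerate configuration: non-positive scale")
  t_vec <- mu_r - s * as.vector(R %*% mu_m)
  fit <- s * Y %*% t(R)
  sse <- sum((X - fit)^2)
  structure(list(rotation = R, scale = s, translation = t_vec, sse = sse),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- atan2(x$rotation[2, 1], x$rotation[1, 1]) * 180 / pi
  cat(sprintf(
    "similarity_transform: angle %.3f deg, scale %.4f, t = (%.2f, %.2f), sse %.3g\n",
    ang, x$scale, x$translation[1], x$translation[2], x$sse))
  invisible(x)
}

#' Apply a similarity transform to (row, col) points
#'
#' @param transform a `similarity_transform`.
#' @param pts n x 2 matrix (row, col).
#' @return Transformed n x 2 matrix.
#' @export
transform_points <- function(transform, pts) {
  pts <- matrix(pts, ncol = 2)
  sweep(transform$scale * pts %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

#' Align two outlines with a circular-shift correspondence search
#'
#' Resamples both outlines to `n_points`, then minimises the Procrustes
#' SSE over all cyclic shifts of the moving point sequence, making the
#' alignment invariant to where the equal-arc-length sampling starts.
#'
#' @param reference,moving [roi_outline()] objects.
#' @param n_points resampling density (default 100).
#' @return The best `similarity_transform`; the matched reference point
#'   set is attached as attribute `reference_points`.
#' @export
align_outlines <- function(reference, moving, n_points = 100) {
  ref_p <- resample_outline(reference, n_points)
  mov_p <- resample_outline(moving, n_points)
  best <- NULL
  for (k in seq_len(n_points) - 1L) {
    shifted <- mov_p[c((k + 1):n_points, seq_len(k))[seq_len(n_points)], ,
                     drop = FALSE]
    tr <- procrustes_align(ref_p, shifted)
    if (is.null(best) || tr$sse < best$sse) best <- tr
  }
  attr(best, "reference_points") <- ref_p
  best
}

#' Map a flow grid or density heatmap into a reference frame
#'
#' Cell and bin positions are pushed through the similarity transform.
#' Flow vectors are rotated by the transform's rotation and (by default)
#' their magnitudes multiplied by its scale, normalising flow speeds to
#' the reference animal's physical size; `scale_magnitudes = FALSE`
#' keeps physical speeds. Heatmaps transport bin mass (density times
#' bin area), which makes the total particle count invariant and is
#' equivalent to dividing densities by `scale^2`. Transformed cells are
#' resampled onto the reference raster by nearest-cell assignment with
#' count-weighted merging.
#'
#' @param transform a `similarity_transform` mapping moving pixel
#'   coordinates into reference pixel coordinates.
#' @param obj a `flow_grid` or `density_heatmap`.
#' @param reference a `flow_grid` / `density_heatmap` defining the
#'   target raster (bounding box, cell size, geometry).
#' @param scale_magnitudes multiply vector magnitudes by the transform
#'   scale (default TRUE).
#' @return An object of the same class as `obj` on the reference raster.
#' @export
apply_transform <- function(transform, obj, reference,
                            scale_magnitudes = TRUE) {
  stopifnot(inherits(transform, "similarity_transform"))
  if (inherits(obj, "flow_grid")) {
    stopifnot(inherits(reference, "flow_grid"))
    valid <- obj$n > 0 & !obj$outlier
    idx <- which(valid, arr.ind = TRUE)
    nrr <- nrow(reference$n); ncc <- ncol(reference$n)
    v_row <- v_col <- matrix(NA_real_, nrr, ncc)
    n <- matrix(0L, nrr, ncc)
    if (nrow(idx)) {
      src <- cbind(obj$bbox[1] + (idx[, 1] - 0.5) * obj$window_px - 0.5,
                   obj$bbox[3] + (idx[, 2] - 0.5) * obj$window_px - 0.5)
      dst <- transform_points(transform, src)
      vel <- cbind(obj$v_row[valid], obj$v_col[valid]) %*% t(transform$rotation)
      if (scale_magnitudes) vel <- vel * transform$scale
      wi <- obj$n[valid]
      ri <- floor((dst[, 1] - reference$bbox[1]) / reference$window_px) + 1
      ci <- floor((dst[, 2] - reference$bbox[3]) / reference$window_px) + 1
      ok <- ri >= 1 & ri <= nrr & ci >= 1 & ci <= ncc
      cell <- (ci[ok] - 1) * nrr + ri[ok]
      sw <- tapply(wi[ok], cell, sum)
      sr <- tapply(wi[ok] * vel[ok, 1], cell, sum)
      sc <- tapply(wi[ok] * vel[ok, 2], cell, sum)
      lin <- as.integer(names(sw))
      n[lin] <- sw
      v_row[lin] <- sr / sw
      v_col[lin] <- sc / sw
    }
    structure(list(v_row = v_row, v_col = v_col, n = n,
                   outlier = matrix(FALSE, nrr, ncc),
                   window_px = reference$window_px, bbox = reference$bbox,
                   geometry = reference$geometry),
              class = "flow_grid")
  } else if (inherits(obj, "density_heatmap")) {
    stopifnot(inherits(reference, "density_heatmap"))
    nrr <- nrow(reference$values); ncc <- ncol(reference$values)
    mass <- rep(0, nrr * ncc)
    touched <- rep(FALSE, nrr * ncc)
    idx <- which(!is.na(obj$values), arr.ind = TRUE)
    if (nrow(idx)) {
      src <- cbind(obj$bbox[1] + (idx[, 1] - 0.5) * obj$bin_px - 0.5,
                   obj$bbox[3] + (idx[, 2] - 0.5) * obj$bin_px - 0.5)
      dst <- transform_points(transform, src)
      m <- obj$values[idx] * obj$bin_area_mm2   # particles per bin per frame
      ri <- floor((dst[, 1] - reference$bbox[1]) / reference$bin_px) + 1
      ci <- floor((dst[, 2] - reference$bbox[3]) / reference$bin_px) + 1
      ok <- ri >= 1 & ri <= nrr & ci >= 1 & ci <= ncc
      cell <- (ci[ok] - 1) * nrr + ri[ok]
      agg <- tapply(m[ok], cell, sum)
      lin <- as.integer(names(agg))
      mass[lin] <- agg
      touched[lin] <- TRUE
    }
    values <- matrix(mass / reference$bin_area_mm2, nrr, ncc)
    values[!matrix(touched, nrr, ncc)] <- NA
    structure(list(values = values, bin_px = reference$bin_px,
                   bbox = reference$bbox, n_frames = obj$n_frames,
                   bin_area_mm2 = reference$bin_area_mm2,
                   geometry = reference$geometry),
              class = "density_heatmap")
  } else stop("obj must be a flow_grid or density_heatmap")
}

#' Average transformed flow grids or heatmaps across animals
#'
#' All inputs must live on the same reference raster (see
#' [apply_transform()]). Flow grids are averaged with sample-count
#' weights per cell; heatmaps as the plain mean of defined bins. The
#' number of contributing animals is recorded per cell.
#'
#' @param objects non-empty list of `flow_grid` or `density_heatmap`
#'   objects on a common raster.
#' @return A group-average object of the same class, with an extra
#'   element `n_animals` (per-cell contributing-animal count).
#' @export
average_group <- function(objects) {
  if (!length(objects)) stop("empty group")
  if (inherits(objects[[1]], "flow_grid")) {
    ref <- objects[[1]]
    sw <- matrix(0, nrow(ref$n), ncol(ref$n))
    sr <- sc <- matrix(0, nrow(ref$n), ncol(ref$n))
    n_anim <- matrix(0L, nrow(ref$n), ncol(ref$n))
    for (g in objects) {
      stopifnot(inherits(g, "flow_grid"), all(dim(g$n) == dim(ref$n)))
      valid <- g$n > 0 & !g$outlier
      sw[valid] <- sw[valid] + g$n[valid]
      sr[valid] <- sr[valid] + g$n[valid] * g$v_row[valid]
      sc[valid] <- sc[valid] + g$n[valid] * g$v_col[valid]
      n_anim[valid] <- n_anim[valid] + 1L
    }
    v_row <- v_col <- matrix(NA_real_, nrow(ref$n), ncol(ref$n))
    nz <- sw > 0
    v_row[nz] <- sr[nz] / sw[nz]
    v_col[nz] <- sc[nz] / sw[nz]
    out <- structure(list(v_row = v_row, v_col = v_col,
                          n = matrix(as.integer(round(sw)), nrow(sw)),
                          outlier = matrix(FALSE, nrow(sw), ncol(sw)),
                          window_px = ref$window_px, bbox = ref$bbox,
                          geometry = ref$geometry, n_animals = n_anim),
                     class = "flow_grid")
    out
  } else if (inherits(objects[[1]], "density_heatmap")) {
    ref <- objects[[1]]
    acc <- matrix(0, nrow(ref$values), ncol(ref$values))
    n_anim <- matrix(0L, nrow(ref$values), ncol(ref$values))
    for (h in objects) {
      stopifnot(inherits(h, "density_heatmap"),
                all(dim(h$values) == dim(ref$values)))
      ok <- !is.na(h$values)
      acc[ok] <- acc[ok] + h$values[ok]
      n_anim[ok] <- n_anim[ok] + 1L
    }
    values <- matrix(NA_real_, nrow(acc), ncol(acc))
    nz <- n_anim > 0
    values[nz] <- acc[nz] / n_anim[nz]
    structure(list(values = values, bin_px = ref$bin_px, bbox = ref$bbox,
                   n_frames = ref$n_frames, bin_area_mm2 = ref$bin_area_mm2,
                   geometry = ref$geometry, n_animals = n_anim),
              class = "density_heatmap")
  } else stop("objects must be flow_grids or density_heatmaps")
}

#' Write / read a similarity transform as config-style text
#'
#' @param transform a `similarity_transform`.
#' @param path output path.
#' @return [read_transform()] returns the `similarity_transform`.
#' @export
write_transform <- function(transform, path) {
  ang <- atan2(transform$rotation[2, 1], transform$rotation[1, 1])
  yaml::write_yaml(list(rotation_angle_rad = ang, scale = transform$scale,
                        translation = as.numeric(transform$translation),
                        sse = transform$sse), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  y <- yaml::read_yaml(path)
  a <- y$rotation_angle_rad
  structure(list(rotation = matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2),
                 scale = y$scale, translation = as.numeric(y$translation),
                 sse = y$sse),
            class = "similarity_transform")
}

#' Geometrically perturbed copy of a scene (a synthetic "animal")
#'
#' Applies a similarity transform (rotation, scale, translation) plus
#' vertex jitter to a scene's outline and fields, emulating
#' animal-to-animal anatomical variation for cross-animal averaging
#' studies. Field angular velocities are kept, so speeds scale with the
#' anatomy (`v = omega r`).
#'
#' @param scene a [scene_spec()].
#' @param angle_deg rotation angle in degrees.
#' @param scale isotropic scale factor.
#' @param translation_um (row, col) shift in um.
#' @param jitter_sd_um per-vertex Gaussian jitter SD in um.
#' @param seed seed for the jitter and the derived scene.
#' @return A [scene_spec()] with transformed outline and fields.
#' @export
perturb_scene <- function(scene, angle_deg = 0, scale = 1,
                          translation_um = c(0, 0), jitter_sd_um = 0,
                          seed = scene$seed) {
  stopifnot(inherits(scene, "scene_spec"))
  a <- angle_deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  ctr <- scene$canvas_hw_um / 2
  map <- function(p) sweep(scale * sweep(matrix(p, ncol = 2), 2, ctr) %*% t(R),
                           2, ctr + translation_um, `+`)
  verts <- map(unclass(scene$outline))
  if (jitter_sd_um > 0) {
    set.seed(seed)
    verts <- verts + matrix(stats::rnorm(length(verts), 0, jitter_sd_um),
                            ncol = 2)
  }
  shift <- pmax(0, 20 - apply(verts, 2, min))
  verts <- sweep(verts, 2, shift, `+`)
  fields <- lapply(scene$fields, function(f) {
    c_new <- as.numeric(map(f$center_um)) + shift
    flow_field_spec(f$kind, c_new, f$core_radius_um * scale, f$omega_rad_s)
  })
  canvas <- c(max(verts[, 1]) + 20, max(verts[, 2]) + 20)
  out <- scene_spec(roi_outline(verts, "um"), fields,
                    n_particles = scene$n_particles,
                    diameter_range_um = scene$diameter_range_um,
                    psf_sigma_um = scene$psf_sigma_um,
                    background_level = scene$background_level,
                    speckle_sd = scene$speckle_sd,
                    particle_amplitude = scene$particle_amplitude,
                    n_frames = scene$n_frames, geometry = scene$geometry,
                    diffusion_sd = scene$diffusion_sd,
                    appear_rate = scene$appear_rate,
                    vanish_rate = scene$vanish_rate,
                    canvas_hw_um = canvas, seed = seed)
  out
}

#' Ground-truth flow grid of a scene
#'
#' Evaluates the scene's analytic velocity field at every grid-cell
#' centre inside the ROI, producing the flow grid an ideal (noise-free,
#' infinitely sampled) velocimetry run would measure. Cell counts are
#' the number of in-ROI pixels per cell.
#'
#' @param scene a [scene_spec()].
#' @param window_px grid window in pixels (default 10).
#' @return A `flow_grid`.
#' @export
scene_flow_grid <- function(scene, window_px = 10) {
  stopifnot(inherits(scene, "scene_spec"))
  g <- scene$geometry
  H <- ceiling(scene$canvas_hw_um[1] / g$pixel_height_um)
  W <- ceiling(scene$canvas_hw_um[2] / g$pixel_width_um)
  out_px <- outline_um_to_px(scene$outline, g)
  mask <- roi_mask(out_px, c(H, W), g)
  bbox <- roi_bbox(mask)
  grid <- window_average(data.frame(row = numeric(0), col = numeric(0),
                                    v_row = numeric(0), v_col = numeric(0)),
                         window_px, bbox, g)
  ctr <- grid_cell_centers_um(grid)
  nr <- nrow(grid$n); nc <- ncol(grid$n)
  pts_um <- cbind(rep(ctr$row_um, nc), rep(ctr$col_um, each = nr))
  # count in-ROI pixels per cell to weight and mask cells
  pix <- which(mask$mask, arr.ind = TRUE)
  ri <- pmin(floor((pix[, 1] - bbox[1]) / window_px) + 1, nr)
  ci <- pmin(floor((pix[, 2] - bbox[3]) / window_px) + 1, nc)
  cnt <- tabulate((ci - 1L) * nr + ri, nr * nc)
  v <- scene_velocity(scene$fields, pts_um)
  grid$v_row <- matrix(ifelse(cnt > 0, v[, 1], NA), nr, nc)
  grid$v_col <- matrix(ifelse(cnt > 0, v[, 2], NA), nr, nc)
  grid$n <- matrix(as.integer(cnt), nr, nc)
  grid
}
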