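#' Seeded region growing segmentation of a 3D volume
#'
#' Starting from manually chosen seed voxels in the ventricular lumen,
#' iteratively accretes neighbouring voxels whose intensity differs from
#' the running region mean by at most `tolerance`, until no neighbour
#' qualifies. The default tolerance is half the inter-class distance of
#' the volume's Otsu threshold, i.e. half the distance between the
#' lumen and tissue intensity modes. Seeds whose intensity lies on the
#' bright (tissue) side of the Otsu threshold plus the tolerance are
#' rejected, since growing from tissue would flood the background.
#'
#' @param volume an [oct_volume()].
#' @param seeds integer matrix of voxel coordinates, one row per seed,
#'   columns (z, y, x), 1-based.
#' @param tolerance intensity tolerance (> 0), or `NULL` for the Otsu
#'   default.
#' @param connectivity 6 (face neighbours, default: robust against
#'   diagonal leakage through thin aqueduct walls) or 26.
#' @return An object of class `segmentation_result`: `mask` (logical
#'   Z x Y x X), `volume_mm3`, `method = "region_grow"`, `seeds`,
#'   `tolerance`, `voxel_dims_um`.
#' @export
region_grow <- function(volume, seeds, tolerance = NULL, connectivity = 6) {
  stopifnot(inherits(volume, "oct_volume"))
  seeds <- matrix(as.integer(seeds), ncol = 3)
  d <- dim(volume$voxels)
  if (any(seeds < 1) || any(sweep(seeds, 2, d, `>`)))
    stop("seeds must lie inside the volume")
  vox <- volume$voxels
  thr <- otsu_threshold(as.vector(vox))
  if (is.null(tolerance)) {
    lum <- mean(vox[vox <= thr]); tis <- mean(vox[vox > thr])
    tolerance <- (tis - lum) / 2
  }
  if (tolerance <= 0) stop("tolerance must be > 0")
  seed_int <- vox[seeds]
  if (any(seed_int > thr + tolerance))
    stop("seed lies on a voxel brighter than the lumen band plus tolerance")
  offs <- neighbour_offsets(3L, connectivity)
  # pad so linear-index neighbour shifts cannot wrap
  pd <- d + 2L
  pvox <- array(Inf, pd)
  pvox[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vox
  strides <- cumprod(c(1L, pd[-3]))
  lin_offs <- as.integer(offs %*% strides)
  seed_lin <- as.integer((seeds[, 3]) * strides[3] + (seeds[, 2]) * strides[2] +
                           seeds[, 1] + 1L)
  in_region <- rep(FALSE, prod(pd))
  in_region[seed_lin] <- TRUE
  region_sum <- sum(pvox[seed_lin])
  region_n <- length(seed_lin)
  frontier <- seed_lin
  while (length(frontier)) {
    nb <- unique(as.vector(outer(frontier, lin_offs, `+`)))
    nb <- nb[!in_region[nb]]
    if (!length(nb)) break
    ok <- abs(pvox[nb] - region_sum / region_n) <= tolerance
    nb <- nb[ok]
    if (!length(nb)) break
    in_region[nb] <- TRUE
    region_sum <- region_sum + sum(pvox[nb])
    region_n <- region_n + length(nb)
    frontier <- nb
  }
  pmask <- array(in_region, pd)
  mask <- pmask[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  voxel_mm3 <- prod(volume$voxel_dims_um) / 1e9
  structure(list(mask = mask, volume_mm3 = sum(mask) * voxel_mm3,
                 method = "region_grow", seeds = seeds,
                 tolerance = tolerance,
                 voxel_dims_um = volume$voxel_dims_um),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result (%s): %d voxels, %.5g mm^3\n",
              x$method, sum(x$mask), x$volume_mm3))
  invisible(x)
}

#' Interpolate a sparse manual segmentation across slices
#'
#' Fallback used when high particle density defeats region growing: a
#' subset of z slices is segmented manually and the full volume is
#' interpolated. Between annotated slices, masks are interpolated by
#' linear blending of their signed distance transforms (the zero level
#' set of the blend); beyond the annotated range the nearest annotated
#' slice is extended unchanged.
#'
#' @param slice_masks named list of logical Y x X matrices; names are
#'   1-based z indices of the annotated slices.
#' @param z_extent total number of z slices in the reconstructed volume.
#' @param voxel_dims_um (z, y, x) voxel pitch in um.
#' @return A `segmentation_result` with `method = "manual_interp"`.
#' @export
interpolate_manual <- function(slice_masks, z_extent, voxel_dims_um) {
  zs <- sort(as.integer(names(slice_masks)))
  if (length(zs) < 2) stop("need at least 2 annotated slices")
  if (any(zs < 1) || any(zs > z_extent)) stop("annotated z outside z_extent")
  dims2 <- dim(slice_masks[[1]])
  sdfs <- lapply(slice_masks[as.character(zs)], function(m) {
    if (!all(dim(m) == dims2)) stop("annotated slices differ in size")
    signed_distance(m)
  })
  mask <- array(FALSE, c(z_extent, dims2))
  for (z in seq_len(z_extent)) {
    if (z <= zs[1]) {
      mask[z, , ] <- slice_masks[[as.character(zs[1])]]
    } else if (z >= zs[length(zs)]) {
      mask[z, , ] <- slice_masks[[as.character(zs[length(zs)])]]
    } else if (z %in% zs) {
      mask[z, , ] <- slice_masks[[as.character(z)]]
    } else {
      i <- findInterval(z, zs)
      a <- (z - zs[i]) / (zs[i + 1] - zs[i])
      blend <- (1 - a) * sdfs[[i]] + a * sdfs[[i + 1]]
      mask[z, , ] <- blend > 0
    }
  }
  voxel_mm3 <- prod(voxel_dims_um) / 1e9
  structure(list(mask = mask, volume_mm3 = sum(mask) * voxel_mm3,
                 method = "manual_interp",
                 seeds = NULL, tolerance = NA,
                 voxel_dims_um = as.numeric(voxel_dims_um)),
            class = "segmentation_result")
}

# signed Euclidean distance: positive inside the mask, negative outside
signed_distance <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  inside <- as.matrix(EBImage::distmap(m))
  outside <- as.matrix(EBImage::distmap(1 - m))
  inside - outside
}

#' Mean and SD of the automatic-vs-manual volume error
#'
#' For paired automatic and manual volume measurements of the same
#' samples, computes the absolute error per pair and returns its sample
#' mean and sample standard deviation (n - 1 denominator).
#'
#' @param auto,manual equal-length numeric vectors of volumes (mm^3),
#'   n >= 2.
#' @return A list: `mean_error_mm3`, `sd_error_mm3`, `n`.
#' @export
compare_methods <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("paired lists differ in length")
  if (length(auto) < 2) stop("need at least 2 pairs")
  err <- abs(auto - manual)
  list(mean_error_mm3 = mean(err), sd_error_mm3 = stats::sd(err),
       n = length(err))
}

#' Morphometry of a segmented ventricular system
#'
#' Per-chamber linear extents and aqueduct patency. Chambers are the
#' connected components of the segmentation mask (6-connectivity),
#' reported anterior to posterior; extents are the voxel-coordinate
#' ranges scaled by the voxel pitch: AP length along y, DV height along
#' z, LR width along x. The aqueduct's minimum cross-sectional area is
#' the smallest in-mask area over transverse (constant-y) planes within
#' `aqueduct_span_y`; the system is patent when the mask voxels
#' anterior and posterior of that span belong to one connected
#' component.
#'
#' @param seg a `segmentation_result`.
#' @param aqueduct_span_y integer (y_min, y_max) slab containing the
#'   aqueduct, or `NULL` to skip patency/cross-section assessment.
#' @return A list of class `morphometry_report`: `chambers` (data frame
#'   with per-chamber `ap_length_um`, `dv_height_um`, `lr_width_um`,
#'   `n_voxels`), `aqueduct_min_area_um2`, `patent`.
#' @export
morphometry <- function(seg, aqueduct_span_y = NULL) {
  stopifnot(inherits(seg, "segmentation_result"))
  if (!any(seg$mask)) stop("empty segmentation mask")
  vd <- seg$voxel_dims_um
  lab <- label_components(seg$mask, connectivity = 6)
  ncomp <- max(lab)
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  ch <- do.call(rbind, lapply(seq_len(ncomp), function(k) {
    v <- idx[l == k, , drop = FALSE]
    data.frame(
      ap_length_um = (diff(range(v[, 2])) + 1) * vd[2],
      dv_height_um = (diff(range(v[, 1])) + 1) * vd[1],
      lr_width_um = (diff(range(v[, 3])) + 1) * vd[3],
      n_voxels = nrow(v),
      centroid_y = mean(v[, 2]))
  }))
  ch <- ch[order(ch$centroid_y), , drop = FALSE]
  ch$centroid_y <- NULL
  rownames(ch) <- NULL
  aq_area <- NA_real_
  patent <- NA
  if (!is.null(aqueduct_span_y)) {
    ys <- max(1, aqueduct_span_y[1]):min(dim(seg$mask)[2], aqueduct_span_y[2])
    areas <- vapply(ys, function(y) sum(seg$mask[, y, ]) * vd[1] * vd[3],
                    numeric(1))
    aq_area <- min(areas)
    ant <- unique(lab[, seq_len(min(ys) - 1), , drop = FALSE])
    post <- unique(lab[, setdiff(seq_len(dim(seg$mask)[2]),
                                 seq_len(max(ys))), , drop = FALSE])
    shared <- intersect(setdiff(ant, 0L), setdiff(post, 0L))
    patent <- length(shared) > 0
  }
  structure(list(chambers = ch, aqueduct_min_area_um2 = aq_area,
                 patent = patent),
            class = "morphometry_report")
}

#' @export
print.morphometry_report <- function(x, ...) {
  cat(sprintf("morphometry_report: %d chamber(s)\n", nrow(x$chambers)))
  print(x$chambers)
  if (!is.na(x$patent))
    cat(sprintf("aqueduct: min cross-section %.4g um^2, %s\n",
                x$aqueduct_min_area_um2,
                if (x$patent) "patent" else "stenosed"))
  invisible(x)
}

#' Write a segmentation mask as a binary multi-page TIFF
#'
#' @param seg a `segmentation_result`.
#' @param path output TIFF path (pages are z slices).
#' @return `path`, invisibly.
#' @export
write_segmentation_tiff <- function(seg, path) {
  pages <- lapply(seq_len(dim(seg$mask)[1]),
                  function(z) matrix(as.numeric(seg$mask[z, , ]),
                                     dim(seg$mask)[2], dim(seg$mask)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  yaml::write_yaml(list(voxel_z_um = seg$voxel_dims_um[1],
                        voxel_y_um = seg$voxel_dims_um[2],
                        voxel_x_um = seg$voxel_dims_um[3],
                        method = seg$method),
                   sidecar_path(path))
  invisible(path)
}
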