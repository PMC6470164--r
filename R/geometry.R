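#' Physical pixel geometry of an acquisition
#'
#' Records the physical size of a pixel and the frame interval of a 2D
#' time series. OCT B-scans are generally acquired with anisotropic
#' pixels (axial and lateral pitch differ), so the geometry must
#' accompany the raw frames through the analysis.
#'
#' @param pixel_height_um pixel height (row pitch) in micrometres, > 0.
#' @param pixel_width_um pixel width (column pitch) in micrometres, > 0.
#' @param frame_interval_s time between consecutive frames in seconds, > 0.
#' @return An object of class `pixel_geometry`.
#' @export
pixel_geometry <- function(pixel_height_um, pixel_width_um, frame_interval_s) {
  vals <- c(pixel_height_um, pixel_width_um, frame_interval_s)
  if (length(vals) != 3L || !all(is.finite(vals)) || any(vals <= 0))
    stop("pixel geometry values must be finite, positive scalars")
  structure(list(pixel_height_um = pixel_height_um,
                 pixel_width_um = pixel_width_um,
                 frame_interval_s = frame_interval_s),
            class = "pixel_geometry")
}

#' @export
print.pixel_geometry <- function(x, ...) {
  cat(sprintf("pixel geometry: %.4g x %.4g um/px, dt = %.4g s\n",
              x$pixel_height_um, x$pixel_width_um, x$frame_interval_s))
  invisible(x)
}

#' Time series of B-scan frames
#'
#' Container for a 2D+time image stack. Frames are stored as an
#' F x H x W array of non-negative intensities in arbitrary units.
#'
#' @param frames numeric array F x H x W (or a single H x W matrix,
#'   promoted to one frame).
#' @param geometry a [pixel_geometry()].
#' @return An object of class `oct_video` with elements `frames` and
#'   `geometry`.
#' @export
oct_video <- function(frames, geometry) {
  if (is.matrix(frames)) frames <- array(frames, c(1L, dim(frames)))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be an F x H x W array")
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  stopifnot(inherits(geometry, "pixel_geometry"))
  structure(list(frames = frames, geometry = geometry), class = "oct_video")
}

#' @export
print.oct_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("oct_video: %d frames of %d x %d px (%.4g x %.4g um/px, dt %.4g s)\n",
              d[1], d[2], d[3], x$geometry$pixel_height_um,
              x$geometry$pixel_width_um, x$geometry$frame_interval_s))
  invisible(x)
}

#' @export
dim.oct_video <- function(x) dim(x$frames)

#' 3D image volume
#'
#' @param voxels numeric array Z x Y x X. z runs dorsal to ventral
#'   (slice index), y anterior to posterior, x left to right.
#' @param voxel_dims_um numeric length-3 vector of (z, y, x) voxel pitch
#'   in micrometres.
#' @return An object of class `oct_volume`.
#' @export
oct_volume <- function(voxels, voxel_dims_um) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a Z x Y x X array")
  if (length(voxel_dims_um) != 3L || any(!is.finite(voxel_dims_um)) ||
      any(voxel_dims_um <= 0))
    stop("voxel_dims_um must be 3 positive values (z, y, x)")
  structure(list(voxels = voxels, voxel_dims_um = as.numeric(voxel_dims_um)),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("oct_volume: %d x %d x %d voxels (z,y,x) at %.4g x %.4g x %.4g um\n",
              d[1], d[2], d[3], x$voxel_dims_um[1], x$voxel_dims_um[2],
              x$voxel_dims_um[3]))
  invisible(x)
}

# ---- TIFF + sidecar I/O ----------------------------------------------------

# Multi-page TIFF stores intensities rescaled to [0, 1]; the scale factor
# and physical geometry travel in a YAML sidecar next to the TIFF.

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".yml")

#' Write a video to multi-page TIFF with a geometry sidecar
#'
#' Pages are time. Intensities are rescaled to `[0, 1]` for 16-bit
#' storage; the scale is recorded in the YAML sidecar
#' (`<stem>.yml`, keys `pixel_height_um`, `pixel_width_um`,
#' `frame_interval_s`, `intensity_scale`) so that [read_video_tiff()]
#' round-trips the original values.
#'
#' @param video an [oct_video()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_video_tiff <- function(video, path) {
  stopifnot(inherits(video, "oct_video"))
  sc <- max(video$frames, 1e-12)
  pages <- lapply(seq_len(dim(video$frames)[1]),
                  function(f) pmin(pmax(video$frames[f, , ] / sc, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  g <- video$geometry
  yaml::write_yaml(list(pixel_height_um = g$pixel_height_um,
                        pixel_width_um = g$pixel_width_um,
                        frame_interval_s = g$frame_interval_s,
                        intensity_scale = sc),
                   sidecar_path(path))
  invisible(path)
}

#' Read a video from multi-page TIFF with a geometry sidecar
#'
#' @param path TIFF path written by [write_video_tiff()], or any
#'   multi-page TIFF accompanied by a YAML sidecar with the geometry keys.
#' @return An [oct_video()].
#' @export
read_video_tiff <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  frames <- aperm(simplify2array(pages), c(3, 1, 2))
  sc <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  oct_video(frames * sc,
            pixel_geometry(meta$pixel_height_um, meta$pixel_width_um,
                           meta$frame_interval_s))
}

#' Write a 3D volume to multi-page TIFF (pages are z slices)
#'
#' @param volume an [oct_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  sc <- max(volume$voxels, 1e-12)
  pages <- lapply(seq_len(dim(volume$voxels)[1]),
                  function(z) pmin(pmax(volume$voxels[z, , ] / sc, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(voxel_z_um = volume$voxel_dims_um[1],
                        voxel_y_um = volume$voxel_dims_um[2],
                        voxel_x_um = volume$voxel_dims_um[3],
                        intensity_scale = sc),
                   sidecar_path(path))
  invisible(path)
}

#' Read a 3D volume from multi-page TIFF
#'
#' @param path TIFF path written by [write_volume_tiff()].
#' @return An [oct_volume()].
#' @export
read_volume_tiff <- function(path) {
  meta <- yaml::read_yaml(sidecar_path(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vox <- aperm(simplify2array(pages), c(3, 1, 2))
  sc <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  oct_volume(vox * sc, c(meta$voxel_z_um, meta$voxel_y_um, meta$voxel_x_um))
}
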