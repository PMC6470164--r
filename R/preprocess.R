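#' Correct pixel anisotropy to a square aspect ratio
#'
#' OCT B-scans are acquired with unequal axial and lateral pixel pitch.
#' This resamples the coarser axis onto the finer pitch by linear
#' interpolation, so that the output has square pixels of size
#' `min(pixel_height, pixel_width)`. The finer axis is never
#' downsampled, which would destroy particle spots only 1-2 px wide.
#' The physical extent of the image is preserved to within one pixel.
#' Applying the function to an already-isotropic video returns it
#' unchanged, so the operation is idempotent.
#'
#' @param video an [oct_video()].
#' @return An [oct_video()] with `pixel_height_um == pixel_width_um`.
#' @export
remove_anisotropy <- function(video) {
  stopifnot(inherits(video, "oct_video"))
  g <- video$geometry
  if (g$pixel_height_um == g$pixel_width_um) return(video)
  p <- min(g$pixel_height_um, g$pixel_width_um)
  d <- dim(video$frames)
  H <- d[2]; W <- d[3]
  H2 <- if (g$pixel_height_um > p) round(H * g$pixel_height_um / p) else H
  W2 <- if (g$pixel_width_um > p) round(W * g$pixel_width_um / p) else W
  out <- array(0, c(d[1], H2, W2))
  for (f in seq_len(d[1])) {
    m <- video$frames[f, , ]
    if (H2 != H) m <- resample_axis(m, 1L, H2, g$pixel_height_um, p)
    if (W2 != W) m <- resample_axis(m, 2L, W2, g$pixel_width_um, p)
    out[f, , ] <- m
  }
  oct_video(out, pixel_geometry(p, p, g$frame_interval_s))
}

# Linear interpolation of matrix m along axis (1 = rows, 2 = cols) from
# pitch_old to pitch_new with n_new samples, matching pixel centres.
resample_axis <- function(m, axis, n_new, pitch_old, pitch_new) {
  n_old <- dim(m)[axis]
  x_old <- (seq_len(n_old) - 0.5) * pitch_old
  x_new <- (seq_len(n_new) - 0.5) * pitch_new
  interp_one <- function(v)
    stats::approx(x_old, v, xout = x_new, rule = 2)$y
  if (axis == 1L) apply(m, 2, interp_one)
  else t(apply(m, 1, interp_one))
}

#' Average consecutive B-scan frames
#'
#' The pixelwise arithmetic mean of `n` consecutive frames. Averaging
#' serial B-scans turns moving particles into a trail of local maxima,
#' visualising particle shift as a function of time.
#'
#' @param video an [oct_video()].
#' @param n number of frames to average (default 10).
#' @param start first frame of the window (default 1).
#' @return An H x W matrix.
#' @export
average_bscans <- function(video, n = 10, start = 1) {
  stopifnot(inherits(video, "oct_video"))
  F <- dim(video$frames)[1]
  if (n < 1 || start < 1 || start + n - 1 > F)
    stop(sprintf("cannot average %d frames from %d: video has %d frames",
                 n, start, F))
  colMeans(video$frames[start:(start + n - 1), , , drop = FALSE], dims = 1)
}

#' Temporal colour coding of particle trajectories
#'
#' Each pixel is assigned the colour of the frame in which it is
#' brightest (ties resolved to the latest frame), scaled by that
#' intensity. The frame-indexed ramp runs from cold (blue, early
#' frames) to warm (red, late frames), so a moving particle leaves a
#' cold-to-warm trail along its path.
#'
#' @param video an [oct_video()].
#' @param n_frames number of leading frames to code (default all).
#' @return An H x W x 3 RGB array, scaled to the video's maximum
#'   intensity.
#' @export
temporal_color_code <- function(video, n_frames = dim(video$frames)[1]) {
  stopifnot(inherits(video, "oct_video"))
  F <- dim(video$frames)[1]
  if (n_frames <= 0) stop("n_frames must be positive")
  if (n_frames > F) stop("n_frames exceeds the video length")
  fr <- video$frames[seq_len(n_frames), , , drop = FALSE]
  d <- dim(fr)
  # argmax over frames, last index on ties
  flat <- matrix(fr, nrow = d[1])
  rev_idx <- max.col(t(flat[rev(seq_len(d[1])), , drop = FALSE]), "first")
  which_f <- d[1] + 1L - rev_idx
  peak <- flat[cbind(which_f, seq_len(ncol(flat)))]
  ramp <- temporal_ramp(d[1])
  scale <- max(peak, 1e-12)
  rgb <- vapply(1:3, function(ch) ramp[which_f, ch] * peak / scale,
                numeric(length(peak)))
  array(rgb, c(d[2], d[3], 3))
}

# blue -> cyan -> green -> yellow -> red ramp, one row per frame
temporal_ramp <- function(n) {
  cols <- grDevices::colorRamp(c("blue", "cyan", "green", "yellow", "red"))(
    if (n == 1) 1 else (seq_len(n) - 1) / (n - 1))
  cols / 255
}
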