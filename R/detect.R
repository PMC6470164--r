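#' Detect particles in a frame by the feature-point method
#'
#' Reimplements the classic intensity-moment feature-point detector used
#' for sparse particle videos: (1) image restoration by a
#' background-subtracting band-pass (Gaussian smoothing minus a boxcar
#' local mean over a `(2w+1)` window); (2) candidate selection as local
#' maxima within `(2w+1)` windows among the top `r`-percentile
#' intensities; (3) subpixel refinement by the intensity centroid within
#' a disc of radius `w`; (4) discrimination of spurious detections by
#' their total intensity `m0` and second intensity moment `m2`:
#' detections falling outside a chi-square quantile ellipse of the
#' per-frame (m0, m2) cloud are removed.
#'
#' @param frame numeric H x W matrix.
#' @param radius_px detection radius `w` in pixels (>= 1); true spots
#'   should be separated by more than `2w`.
#' @param intensity_percentile `r`: candidates must rank in the top `r`
#'   percent of restored intensities (0 < r < 100).
#' @param cutoff quantile trimmed from the (m0, m2) cloud (default 0.1);
#'   0 disables discrimination.
#' @return A data frame with columns `row`, `col` (subpixel, px), `m0`,
#'   `m2`; zero rows when nothing is detected.
#' @export
detect_particles <- function(frame, radius_px = 3, intensity_percentile = 0.5,
                             cutoff = 0.1) {
  w <- as.integer(radius_px)
  if (w < 1) stop("radius_px must be >= 1")
  if (intensity_percentile <= 0 || intensity_percentile >= 100)
    stop("intensity_percentile must be in (0, 100)")
  stopifnot(is.matrix(frame))
  restored <- restore_image(frame, w)
  thr <- stats::quantile(restored, 1 - intensity_percentile / 100, names = FALSE)
  mx <- max_filter(restored, w)
  cand <- which(restored == mx & restored > thr & restored > 0, arr.ind = TRUE)
  det <- refine_detections(restored, cand, w)
  if (nrow(det) && cutoff > 0) det <- discriminate_m0m2(det, cutoff)
  det
}

restore_image <- function(frame, w) {
  sm <- sep_conv(frame, gauss_kernel(1))
  bg <- sep_conv(frame, box_kernel(w))
  pmax(sm - bg, 0)
}

refine_detections <- function(img, cand, w) {
  H <- nrow(img); W <- ncol(img)
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      m0 = numeric(0), m2 = numeric(0))
  if (!nrow(cand)) return(empty)
  # drop candidates whose refinement disc would leave the image
  keep <- cand[, 1] > w & cand[, 1] <= H - w & cand[, 2] > w & cand[, 2] <= W - w
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  off <- expand.grid(dr = -w:w, dc = -w:w)
  off <- off[off$dr^2 + off$dc^2 <= w^2, ]
  res <- matrix(0, nrow(cand), 4)
  for (i in seq_len(nrow(cand))) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    # two centroid iterations for subpixel accuracy
    for (it in 1:2) {
      ri <- round(r0); ci <- round(c0)
      ri <- min(max(ri, w + 1L), H - w); ci <- min(max(ci, w + 1L), W - w)
      vals <- img[cbind(ri + off$dr, ci + off$dc)]
      m0 <- sum(vals)
      if (m0 <= 0) break
      r0 <- ri + sum(vals * off$dr) / m0
      c0 <- ci + sum(vals * off$dc) / m0
    }
    dr <- ri + off$dr - r0; dc <- ci + off$dc - c0
    m2 <- if (m0 > 0) sum(vals * (dr^2 + dc^2)) / m0 else 0
    res[i, ] <- c(r0, c0, m0, m2)
  }
  res <- res[res[, 3] > 0, , drop = FALSE]
  # merge duplicate candidates converging to the same spot
  if (nrow(res) > 1) {
    o <- order(-res[, 3])
    res <- res[o, , drop = FALSE]
    keep <- rep(TRUE, nrow(res))
    for (i in 2:nrow(res)) {
      if (!keep[i]) next
      d2 <- (res[seq_len(i - 1), 1] - res[i, 1])^2 +
        (res[seq_len(i - 1), 2] - res[i, 2])^2
      if (any(keep[seq_len(i - 1)] & d2 <= w^2)) keep[i] <- FALSE
    }
    res <- res[keep, , drop = FALSE]
  }
  data.frame(row = res[, 1], col = res[, 2], m0 = res[, 3], m2 = res[, 4])
}

# Quantile-ellipse discrimination on the (m0, m2) cloud. The covariance
# is ridge-regularised so that a tight cloud of identical spots (zero
# variance) keeps every member.
discriminate_m0m2 <- function(det, cutoff) {
  if (nrow(det) < 10) return(det)
  X <- cbind(det$m0, det$m2)
  mu <- colMeans(X)
  S <- stats::cov(X) + diag(c(mu[1], max(mu[2], 1))^2 * 1e-4)
  d2 <- stats::mahalanobis(X, mu, S)
  det[d2 <= stats::qchisq(1 - cutoff, df = 2), , drop = FALSE]
}

#' Detect particles by the H-dome transform
#'
#' Single-image detector for dense scenes where frame-to-frame tracking
#' yields many false negatives. The H-dome image
#' `D = I - reconstruct(I - h, I)` (grayscale geodesic reconstruction by
#' dilation) isolates local intensity peaks of height >= `h`; connected
#' regions of `D > 0` with at least `min_area` pixels become detections
#' at their intensity centroids.
#'
#' @param frame numeric H x W matrix.
#' @param h dome height (> 0), in intensity units.
#' @param min_area minimum region area in pixels.
#' @return A data frame with columns `row`, `col`, `m0`, `m2` as in
#'   [detect_particles()].
#' @export
detect_particles_hdome <- function(frame, h, min_area = 2) {
  if (h <= 0) stop("dome height h must be > 0")
  stopifnot(is.matrix(frame))
  rec <- reconstruct_dilation(frame - h, frame)
  dome <- frame - rec
  # a featureless (constant) frame reconstructs to I - h everywhere,
  # leaving a uniform pedestal of height h; remove the global offset so
  # only genuine local peaks survive
  dome <- dome - min(dome)
  fg <- dome > 1e-9
  if (!any(fg))
    return(data.frame(row = numeric(0), col = numeric(0),
                      m0 = numeric(0), m2 = numeric(0)))
  lab <- label_components(fg, connectivity = 8)
  n <- max(lab)
  idx <- which(fg, arr.ind = TRUE)
  l <- lab[fg]; v <- dome[fg]
  m0 <- as.numeric(tapply(v, l, sum))
  area <- as.numeric(tapply(v, l, length))
  rowc <- as.numeric(tapply(v * idx[, 1], l, sum)) / m0
  colc <- as.numeric(tapply(v * idx[, 2], l, sum)) / m0
  m2 <- vapply(seq_len(n), function(k) {
    sel <- l == k
    sum(v[sel] * ((idx[sel, 1] - rowc[k])^2 + (idx[sel, 2] - colc[k])^2)) / m0[k]
  }, numeric(1))
  keep <- area >= min_area
  data.frame(row = rowc[keep], col = colc[keep], m0 = m0[keep], m2 = m2[keep])
}

# Grayscale geodesic reconstruction of marker under mask by iterated
# 8-neighbour dilation; converges because the image is finite.
reconstruct_dilation <- function(marker, mask, max_iter = 10000L) {
  cur <- pmin(marker, mask)
  for (i in seq_len(max_iter)) {
    nxt <- pmin(dilate8(cur), mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
  cur
}

#' Detect particles in every frame of a video
#'
#' Runs the chosen detector per frame and stacks the results with a
#' `frame` column. When the per-frame detection count varies by more
#' than 30\% between consecutive frames, an advisory warning suggests
#' the dense-scene H-dome mode (the symptom of a high false-negative
#' rate in feature-point mode).
#'
#' @param video an [oct_video()].
#' @param mode `"feature_point"` or `"hdome"`.
#' @param ... parameters passed to [detect_particles()] or
#'   [detect_particles_hdome()].
#' @return A data frame `frame, row, col, m0, m2` sorted by frame.
#' @export
detect_video <- function(video, mode = c("feature_point", "hdome"), ...) {
  stopifnot(inherits(video, "oct_video"))
  mode <- match.arg(mode)
  F <- dim(video$frames)[1]
  out <- vector("list", F)
  for (f in seq_len(F)) {
    d <- if (mode == "feature_point") detect_particles(video$frames[f, , ], ...)
         else detect_particles_hdome(video$frames[f, , ], ...)
    if (nrow(d)) out[[f]] <- cbind(frame = f, d)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(0), row = numeric(0), col = numeric(0),
                      m0 = numeric(0), m2 = numeric(0))
  counts <- tabulate(res$frame, F)
  if (mode == "feature_point" && F > 1) {
    rel <- abs(diff(counts)) / pmax(counts[-F], 1)
    if (any(rel > 0.3, na.rm = TRUE))
      warning("detection count varies > 30% between frames; ",
              "consider mode = \"hdome\" for dense scenes")
  }
  res
}

#' Read / write detection tables
#'
#' Delimited text with columns `frame,row,col,m0,m2`.
#' @param path file path.
#' @param detections a detection data frame.
#' @return [read_detections()] returns the data frame.
#' @export
write_detections <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  utils::read.csv(path)
}
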