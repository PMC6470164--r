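#' Region-of-interest outline
#'
#' A simple closed polygon delimiting the ventricular lumen in the
#' anisotropy-corrected image, given as (row, col) vertices. Coordinates
#' may be in pixels (image analysis) or micrometres (scene space); the
#' unit is recorded for bookkeeping only.
#'
#' @param vertices numeric matrix with two columns (row, col); the
#'   polygon is implicitly closed (do not repeat the first vertex).
#' @param units `"px"` or `"um"`.
#' @return A matrix of class `roi_outline` with a `units` attribute.
#' @export
roi_outline <- function(vertices, units = c("px", "um")) {
  units <- match.arg(units)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("an outline needs at least 3 (row, col) vertices")
  if (!all(is.finite(vertices))) stop("outline vertices must be finite")
  if (abs(polygon_signed_area(vertices)) < .Machine$double.eps)
    stop("degenerate (zero-area) outline")
  colnames(vertices) <- c("row", "col")
  structure(vertices, units = units, class = c("roi_outline", "matrix", "array"))
}

#' Convert an outline between micrometre and pixel coordinates
#'
#' Pixel centres sit at `(i - 0.5) * pitch`, so micrometre position `u`
#' maps to pixel coordinate `u / pitch + 0.5`.
#'
#' @param outline a [roi_outline()] in micrometres.
#' @param geometry a [pixel_geometry()].
#' @return A [roi_outline()] in pixels.
#' @export
outline_um_to_px <- function(outline, geometry) {
  stopifnot(attr(outline, "units") == "um")
  px <- cbind(outline[, 1] / geometry$pixel_height_um + 0.5,
              outline[, 2] / geometry$pixel_width_um + 0.5)
  roi_outline(px, "px")
}

#' Rasterise an ROI outline to a boolean mask
#'
#' A pixel belongs to the mask when its centre falls inside the polygon.
#' The physical ROI area is taken from the polygon (shoelace formula),
#' which agrees with the rasterised area to within a one-pixel rim.
#'
#' @param outline a [roi_outline()] in pixel coordinates.
#' @param dim_hw integer (H, W) of the target image.
#' @param geometry a [pixel_geometry()] used to express the area in mm^2.
#' @return A list of class `roi_mask`: `mask` (logical H x W), `outline`,
#'   `area_mm2` (polygon area), `geometry`.
#' @export
roi_mask <- function(outline, dim_hw, geometry) {
  stopifnot(inherits(outline, "roi_outline"), attr(outline, "units") == "px")
  H <- dim_hw[1]; W <- dim_hw[2]
  pts <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H))
  inside <- points_in_polygon(pts, unclass(outline))
  mask <- matrix(inside, H, W)
  area_px2 <- abs(polygon_signed_area(outline))
  area_mm2 <- area_px2 * geometry$pixel_height_um * geometry$pixel_width_um / 1e6
  if (area_mm2 <= 0) stop("ROI area must be positive")
  structure(list(mask = mask, outline = outline, area_mm2 = area_mm2,
                 geometry = geometry), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: %d x %d px, %d in-mask px, area %.4g mm^2\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$area_mm2))
  invisible(x)
}

#' Read / write ROI polygon files
#'
#' Plain-text, whitespace-delimited, two columns per line: 0-based
#' `row col` pixel coordinates of consecutive vertices in the
#' anisotropy-corrected image.
#'
#' @param path file path.
#' @return [read_roi()] returns a [roi_outline()] in pixel coordinates
#'   (converted to this package's 1-based convention).
#' @export
read_roi <- function(path) {
  m <- as.matrix(utils::read.table(path, col.names = c("row", "col")))
  roi_outline(m + 1, "px")
}

#' @rdname read_roi
#' @param outline a [roi_outline()] in pixel coordinates.
#' @export
write_roi <- function(outline, path) {
  stopifnot(inherits(outline, "roi_outline"), attr(outline, "units") == "px")
  utils::write.table(round(unclass(outline) - 1, 6), path,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
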