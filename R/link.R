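#' Link per-frame detections into particle trajectories
#'
#' Frame-by-frame linking with optimal per-frame-pair assignment: for
#' each frame, candidate pairs between open track ends and new
#' detections within `max_disp` pixels are matched so that the number of
#' links is maximal and, among maximal matchings, the total squared
#' displacement is minimal (solved as a maximum-weight bipartite
#' matching). Unmatched detections start new tracks. A track end stays
#' open for `link_range` frames, so trajectories can bridge temporary
#' occlusions of up to `link_range - 1` missing frames. No two tracks
#' share a detection.
#'
#' @param detections data frame with columns `frame`, `row`, `col`
#'   (extra columns ignored), sorted by frame.
#' @param max_disp maximum link displacement in pixels (> 0).
#' @param link_range maximum frame gap a link may bridge (>= 1;
#'   1 = consecutive frames only).
#' @param greedy use greedy nearest-neighbour matching instead of the
#'   optimal assignment (documented fallback for very dense scenes).
#' @return A data frame of class `track_set` with columns
#'   `track_id, frame, row, col`, ordered by track then frame.
#' @export
link_tracks <- function(detections, max_disp = 10, link_range = 2,
                        greedy = FALSE) {
  if (max_disp <= 0) stop("max_disp must be > 0")
  if (link_range < 1) stop("link_range must be >= 1")
  cols <- c("frame", "row", "col")
  if (!all(cols %in% names(detections)))
    stop("detections need columns frame, row, col")
  if (!nrow(detections))
    return(empty_track_set())
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  # open track ends: id, frame, row, col
  ends <- NULL
  links <- vector("list", length(frames))
  next_id <- 1L
  pieces <- list()
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    det_f <- detections[detections$frame == f, cols, drop = FALSE]
    nd <- nrow(det_f)
    assigned <- rep(NA_integer_, nd)
    if (!is.null(ends) && nrow(ends)) {
      ends <- ends[ends$frame >= f - link_range, , drop = FALSE]
    }
    if (!is.null(ends) && nrow(ends) && nd) {
      cost <- outer(ends$row, det_f$row, `-`)^2 +
        outer(ends$col, det_f$col, `-`)^2
      cost[cost > max_disp^2] <- NA
      assigned <- if (greedy) greedy_assign(cost) else optimal_assign(cost)
    }
    ids <- integer(nd)
    for (j in seq_len(nd)) {
      if (!is.na(assigned[j])) {
        ids[j] <- ends$id[assigned[j]]
      } else {
        ids[j] <- next_id
        next_id <- next_id + 1L
      }
    }
    pieces[[fi]] <- data.frame(track_id = ids, frame = det_f$frame,
                               row = det_f$row, col = det_f$col)
    matched_end <- stats::na.omit(assigned)
    new_ends <- data.frame(id = ids, frame = f, row = det_f$row,
                           col = det_f$col)
    ends <- if (is.null(ends) || !nrow(ends)) new_ends
            else rbind(ends[setdiff(seq_len(nrow(ends)), matched_end), ,
                            drop = FALSE][, c("id", "frame", "row", "col")],
                       new_ends)
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("track_set", "data.frame")
  out
}

empty_track_set <- function() {
  out <- data.frame(track_id = integer(0), frame = integer(0),
                    row = numeric(0), col = numeric(0))
  class(out) <- c("track_set", "data.frame")
  out
}

# cost: ends x detections matrix of squared displacements, NA = forbidden.
# Returns, per detection, the matched end row index or NA. The matching
# maximises cardinality first, then minimises total cost (achieved by
# edge weight B - cost with B large enough).
optimal_assign <- function(cost) {
  ne <- nrow(cost); nd <- ncol(cost)
  edges <- which(!is.na(cost), arr.ind = TRUE)
  out <- rep(NA_integer_, nd)
  if (!nrow(edges)) return(out)
  maxc <- max(cost[edges])
  B <- (min(ne, nd) + 1) * (maxc + 1)
  w <- B - cost[edges]
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, ne), rep(TRUE, nd)),
    edges = as.vector(t(cbind(edges[, 1], ne + edges[, 2]))))
  m <- igraph::max_bipartite_match(g, weights = w)$matching
  for (j in seq_len(nd)) {
    v <- m[ne + j]
    if (!is.na(v)) out[j] <- as.integer(v)
  }
  out
}

greedy_assign <- function(cost) {
  ne <- nrow(cost); nd <- ncol(cost)
  out <- rep(NA_integer_, nd)
  repeat {
    if (all(is.na(cost))) break
    k <- which.min(cost)
    i <- (k - 1) %% ne + 1; j <- (k - 1) %/% ne + 1
    out[j] <- i
    cost[i, ] <- NA; cost[, j] <- NA
  }
  out
}

#' Restrict a track set to a region of interest
#'
#' Track points outside the ROI mask are removed (the pointwise rule:
#' all tracking data outside the ROI is discarded before analysis).
#' A track whose interior points are removed is split at the exits, and
#' resulting fragments shorter than 2 points are dropped. Track ids are
#' renumbered deterministically, so the operation is idempotent.
#'
#' @param tracks a `track_set` from [link_tracks()].
#' @param mask a [roi_mask()] whose raster matches the frame size the
#'   tracks were measured on.
#' @param frame_dim optional (H, W) to validate against the mask.
#' @return A filtered `track_set`.
#' @export
filter_tracks_by_roi <- function(tracks, mask, frame_dim = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!is.null(frame_dim) && !all(dim(mask$mask) == frame_dim))
    stop("ROI mask dimensions do not match the frame dimensions")
  if (!nrow(tracks)) return(empty_track_set())
  H <- nrow(mask$mask); W <- ncol(mask$mask)
  ri <- round(tracks$row); ci <- round(tracks$col)
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  ok[ok] <- mask$mask[cbind(ri[ok], ci[ok])]
  tracks <- tracks[order(tracks$track_id, tracks$frame), ]
  # split at removed points: a kept point that follows a removed point of
  # the same original track starts a new fragment
  new_track <- c(TRUE, diff(as.integer(factor(tracks$track_id))) != 0) | c(TRUE, !ok[-length(ok)])
  frag <- cumsum(new_track)
  kept <- tracks[ok, , drop = FALSE]
  frag <- frag[ok]
  if (!nrow(kept)) return(empty_track_set())
  len <- table(frag)
  keep_frag <- names(len)[len >= 2]
  sel <- frag %in% keep_frag
  kept <- kept[sel, , drop = FALSE]
  frag <- frag[sel]
  if (!nrow(kept)) return(empty_track_set())
  kept$track_id <- as.integer(factor(frag, levels = unique(frag)))
  rownames(kept) <- NULL
  class(kept) <- c("track_set", "data.frame")
  kept
}

#' Per-frame particle counts and area-normalised density
#'
#' Counts detections falling inside the ROI for every frame, and
#' normalises the mean count by the ROI area, giving the mean particle
#' density in particles per mm^2.
#'
#' @param detections data frame with columns `frame`, `row`, `col`.
#' @param mask a [roi_mask()] (its `area_mm2` must be > 0).
#' @param n_frames total number of frames (default: the largest frame
#'   index present); frames without detections count 0.
#' @return A list: `counts` (integer vector of length `n_frames`),
#'   `mean_count`, `density_mm2`.
#' @export
particle_counts <- function(detections, mask, n_frames = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  if (mask$area_mm2 <= 0) stop("ROI area must be positive")
  if (is.null(n_frames))
    n_frames <- if (nrow(detections)) max(detections$frame) else 0L
  if (n_frames < 1) stop("no frames to count over")
  H <- nrow(mask$mask); W <- ncol(mask$mask)
  if (nrow(detections)) {
    ri <- round(detections$row); ci <- round(detections$col)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    ok[ok] <- mask$mask[cbind(ri[ok], ci[ok])]
    counts <- tabulate(detections$frame[ok], n_frames)
  } else counts <- integer(n_frames)
  mean_count <- mean(counts)
  list(counts = counts, mean_count = mean_count,
       density_mm2 = mean_count / mask$area_mm2)
}

#' Read / write track tables
#'
#' Delimited text with columns `track_id,frame,row,col`.
#' @param tracks a `track_set`.
#' @param path file path.
#' @return [read_tracks()] returns a `track_set`.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks)[, c("track_id", "frame", "row", "col")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("track_set", "data.frame")
  out
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks, %d points over %s frames\n",
              length(unique(x$track_id)), nrow(x),
              if (nrow(x)) diff(range(x$frame)) + 1 else 0))
  invisible(x)
}
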