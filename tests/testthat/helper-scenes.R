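# Shared fixture builders (all synthetic, generated at test time).

circle_outline <- function(center = c(150, 150), radius = 140, n = 99,
                           units = "um") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  roi_outline(cbind(center[1] + radius * sin(th),
                    center[2] + radius * cos(th)), units)
}

square_outline <- function(r0, c0, side, units = "px") {
  roi_outline(rbind(c(r0, c0), c(r0, c0 + side),
                    c(r0 + side, c0 + side), c(r0 + side, c0)), units)
}

# one-vortex scene used by several recovery tests
vortex_scene <- function(seed, omega = 0.5, kind = "rankine",
                         core_radius = 100, n_frames = 100,
                         n_particles = 200, ...) {
  scene_spec(circle_outline(),
             list(flow_field_spec(kind, c(150, 150), core_radius, omega)),
             n_particles = n_particles, n_frames = n_frames,
             canvas_hw_um = c(300, 300), seed = seed,
             appear_rate = 0, vanish_rate = 0, ...)
}

# render one frame with Gaussian spots at given pixel positions
spot_frame <- function(H, W, pos_px, amplitude = 100, sigma = 1.3,
                       background = 0) {
  img <- matrix(background, H, W)
  for (i in seq_len(nrow(pos_px))) {
    rr <- pmax(1, floor(pos_px[i, 1] - 6)):pmin(H, ceiling(pos_px[i, 1] + 6))
    cc <- pmax(1, floor(pos_px[i, 2] - 6)):pmin(W, ceiling(pos_px[i, 2] + 6))
    img[rr, cc] <- img[rr, cc] + amplitude *
      exp(-(outer((rr - pos_px[i, 1])^2, (cc - pos_px[i, 2])^2, `+`)) /
            (2 * sigma^2))
  }
  img
}

# ground-truth tracks (um) converted to a pixel track_set
truth_to_tracks <- function(truth, geometry) {
  tt <- truth$true_tracks
  out <- data.frame(track_id = tt$track_id, frame = tt$frame,
                    row = tt$row_um / geometry$pixel_height_um + 0.5,
                    col = tt$col_um / geometry$pixel_width_um + 0.5)
  class(out) <- c("track_set", "data.frame")
  out
}

# analysis settings used for the phantom studies: detection percentile
# matched to ~200 spots per frame, link gate a few times the largest
# per-frame displacement
phantom_config <- function(seed = 1L) {
  list(intensity_percentile = 2, max_disp = 3, seed = seed)
}

# independent brute-force linker: per frame pair, enumerate all injective
# assignments of open ends (within link_range) to detections gated by
# max_disp and keep the one with maximal matches, then minimal cost.
brute_force_link <- function(detections, max_disp, link_range) {
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  ends <- data.frame(id = integer(0), frame = integer(0),
                     row = numeric(0), col = numeric(0))
  next_id <- 1L
  rows <- list()
  for (f in frames) {
    det_f <- detections[detections$frame == f, c("frame", "row", "col")]
    nd <- nrow(det_f)
    ends <- ends[ends$frame >= f - link_range, , drop = FALSE]
    ne <- nrow(ends)
    best <- NULL
    if (ne && nd) {
      cost <- outer(ends$row, det_f$row, `-`)^2 +
        outer(ends$col, det_f$col, `-`)^2
      cost[cost > max_disp^2] <- NA
      # enumerate assignments detection -> end index or NA
      choices <- lapply(seq_len(nd), function(j) c(NA, which(!is.na(cost[, j]))))
      grid <- expand.grid(choices)
      for (k in seq_len(nrow(grid))) {
        a <- as.integer(grid[k, ])
        used <- a[!is.na(a)]
        if (anyDuplicated(used)) next
        sz <- length(used)
        cst <- sum(cost[cbind(used, which(!is.na(a)))])
        if (is.null(best) || sz > best$sz ||
            (sz == best$sz && cst < best$cst - 1e-12))
          best <- list(a = a, sz = sz, cst = cst)
      }
    }
    a <- if (is.null(best)) rep(NA_integer_, nd) else best$a
    ids <- integer(nd)
    for (j in seq_len(nd)) {
      if (!is.na(a[j])) ids[j] <- ends$id[a[j]]
      else { ids[j] <- next_id; next_id <- next_id + 1L }
    }
    rows[[length(rows) + 1L]] <- cbind(det_f, track_id = ids)
    keep <- if (ne) setdiff(seq_len(ne), a[!is.na(a)]) else integer(0)
    ends <- rbind(ends[keep, , drop = FALSE],
                  data.frame(id = ids, frame = f, row = det_f$row,
                             col = det_f$col))
  }
  out <- do.call(rbind, rows)
  out[order(out$track_id, out$frame), c("track_id", "frame", "row", "col")]
}

# canonical form for comparing track sets regardless of id numbering
canonical_tracks <- function(tr) {
  sp <- split(tr[, c("frame", "row", "col")], tr$track_id)
  sp <- lapply(sp, function(d) {
    rownames(d) <- NULL
    d[order(d$frame), ]
  })
  key <- vapply(sp, function(d) paste(round(unlist(d), 6), collapse = ","), "")
  sp[order(key)]
}
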