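px_geom <- function() pixel_geometry(2.2, 2.2, 0.015)

test_that("velocity samples follow the stated geometry arithmetic", {
  g <- px_geom()
  tr <- data.frame(track_id = 1L, frame = 0:1, row = c(0, 0), col = c(0, 2))
  class(tr) <- c("track_set", "data.frame")
  v <- tracks_to_velocities(tr, g)
  expect_equal(nrow(v), 1)
  expect_equal(v$v_col, 2 * 2.2 / 0.015, tolerance = 1e-12)  # ~293.3 um/s
  expect_equal(v$v_row, 0)
  expect_equal(v$col, 1)  # midpoint

  # static track: zero velocities
  st <- data.frame(track_id = 1L, frame = 1:4, row = rep(5, 4), col = rep(7, 4))
  class(st) <- c("track_set", "data.frame")
  vs <- tracks_to_velocities(st, g)
  expect_true(all(vs$v_row == 0 & vs$v_col == 0))

  # a bridged 2-frame gap contributes no sample
  gp <- data.frame(track_id = 1L, frame = c(1, 2, 4), row = c(0, 1, 3),
                   col = c(0, 0, 0))
  class(gp) <- c("track_set", "data.frame")
  vg <- tracks_to_velocities(gp, g)
  expect_equal(nrow(vg), 1)
})

test_that("window averaging uses ceiling division and per-cell means", {
  g <- px_geom()
  bbox <- c(1, 25, 1, 25)
  s <- data.frame(row = c(5, 5, 5), col = c(5, 6, 7),
                  v_row = c(1, 1, 1), v_col = c(2, 2, 2))
  grid <- window_average(s, 10, bbox, g)
  expect_equal(dim(grid$n), c(3, 3))        # ceil(25/10) per axis
  expect_equal(grid$v_row[1, 1], 1)
  expect_equal(grid$v_col[1, 1], 2)
  expect_equal(grid$n[1, 1], 3L)
  # opposite samples cancel
  s2 <- data.frame(row = c(5, 5), col = c(5, 6), v_row = c(3, -3),
                   v_col = c(1, -1))
  g2 <- window_average(s2, 10, bbox, g)
  expect_equal(g2$v_row[1, 1], 0)
  expect_equal(g2$n[1, 1], 2L)
})

test_that("outlier flagging implements the nearest-rank percentile", {
  g <- px_geom()
  # 100 cells with distinct magnitudes 1..100 -> P97 = 97, remove 98..100
  s <- data.frame(row = rep(seq(5, 95, 10), 10),
                  col = rep(seq(5, 95, 10), each = 10))
  mags <- 1:100
  s$v_row <- 0; s$v_col <- mags
  grid <- window_average(s, 10, c(1, 100, 1, 100), g)
  out <- remove_outliers(grid, 97)
  expect_equal(sum(out$outlier), 3)
  expect_setequal(out$v_col[out$outlier], c(98, 99, 100))
  # all-equal magnitudes: nothing strictly exceeds the percentile
  s$v_col <- 5
  out2 <- remove_outliers(window_average(s, 10, c(1, 100, 1, 100), g), 97)
  expect_equal(sum(out2$outlier), 0)
  expect_error(remove_outliers(window_average(s[0, ], 10, c(1, 10, 1, 10), g)),
               "non-empty")
})

test_that("outlier fraction is bounded by 3% plus one cell for any input", {
  g <- px_geom()
  set.seed(31)
  for (trial in 1:20) {
    n <- sample(5:200, 1)
    pos <- matrix(runif(2 * n, 1, 100), ncol = 2)
    s <- data.frame(row = pos[, 1], col = pos[, 2],
                    v_row = rnorm(n, 0, 10), v_col = rexp(n, 0.1))
    grid <- window_average(s, 5, c(1, 100, 1, 100), g)
    out <- remove_outliers(grid, 97)
    expect_lte(sum(out$outlier), 0.03 * sum(grid$n > 0) + 1)
  }
})

test_that("count-weighted cell means conserve the sample mean exactly", {
  g <- px_geom()
  set.seed(12)
  n <- 500
  s <- data.frame(row = runif(n, 1, 60), col = runif(n, 1, 80),
                  v_row = rnorm(n), v_col = rnorm(n))
  grid <- window_average(s, 10, c(1, 60, 1, 80), g)
  valid <- grid$n > 0
  wmean_r <- sum(grid$v_row[valid] * grid$n[valid]) / sum(grid$n[valid])
  expect_equal(wmean_r, mean(s$v_row), tolerance = 1e-12)
  wmean_c <- sum(grid$v_col[valid] * grid$n[valid]) / sum(grid$n[valid])
  expect_equal(wmean_c, mean(s$v_col), tolerance = 1e-12)
})

test_that("heatmap mass equals the mean in-ROI particle count", {
  g <- pixel_geometry(10, 10, 0.1)
  mask <- roi_mask(square_outline(0.5, 0.5, 100), c(100, 100), g)
  set.seed(4)
  dets <- data.frame(frame = rep(1:20, each = 40),
                     row = runif(800, 1, 100), col = runif(800, 1, 100))
  hm <- density_heatmap(dets, mask, bin_px = 10, n_frames = 20)
  pc <- particle_counts(dets, mask, n_frames = 20)
  mass <- sum(hm$values * hm$bin_area_mm2, na.rm = TRUE)
  expect_equal(mass, pc$mean_count, tolerance = 1e-9)

  # single-bin and empty cases
  one <- data.frame(frame = 1, row = 5, col = 5)
  h1 <- density_heatmap(one, mask, 10, n_frames = 1)
  expect_equal(sum(h1$values > 0, na.rm = TRUE), 1)
  h0 <- density_heatmap(one[0, ], mask, 10, n_frames = 1)
  expect_true(all(h0$values[!is.na(h0$values)] == 0))
})

test_that("uniform detections give near-uniform density within Poisson error", {
  g <- pixel_geometry(10, 10, 0.1)
  mask <- roi_mask(square_outline(0.5, 0.5, 100), c(100, 100), g)
  set.seed(9)
  n_frames <- 200; per_frame <- 50
  dets <- data.frame(frame = rep(seq_len(n_frames), each = per_frame),
                     row = runif(n_frames * per_frame, 1, 100),
                     col = runif(n_frames * per_frame, 1, 100))
  hm <- density_heatmap(dets, mask, bin_px = 10, n_frames = n_frames)
  lambda <- per_frame / 100 * n_frames      # expected count per bin over video
  vals_counts <- hm$values * hm$bin_area_mm2 * n_frames
  z <- abs(vals_counts - lambda) / sqrt(lambda)
  expect_gte(mean(z <= 3, na.rm = TRUE), 0.99)
})

test_that("an ideal solid-body vortex segments into one region of its polarity", {
  # ROI matching the core: no truncation shell inside the ROI
  for (om in c(0.5, -0.5)) {
    sc <- scene_spec(circle_outline(c(150, 150), 99),
                     list(flow_field_spec("solid_body", c(150, 150), 100, om)),
                     canvas_hw_um = c(300, 300), seed = 1)
    grid <- scene_flow_grid(sc, 10)
    # analytic curl inside the core is 2 omega
    curl <- ventriflow:::grid_curl(grid)
    interior <- !is.na(curl)
    expect_equal(median(curl[interior], na.rm = TRUE), 2 * om,
                 tolerance = 0.05)
    regs <- segment_flow_regions(grid, n_shuffles = 200)
    expect_equal(nrow(regs), 1)
    expect_equal(regs$polarity, if (om > 0) "CCW" else "CW")
  }
})

test_that("a zero field yields no flow regions and sparse grids warn", {
  sc <- scene_spec(circle_outline(c(150, 150), 99),
                   list(flow_field_spec("solid_body", c(150, 150), 100, 0)),
                   canvas_hw_um = c(300, 300), seed = 1)
  grid <- scene_flow_grid(sc, 10)
  regs <- segment_flow_regions(grid, circulation_threshold = 1)
  expect_equal(nrow(regs), 0)
  g <- px_geom()
  s <- data.frame(row = c(2, 3), col = c(2, 3), v_row = c(1, 1), v_col = 0:1)
  sparse <- window_average(s, 10, c(1, 20, 1, 20), g)
  expect_warning(segment_flow_regions(sparse, circulation_threshold = 1),
                 "sparse")
})

test_that("angular velocity regression recovers omega from an ideal grid", {
  sc <- scene_spec(circle_outline(c(150, 150), 140),
                   list(flow_field_spec("rankine", c(150, 150), 100, 0.5)),
                   canvas_hw_um = c(300, 300), seed = 1)
  grid <- scene_flow_grid(sc, 10)
  est <- estimate_angular_velocity(grid, c(150, 150), max_radius_um = 100)
  expect_equal(est$omega_rad_s, 0.5, tolerance = 0.03)
  expect_equal(est$polarity, "CCW")
})

test_that("flow grids round-trip through the text format", {
  g <- px_geom()
  set.seed(2)
  s <- data.frame(row = runif(50, 1, 40), col = runif(50, 1, 60),
                  v_row = rnorm(50), v_col = rnorm(50))
  grid <- remove_outliers(window_average(s, 10, c(1, 40, 1, 60), g), 97)
  f <- tempfile(fileext = ".csv")
  write_flow_grid(grid, f)
  back <- read_flow_grid(f)
  expect_equal(back$v_row, grid$v_row)
  expect_equal(back$n, grid$n)
  expect_equal(back$outlier, grid$outlier)
  expect_equal(back$window_px, grid$window_px)
})
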