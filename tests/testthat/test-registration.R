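rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

test_that("outline resampling spaces points equally from the anterior vertex", {
  sq <- square_outline(0, 0, 40, units = "px")
  p4 <- resample_outline(sq, 4)
  # 4 samples on a square = the 4 corners (start at the anterior-most)
  expect_equal(sort(p4[, 1]), c(0, 0, 40, 40))
  expect_equal(sort(p4[, 2]), c(0, 0, 40, 40))

  out <- circle_outline(c(100, 100), 80, n = 57, units = "px")
  p <- resample_outline(out, 100)
  seg <- sqrt(rowSums((rbind(p[-1, ], p[1, ]) - p)^2))
  per <- sum(seg)
  expect_lt(max(abs(seg - per / 100)) / (per / 100), 0.01)
  # starts at the anterior-most (minimum column) point
  expect_equal(as.numeric(p[1, 2]), min(p[, 2]), tolerance = per / 100)

  # resampling a resampled outline moves points only marginally
  p2 <- resample_outline(roi_outline(p, "px"), 100)
  expect_lt(max(abs(p2 - p)), per / 100 * 0.1)
})

test_that("procrustes recovers identity, rotation and scale/shift exactly", {
  set.seed(3)
  ref <- matrix(rnorm(60, sd = 20), 30, 2)
  idt <- procrustes_align(ref, ref)
  expect_equal(idt$rotation, diag(2), tolerance = 1e-12)
  expect_equal(idt$scale, 1, tolerance = 1e-12)
  expect_equal(as.numeric(idt$translation), c(0, 0), tolerance = 1e-10)
  expect_lt(idt$sse, 1e-20)

  mov_rot <- ref %*% t(rot2(90))
  tr <- procrustes_align(ref, mov_rot)
  expect_equal(tr$rotation, rot2(-90), tolerance = 1e-10)
  expect_lt(tr$sse, 1e-10)

  mov_ss <- sweep(2 * ref, 2, c(5, 7), `+`)
  tr2 <- procrustes_align(ref, mov_ss)
  expect_equal(tr2$scale, 0.5, tolerance = 1e-12)
  expect_equal(as.numeric(tr2$translation), -0.5 * c(5, 7), tolerance = 1e-9)
  expect_lt(tr2$sse, 1e-10)
  expect_equal(transform_points(tr2, mov_ss), ref, tolerance = 1e-9)

  expect_error(procrustes_align(ref, matrix(1, 30, 2)), "coincident")
})

test_that("random similarity transforms are recovered to 1e-6 over 100 trials", {
  set.seed(19)
  ref <- matrix(rnorm(80, sd = 15), 40, 2)
  for (trial in 1:100) {
    ang <- runif(1, -180, 180)
    s <- runif(1, 0.5, 2)
    tv <- runif(2, -50, 50)
    mov <- sweep(s * ref %*% t(rot2(ang)), 2, tv, `+`)
    tr <- procrustes_align(ref, mov)
    # recovered transform is the inverse similarity
    expect_lt(abs(tr$scale - 1 / s), 1e-6)
    expect_lt(max(abs(tr$rotation - rot2(-ang))), 1e-6)
    expect_lt(max(abs(transform_points(tr, mov) - ref)), 1e-6)
    expect_lt(tr$sse, 1e-12)
  }
})

test_that("rotations never reflect even when a reflection fits better", {
  set.seed(23)
  ref <- matrix(rnorm(40, sd = 10), 20, 2)
  mov <- ref[, c(1, 2)] %*% diag(c(1, -1))   # reflected copy
  tr <- procrustes_align(ref, mov)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-12)
})

test_that("procrustes agrees with the vegan reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(6)
  ref <- matrix(rnorm(50, sd = 8), 25, 2)
  mov <- sweep(1.7 * (ref + matrix(rnorm(50), 25, 2)) %*% t(rot2(33)),
               2, c(4, -9), `+`)
  ours <- procrustes_align(ref, mov)
  vg <- vegan::procrustes(ref, mov, scale = TRUE, symmetric = FALSE)
  expect_equal(ours$scale, vg$scale, tolerance = 1e-9)
  expect_equal(t(ours$rotation), unclass(vg$rotation), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(ours$sse, vg$ss, tolerance = 1e-9)
})

test_that("alignment never scores worse than the identity placement", {
  set.seed(41)
  base <- circle_outline(c(120, 150), 90, n = 60, units = "px")
  for (trial in 1:10) {
    pert <- unclass(base) + matrix(rnorm(120, 0, 4), ncol = 2)
    mov <- roi_outline(pert, "px")
    tr <- align_outlines(base, mov, 80)
    ref_p <- attr(tr, "reference_points")
    mov_p <- resample_outline(mov, 80)
    sse_identity <- sum((ref_p - mov_p)^2)
    expect_lte(tr$sse, sse_identity + 1e-9)
  }
})

test_that("apply_transform rotates vectors and conserves heatmap mass", {
  g <- pixel_geometry(2, 2, 0.015)
  set.seed(13)
  s <- data.frame(row = runif(300, 1, 60), col = runif(300, 1, 60),
                  v_row = 0, v_col = 10)     # uniform rightward field
  grid <- window_average(s, 10, c(1, 60, 1, 60), g)

  idt <- structure(list(rotation = diag(2), scale = 1, translation = c(0, 0),
                        sse = 0), class = "similarity_transform")
  same <- apply_transform(idt, grid, grid)
  expect_equal(same$v_col, grid$v_col)
  expect_equal(same$n, grid$n)

  # rotate by 90 degrees about the grid centre: (row, col) -> (col, -row)+t
  t90 <- structure(list(rotation = rot2(90), scale = 1,
                        translation = c(62, 0), sse = 0),
                   class = "similarity_transform")
  # (v_row, v_col) = (0, 10) maps to (-10, 0): rightward becomes upward
  # (toward smaller row indices) under this rotation sense
  rot <- apply_transform(t90, grid, grid)
  ok <- rot$n > 0
  expect_true(all(abs(rot$v_col[ok]) < 1e-9))
  expect_equal(unique(round(rot$v_row[ok], 9)), -10)

  # heatmap mass is invariant under scaling
  mask <- roi_mask(square_outline(0.5, 0.5, 60), c(62, 62), g)
  dets <- data.frame(frame = rep(1:5, each = 30),
                     row = runif(150, 1, 60), col = runif(150, 1, 60))
  hm <- density_heatmap(dets, mask, 10, n_frames = 5)
  # target raster covering the doubled extent
  mask2 <- roi_mask(square_outline(0.5, 0.5, 120), c(125, 125), g)
  hm_ref <- density_heatmap(data.frame(frame = 1, row = 60, col = 60),
                            mask2, 10, n_frames = 1)
  t2 <- structure(list(rotation = diag(2), scale = 2, translation = c(0, 0),
                       sse = 0), class = "similarity_transform")
  moved <- apply_transform(t2, hm, hm_ref)
  expect_equal(sum(moved$values * moved$bin_area_mm2, na.rm = TRUE),
               sum(hm$values * hm$bin_area_mm2, na.rm = TRUE),
               tolerance = 1e-9)
})

test_that("group averaging is count-weighted and permutation-invariant", {
  g <- pixel_geometry(2, 2, 0.015)
  set.seed(17)
  grids <- lapply(1:4, function(k) {
    s <- data.frame(row = runif(200, 1, 50), col = runif(200, 1, 50),
                    v_row = rnorm(200, k), v_col = rnorm(200, -k))
    window_average(s, 10, c(1, 50, 1, 50), g)
  })
  avg <- average_group(grids)
  # identical grids average to themselves
  same <- average_group(list(grids[[1]], grids[[1]], grids[[1]]))
  expect_equal(same$v_row, grids[[1]]$v_row)
  # a grid plus its negation cancels
  neg <- grids[[2]]; neg$v_row <- -neg$v_row; neg$v_col <- -neg$v_col
  zero <- average_group(list(grids[[2]], neg))
  ok <- zero$n > 0
  expect_true(all(abs(zero$v_row[ok]) < 1e-12))
  # permutation invariance
  avg2 <- average_group(grids[c(3, 1, 4, 2)])
  expect_equal(avg2$v_row, avg$v_row)
  expect_equal(avg2$n, avg$n)
  expect_error(average_group(list()), "empty")
})

test_that("transforms round-trip through the config text format", {
  tr <- structure(list(rotation = rot2(25), scale = 1.4,
                       translation = c(3, -8), sse = 0.5),
                  class = "similarity_transform")
  f <- tempfile(fileext = ".yml")
  write_transform(tr, f)
  back <- read_transform(f)
  expect_equal(back$rotation, tr$rotation, tolerance = 1e-6)
  expect_equal(back$scale, tr$scale)
  expect_equal(back$translation, tr$translation)
})
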