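test_that("region growing floods a dark cube exactly", {
  vox <- array(100, c(9, 9, 9))
  vox[4:6, 4:6, 4:6] <- 10
  vol <- oct_volume(vox, c(5, 5, 5))
  seg <- region_grow(vol, matrix(c(5, 5, 5), 1), tolerance = 20,
                     connectivity = 6)
  expect_equal(sum(seg$mask), 27)
  expect_true(all(which(seg$mask, arr.ind = TRUE) >= 4 &
                    which(seg$mask, arr.ind = TRUE) <= 6))
  expect_equal(seg$volume_mm3, 27 * 125 / 1e9)
})

test_that("sphere phantom volume is recovered within 3%", {
  ph <- build_volume_phantom(
    volume_phantom_spec(list(c(150, 150, 150, 100, 100, 100)),
                        voxel_dims_um = c(5, 5, 5)))
  seg <- region_grow(ph$volume, phantom_voxel(ph, c(150, 150, 150)))
  expect_lt(abs(seg$volume_mm3 / 4.18879e-3 - 1), 0.03)
})

test_that("one seed segments only the seeded chamber when stenosed", {
  ph <- build_volume_phantom(two_chamber_phantom_spec(0))
  seg <- region_grow(ph$volume, phantom_voxel(ph, c(150, 150, 150)))
  lab <- ventriflow:::label_components(ph$lumen_mask, 6)
  seeded_comp <- lab[phantom_voxel(ph, c(150, 150, 150))]
  expect_equal(seg$mask, lab == seeded_comp)
})

test_that("region growing is seed-invariant, monotone and noise-tolerant", {
  ph <- build_volume_phantom(
    volume_phantom_spec(list(c(100, 120, 100, 60, 80, 60)),
                        voxel_dims_um = c(5, 5, 5)))
  s1 <- region_grow(ph$volume, phantom_voxel(ph, c(100, 120, 100)))
  s2 <- region_grow(ph$volume, phantom_voxel(ph, c(120, 150, 110)))
  expect_equal(s1$mask, s2$mask)   # any interior seed, same region
  # noiseless: mask equals the ground-truth lumen mask exactly
  expect_equal(s1$mask, ph$lumen_mask)
  # monotone in tolerance
  sm <- region_grow(ph$volume, phantom_voxel(ph, c(100, 120, 100)),
                    tolerance = 10)
  lg <- region_grow(ph$volume, phantom_voxel(ph, c(100, 120, 100)),
                    tolerance = 60)
  expect_true(all(lg$mask[sm$mask]))
  # with noise up to 20% of the contrast, volume error <= 5%
  phn <- build_volume_phantom(
    volume_phantom_spec(list(c(100, 120, 100, 60, 80, 60)),
                        noise_sd = 20, voxel_dims_um = c(5, 5, 5), seed = 2))
  sn <- region_grow(phn$volume, phantom_voxel(phn, c(100, 120, 100)))
  truth <- sum(phn$lumen_mask) * 125 / 1e9
  expect_lt(abs(sn$volume_mm3 / truth - 1), 0.05)
  # a tissue seed is rejected
  expect_error(region_grow(ph$volume, matrix(c(1, 1, 1), 1)), "brighter")
})

test_that("manual slice interpolation blends signed distance level sets", {
  disk <- function(r, n = 61) {
    d <- outer(seq_len(n) - 31, seq_len(n) - 31, function(i, j) i^2 + j^2)
    d <= r^2
  }
  # identical annotations propagate unchanged
  seg <- interpolate_manual(list(`1` = disk(12), `11` = disk(12)), 11,
                            c(5, 5, 5))
  for (z in 1:11) expect_equal(seg$mask[z, , ], disk(12))
  # concentric disks r = 10 and 20: midpoint radius within 1 px of 15
  seg2 <- interpolate_manual(list(`1` = disk(10), `11` = disk(20)), 11,
                             c(5, 5, 5))
  mid <- seg2$mask[6, , ]
  r_mid <- sqrt(sum(mid) / pi)
  expect_lt(abs(r_mid - 15), 1)
  # annotations on every slice reproduce the direct voxel count
  full <- lapply(1:5, function(z) disk(8 + z))
  names(full) <- 1:5
  seg3 <- interpolate_manual(full, 5, c(5, 5, 5))
  expect_equal(sum(seg3$mask), sum(vapply(full, sum, numeric(1))))
  expect_error(interpolate_manual(list(`1` = disk(5)), 5, c(5, 5, 5)),
               "at least 2")
})

test_that("interpolation error shrinks as annotated slices densify", {
  ph <- build_volume_phantom(
    volume_phantom_spec(list(c(100, 120, 100, 60, 80, 60)),
                        voxel_dims_um = c(5, 5, 5)))
  nz <- dim(ph$lumen_mask)[1]
  truth <- sum(ph$lumen_mask)
  errs <- vapply(c(8, 4, 2, 1), function(k) {
    zs <- unique(c(seq(1, nz, by = k), nz))
    masks <- lapply(zs, function(z) ph$lumen_mask[z, , ])
    names(masks) <- zs
    seg <- interpolate_manual(masks, nz, c(5, 5, 5))
    abs(sum(seg$mask) - truth) / truth
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[3], 0.05)
  expect_equal(errs[4], 0)
})

test_that("compare_methods returns the absolute-error mean and sample SD", {
  expect_equal(compare_methods(c(1, 2, 3), c(1, 2, 3)),
               list(mean_error_mm3 = 0, sd_error_mm3 = 0, n = 3L))
  got <- compare_methods(c(0.105, 0.206), c(0.101, 0.198))
  expect_equal(got$mean_error_mm3, 0.006, tolerance = 1e-12)
  expect_equal(got$sd_error_mm3, 0.004 / sqrt(2), tolerance = 1e-12)
  expect_equal(round(got$sd_error_mm3, 8), 0.00282843)
  expect_error(compare_methods(1:3, 1:4), "length")
  expect_error(compare_methods(1, 1), "at least 2")
})

test_that("morphometry reports analytic extents and aqueduct patency", {
  ph <- build_volume_phantom(
    volume_phantom_spec(list(c(150, 250, 120, 50, 200, 100)),
                        voxel_dims_um = c(5, 5, 5)))
  seg <- region_grow(ph$volume, phantom_voxel(ph, c(150, 250, 120)))
  m <- morphometry(seg)
  expect_equal(m$chambers$ap_length_um, 400, tolerance = 5 / 400 * 2)
  expect_equal(m$chambers$dv_height_um, 100, tolerance = 5 / 100 * 2)
  expect_equal(m$chambers$lr_width_um, 200, tolerance = 5 / 200 * 2)

  # stenosed phantom: two chambers, not patent
  sten <- build_volume_phantom(two_chamber_phantom_spec(0))
  seg_s <- region_grow(sten$volume, phantom_voxel(sten, c(150, 150, 150)))
  seg_s$mask <- sten$lumen_mask   # assess the full system
  span <- range(phantom_voxel(sten, rbind(c(150, 255, 150),
                                          c(150, 305, 150)))[, 2])
  m_s <- morphometry(seg_s, aqueduct_span_y = span)
  expect_false(m_s$patent)
  expect_equal(nrow(m_s$chambers), 2)

  # open phantom: patent, min cross-section near pi r^2
  open <- build_volume_phantom(two_chamber_phantom_spec(20))
  seg_o <- region_grow(open$volume, phantom_voxel(open, c(150, 150, 150)))
  span_o <- range(phantom_voxel(open, rbind(c(150, 255, 150),
                                            c(150, 305, 150)))[, 2])
  m_o <- morphometry(seg_o, aqueduct_span_y = span_o)
  expect_true(m_o$patent)
  expect_lt(abs(m_o$aqueduct_min_area_um2 / (pi * 20^2) - 1), 0.3)
  expect_error(morphometry(structure(list(mask = array(FALSE, c(2, 2, 2)),
                                          voxel_dims_um = c(5, 5, 5)),
                                     class = "segmentation_result")),
               "empty")
})
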