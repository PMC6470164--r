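test_that("field velocity matches the closed-form vortex profiles", {
  f <- flow_field_spec("solid_body", c(100, 100), 50, 0.4)
  # zero at the centre
  expect_equal(as.numeric(field_velocity(f, c(100, 100))), c(0, 0))
  # |v| = |omega| r inside the core, 0 outside
  v <- field_velocity(f, c(100, 130))
  expect_equal(sqrt(sum(v^2)), 0.4 * 30)
  expect_equal(as.numeric(field_velocity(f, c(100, 170))), c(0, 0))
  # rankine decays as R^2 |omega| / r outside
  fr <- flow_field_spec("rankine", c(100, 100), 50, -0.4)
  v2 <- field_velocity(fr, c(200, 100))
  expect_equal(sqrt(sum(v2^2)), 50^2 * 0.4 / 100)
})

test_that("superposition: scene velocity is the vector sum of fields", {
  fields <- list(flow_field_spec("solid_body", c(80, 80), 60, 0.3),
                 flow_field_spec("rankine", c(200, 150), 40, -0.7),
                 flow_field_spec("rankine", c(120, 260), 50, 0.2))
  set.seed(11)
  pts <- cbind(runif(100, 0, 300), runif(100, 0, 300))
  total <- scene_velocity(fields, pts)
  manual <- Reduce(`+`, lapply(fields, field_velocity, pts_um = pts))
  expect_equal(total, manual, tolerance = 1e-12)
})

test_that("discrete circulation around an in-core circle has the sign of omega", {
  for (om in c(0.5, -0.5)) {
    f <- flow_field_spec("solid_body", c(150, 150), 100, om)
    th <- seq(0, 2 * pi, length.out = 201)[-1]
    pts <- cbind(150 + 50 * sin(th), 150 + 50 * cos(th))
    v <- field_velocity(f, pts)
    dl <- rbind(pts[-1, ], pts[1, ]) - pts
    circ <- sum(v[, 1] * dl[, 1] + v[, 2] * dl[, 2])
    expect_equal(sign(circ), sign(om))
  }
})

test_that("wildtype scene encodes the five-field anterior-posterior layout", {
  sc <- wildtype_scene(seed = 1)
  expect_length(sc$fields, 5)
  om <- vapply(sc$fields, function(f) f$omega_rad_s, numeric(1))
  pol <- ifelse(om < 0, "CW", "CCW")
  expect_equal(pol, c("CW", "CCW", "CCW", "CW", "CCW"))
  # posterior rhombencephalic field is fastest; the two anterior slowest
  expect_true(abs(om[5]) > abs(om[1]) && abs(om[5]) > abs(om[2]))
  expect_true(max(abs(om[1:2])) <= min(abs(om[3:5])))
  # ordered anterior -> posterior
  centers <- t(vapply(sc$fields, function(f) f$center_um, numeric(2)))
  expect_true(all(diff(centers[, 2]) > 0))
  # layout is seed-invariant, particles are not
  sc2 <- wildtype_scene(seed = 2)
  expect_equal(sc$fields, sc2$fields)
  expect_equal(unclass(sc$outline), unclass(sc2$outline))
  p1 <- simulate_video(wildtype_scene(seed = 1, n_frames = 2, n_particles = 20))
  p2 <- simulate_video(wildtype_scene(seed = 2, n_frames = 2, n_particles = 20))
  f1 <- subset(p1$truth$true_tracks, frame == 1)
  f2 <- subset(p2$truth$true_tracks, frame == 1)
  expect_false(isTRUE(all.equal(f1$row_um, f2$row_um)))
})

test_that("zero-velocity zero-diffusion scenes give constant tracks", {
  sc <- scene_spec(circle_outline(), list(), n_particles = 30, n_frames = 5,
                   canvas_hw_um = c(300, 300), diffusion_sd = 0,
                   appear_rate = 0, vanish_rate = 0, seed = 3)
  sim <- simulate_video(sc)
  sp <- split(sim$truth$true_tracks, sim$truth$true_tracks$track_id)
  for (d in sp) {
    expect_equal(diff(range(d$row_um)), 0)
    expect_equal(diff(range(d$col_um)), 0)
  }
})

test_that("solid-body advection moves particles by |omega| r dt per frame", {
  sc <- vortex_scene(seed = 5, omega = 0.5, kind = "solid_body",
                     n_frames = 3, n_particles = 40, diffusion_sd = 0)
  sim <- simulate_video(sc)
  tt <- sim$truth$true_tracks
  sp <- split(tt, tt$track_id)
  dt <- sc$geometry$frame_interval_s
  for (d in sp[1:10]) {
    r <- sqrt((d$row_um[1] - 150)^2 + (d$col_um[1] - 150)^2)
    if (r > 99) next  # skip the core edge where reflection may kick in
    step <- sqrt(diff(d$row_um)[1]^2 + diff(d$col_um)[1]^2)
    expect_equal(step, 0.5 * r * dt, tolerance = 1e-9)
  }
})

test_that("particle number is conserved without appearance/disappearance", {
  sc <- vortex_scene(seed = 9, n_frames = 20, n_particles = 50)
  sim <- simulate_video(sc)
  counts <- table(sim$truth$true_tracks$frame)
  expect_equal(as.numeric(counts), rep(50, 20))
  # and every truth position stays inside the outline
  inside <- ventriflow:::points_in_polygon(
    cbind(sim$truth$true_tracks$row_um, sim$truth$true_tracks$col_um),
    unclass(sc$outline))
  expect_true(all(inside))
})

test_that("volume phantom reproduces the analytic sphere volume", {
  spec <- volume_phantom_spec(list(c(150, 150, 150, 100, 100, 100)),
                              voxel_dims_um = c(5, 5, 5))
  ph <- build_volume_phantom(spec)
  expect_equal(ph$true_volume_mm3, 4 / 3 * pi * 1e-3, tolerance = 1e-12)
  # voxelised mask within one surface-voxel shell of the analytic volume
  vox_mm3 <- sum(ph$lumen_mask) * prod(spec$voxel_dims_um) / 1e9
  shell_mm3 <- 4 * pi * 100^2 * 5 / 1e9  # surface area x voxel pitch
  expect_lt(abs(vox_mm3 - ph$true_volume_mm3), shell_mm3)
})

test_that("aqueduct radius controls lumen topology", {
  sten <- build_volume_phantom(two_chamber_phantom_spec(0))
  open <- build_volume_phantom(two_chamber_phantom_spec(20))
  lab_s <- ventriflow:::label_components(sten$lumen_mask, 6)
  lab_o <- ventriflow:::label_components(open$lumen_mask, 6)
  expect_gte(max(lab_s), 2)
  expect_equal(max(lab_o), 1)
  # stenosis contributes no aqueduct volume
  expect_equal(sten$true_volume_mm3,
               4 / 3 * pi * (100^3 + 80^3) / 1e9, tolerance = 1e-12)
  expect_gt(open$true_volume_mm3, sten$true_volume_mm3)
})

test_that("phantom construction rejects invalid specifications", {
  expect_error(volume_phantom_spec(list(c(0, 0, 0, 50, 50, 50),
                                        c(10, 10, 10, 50, 50, 50))),
               "overlap")
  expect_error(volume_phantom_spec(list(c(0, 0, 0, 50, 50, 50)),
                                   lumen_level = 100, tissue_level = 50))
  expect_error(volume_phantom_spec(list(c(0, 0, 0, 50, 50, 50)),
                                   voxel_dims_um = c(0, 5, 5)))
  expect_error(scene_spec(circle_outline(), list(), n_frames = 1), "n_frames")
  expect_error(scene_spec(circle_outline(), list(), appear_rate = 1.5))
})

test_that("scene and ground-truth files round-trip", {
  sc <- wildtype_scene(seed = 4, n_frames = 3, n_particles = 15)
  p <- tempfile(fileext = ".yml")
  write_scene(sc, p)
  sc2 <- read_scene(p)
  expect_equal(sc2$fields, sc$fields)
  expect_equal(unclass(sc2$outline), unclass(sc$outline), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(sc2$seed, sc$seed)
  sim <- simulate_video(sc)
  f <- tempfile(fileext = ".csv")
  write_ground_truth(sim$truth, f)
  back <- utils::read.csv(f)
  expect_equal(back$row_um, sim$truth$true_tracks$row_um, tolerance = 1e-9)
})
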