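#' Specify a single vortical flow field
#'
#' Velocity model for one circulating CSF flow field. Positions and
#' velocities live in micrometre image coordinates with row increasing
#' downward (dorsal at row 0). The rotation sense of `omega` is defined
#' through the discrete circulation: `omega > 0` gives positive
#' circulation in the (row, col) frame and is labelled counter-clockwise
#' (CCW); `omega < 0` is clockwise (CW).
#'
#' `solid_body` fields rotate rigidly inside `core_radius_um` (tangential
#' speed `|omega| * r`) and are zero outside. `rankine` fields keep the
#' rigid core but decay outside as `core_radius_um^2 * |omega| / r`, the
#' classic Rankine vortex.
#'
#' @param kind `"solid_body"` or `"rankine"`.
#' @param center_um numeric (row, col) centre in micrometres.
#' @param core_radius_um core radius in micrometres, > 0.
#' @param omega_rad_s signed angular velocity in rad/s.
#' @return An object of class `flow_field_spec`.
#' @export
flow_field_spec <- function(kind = c("solid_body", "rankine"), center_um,
                            core_radius_um, omega_rad_s) {
  kind <- match.arg(kind)
  if (length(center_um) != 2L || !all(is.finite(center_um)))
    stop("center_um must be finite (row, col)")
  if (!is.finite(core_radius_um) || core_radius_um <= 0)
    stop("core_radius_um must be > 0")
  if (!is.finite(omega_rad_s)) stop("omega_rad_s must be finite")
  structure(list(kind = kind, center_um = as.numeric(center_um),
                 core_radius_um = core_radius_um, omega_rad_s = omega_rad_s),
            class = "flow_field_spec")
}

#' Evaluate the velocity of one flow field at given positions
#'
#' @param field a [flow_field_spec()].
#' @param pts_um matrix with columns (row, col) in micrometres.
#' @return Matrix with columns (v_row, v_col) in um/s.
#' @export
field_velocity <- function(field, pts_um) {
  pts_um <- matrix(pts_um, ncol = 2)
  dr <- pts_um[, 1] - field$center_um[1]
  dc <- pts_um[, 2] - field$center_um[2]
  r <- sqrt(dr^2 + dc^2)
  w <- field$omega_rad_s
  # rigid rotation: v_row = omega * dc, v_col = -omega * dr
  v <- cbind(w * dc, -w * dr)
  outside <- r > field$core_radius_um
  if (any(outside)) {
    if (field$kind == "solid_body") {
      v[outside, ] <- 0
    } else {
      fac <- (field$core_radius_um / r[outside])^2
      v[outside, ] <- v[outside, , drop = FALSE] * fac
    }
  }
  v[r == 0, ] <- 0
  colnames(v) <- c("v_row", "v_col")
  v
}

#' Superposed velocity of a list of flow fields
#'
#' @param fields list of [flow_field_spec()].
#' @param pts_um matrix with columns (row, col) in micrometres.
#' @return Matrix with columns (v_row, v_col) in um/s, the vector sum of
#'   every field's contribution.
#' @export
scene_velocity <- function(fields, pts_um) {
  pts_um <- matrix(pts_um, ncol = 2)
  v <- matrix(0, nrow(pts_um), 2)
  for (f in fields) v <- v + field_velocity(f, pts_um)
  colnames(v) <- c("v_row", "v_col")
  v
}

#' Specify a synthetic particle-video scene
#'
#' Bundles everything needed to simulate an OCT-like B-scan video of
#' free-floating particles advected by prescribed vortical flow fields
#' inside a ventricle-shaped ROI.
#'
#' @param outline a [roi_outline()] in micrometres bounding the lumen.
#' @param fields list of [flow_field_spec()].
#' @param n_particles initial particle count.
#' @param diameter_range_um particle diameter range (uniform), um.
#' @param psf_sigma_um optical point-spread sigma, um.
#' @param background_level,speckle_sd background intensity and additive
#'   speckle noise SD (arbitrary intensity units).
#' @param particle_amplitude peak intensity of a rendered particle above
#'   background.
#' @param n_frames number of frames, >= 2.
#' @param geometry a [pixel_geometry()].
#' @param diffusion_sd random-walk step SD per frame, um.
#' @param appear_rate,vanish_rate per-particle per-frame probabilities of
#'   a new particle appearing / an existing one vanishing, in `[0, 1]`.
#' @param canvas_hw_um physical (height, width) of the rendered frame, um.
#' @param seed integer seed; all randomness in the simulation flows from it.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(outline, fields, n_particles = 220,
                       diameter_range_um = c(3.57, 3.88), psf_sigma_um = 2,
                       background_level = 20, speckle_sd = 6,
                       particle_amplitude = 120, n_frames = 300,
                       geometry = pixel_geometry(2.2, 2.2, 0.015),
                       diffusion_sd = 0.15, appear_rate = 0.001,
                       vanish_rate = 0.001, canvas_hw_um = NULL, seed = 1L) {
  stopifnot(inherits(outline, "roi_outline"), attr(outline, "units") == "um")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (diff(diameter_range_um) < 0 || diameter_range_um[1] <= 0)
    stop("diameter_range_um must be a positive interval")
  if (appear_rate < 0 || appear_rate > 1 || vanish_rate < 0 || vanish_rate > 1)
    stop("appear/vanish rates must be in [0, 1]")
  if (is.null(canvas_hw_um))
    canvas_hw_um <- c(max(outline[, 1]) + 20, max(outline[, 2]) + 20)
  structure(list(outline = outline, fields = fields,
                 n_particles = as.integer(n_particles),
                 diameter_range_um = diameter_range_um,
                 psf_sigma_um = psf_sigma_um,
                 background_level = background_level, speckle_sd = speckle_sd,
                 particle_amplitude = particle_amplitude,
                 n_frames = as.integer(n_frames), geometry = geometry,
                 diffusion_sd = diffusion_sd, appear_rate = appear_rate,
                 vanish_rate = vanish_rate,
                 canvas_hw_um = as.numeric(canvas_hw_um),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(paste0("scene_spec: %d fields, %d particles, %d frames, ",
                     "canvas %.0f x %.0f um, seed %d\n"),
              length(x$fields), x$n_particles, x$n_frames,
              x$canvas_hw_um[1], x$canvas_hw_um[2], x$seed))
  invisible(x)
}

# Union of ellipses and axis-aligned rectangles rasterised on a um grid,
# traced to a single closed polygon.
trace_union_outline <- function(ellipses, rects, canvas_hw_um, step_um = 2) {
  rr <- seq(0, canvas_hw_um[1], by = step_um)
  cc <- seq(0, canvas_hw_um[2], by = step_um)
  z <- matrix(0, length(rr), length(cc))
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  for (e in ellipses)
    z[((R - e[1]) / e[3])^2 + ((C - e[2]) / e[4])^2 <= 1] <- 1
  for (rct in rects)
    z[R >= rct[1] & R <= rct[2] & C >= rct[3] & C <= rct[4]] <- 1
  cl <- grDevices::contourLines(rr, cc, z, levels = 0.5)
  best <- cl[[which.max(vapply(cl, function(s) length(s$x), numeric(1)))]]
  poly <- cbind(best$x, best$y)
  keep <- seq(1, nrow(poly), by = 3)
  roi_outline(poly[keep, , drop = FALSE], "um")
}

#' Wild-type mid-sagittal ventricle scene with five flow fields
#'
#' Builds the reference phantom: a four-chambered mid-sagittal
#' ventricular outline (lateral, third, midbrain and fourth ventricle
#' lobes connected by narrow aqueducts, anterior at low column index)
#' containing five vortical flow fields numbered FF1..FF5 anterior to
#' posterior. FF1 and FF4 are clockwise, FF2, FF3 and FF5
#' counter-clockwise; FF5 has the largest angular speed (the posterior
#' rhombencephalic field is the largest and fastest), FF1 and FF2 the
#' smallest. The layout is fixed; the seed only controls particle
#' initialisation and noise.
#'
#' @param seed integer seed passed to the scene.
#' @param n_frames number of frames (default 300).
#' @param n_particles initial particle count (default 220).
#' @param ... further arguments passed to [scene_spec()].
#' @return A [scene_spec()] with exactly five fields and attribute
#'   `polarity` giving the CW/CCW pattern.
#' @export
wildtype_scene <- function(seed = 1L, n_frames = 300, n_particles = 220, ...) {
  canvas <- c(260, 800)
  ellipses <- list(c(130, 130, 90, 110),   # lateral ventricle
                   c(130, 295, 55, 62),    # third ventricle
                   c(130, 450, 70, 85),    # midbrain ventricle
                   c(130, 640, 85, 120))   # fourth ventricle
  rects <- list(c(118, 142, 230, 300),     # aqueduct lateral-third
                c(118, 142, 350, 390),     # cerebral aqueduct third-midbrain
                c(118, 142, 515, 545))     # aqueduct midbrain-fourth
  outline <- trace_union_outline(ellipses, rects, canvas)
  # Rankine profiles: the irrotational exterior avoids the spurious
  # opposite-sign curl ring a hard-truncated core would produce
  fields <- list(
    flow_field_spec("rankine", c(130,  75), 45, -0.25),  # FF1 CW
    flow_field_spec("rankine", c(130, 185), 45, +0.25),  # FF2 CCW
    flow_field_spec("rankine", c(130, 450), 55, +0.45),  # FF3 CCW
    flow_field_spec("rankine", c(130, 565), 40, -0.45),  # FF4 CW
    flow_field_spec("rankine", c(130, 690), 55, +0.80))  # FF5 CCW
  sc <- scene_spec(outline, fields, n_particles = n_particles,
                   n_frames = n_frames, canvas_hw_um = canvas, seed = seed, ...)
  attr(sc, "polarity") <- c("CW", "CCW", "CCW", "CW", "CCW")
  sc
}

# uniform rejection sampling of points inside an outline (um coordinates)
sample_in_outline <- function(n, outline, canvas_hw_um) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    cand <- cbind(stats::runif(m, 0, canvas_hw_um[1]),
                  stats::runif(m, 0, canvas_hw_um[2]))
    keep <- points_in_polygon(cand, unclass(outline))
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a particle video from a scene specification
#'
#' Particles are advected each frame by the superposed field velocity
#' (`x_{t+1} = x_t + v(x_t) dt + diffusion`), reflected at the ROI
#' boundary, and may vanish or be replaced by newly appearing particles
#' at the configured rates. Frames are rendered as Gaussian spots on a
#' speckled background. The returned ground truth records exact
#' subpixel positions in micrometres.
#'
#' @param scene a [scene_spec()].
#' @return A list with elements
#'   `video` (an [oct_video()]),
#'   `truth` (list: `true_tracks` data frame with columns
#'   `track_id, frame, row_um, col_um`; `velocity_function(pts_um)`;
#'   `expected_density_mm2`), and `scene`.
#' @export
simulate_video <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  g <- scene$geometry
  dt <- g$frame_interval_s
  if (dt <= 0) stop("frame interval must be positive")
  if (scene$n_frames < 2) stop("n_frames must be >= 2")
  set.seed(scene$seed)
  H <- ceiling(scene$canvas_hw_um[1] / g$pixel_height_um)
  W <- ceiling(scene$canvas_hw_um[2] / g$pixel_width_um)
  poly <- unclass(scene$outline)

  pos <- sample_in_outline(scene$n_particles, scene$outline, scene$canvas_hw_um)
  ids <- seq_len(scene$n_particles)
  next_id <- scene$n_particles + 1L
  diam <- stats::runif(scene$n_particles, scene$diameter_range_um[1],
                       scene$diameter_range_um[2])
  sigma_um <- function(d) sqrt((d / 2.355)^2 + scene$psf_sigma_um^2)
  sig <- sigma_um(diam)

  frames <- array(0, c(scene$n_frames, H, W))
  rec <- vector("list", scene$n_frames)
  for (f in seq_len(scene$n_frames)) {
    rec[[f]] <- data.frame(track_id = ids, frame = f,
                           row_um = pos[, 1], col_um = pos[, 2])
    frames[f, , ] <- render_frame(pos, sig, scene, H, W)
    if (f == scene$n_frames) break
    # advect with boundary reflection
    v <- scene_velocity(scene$fields, pos)
    step <- v * dt
    if (scene$diffusion_sd > 0)
      step <- step + matrix(stats::rnorm(length(pos), 0, scene$diffusion_sd),
                            ncol = 2)
    prop <- pos + step
    inside <- points_in_polygon(prop, poly)
    bad <- which(!inside)
    if (length(bad)) {
      refl <- pos[bad, , drop = FALSE] - step[bad, , drop = FALSE]
      ok <- points_in_polygon(refl, poly)
      prop[bad[ok], ] <- refl[ok, , drop = FALSE]
      prop[bad[!ok], ] <- pos[bad[!ok], , drop = FALSE]
    }
    pos <- prop
    # vanish / appear
    if (scene$vanish_rate > 0 && length(ids)) {
      gone <- stats::runif(length(ids)) < scene$vanish_rate
      pos <- pos[!gone, , drop = FALSE]; ids <- ids[!gone]; sig <- sig[!gone]
    }
    if (scene$appear_rate > 0) {
      n_new <- stats::rbinom(1, scene$n_particles, scene$appear_rate)
      if (n_new > 0) {
        pos <- rbind(pos, sample_in_outline(n_new, scene$outline,
                                            scene$canvas_hw_um))
        ids <- c(ids, seq(next_id, length.out = n_new))
        next_id <- next_id + n_new
        sig <- c(sig, sigma_um(stats::runif(n_new, scene$diameter_range_um[1],
                                            scene$diameter_range_um[2])))
      }
    }
  }
  truth <- do.call(rbind, rec)
  truth <- truth[order(truth$track_id, truth$frame), ]
  rownames(truth) <- NULL
  area_mm2 <- abs(polygon_signed_area(scene$outline)) / 1e6
  list(video = oct_video(frames, g),
       truth = list(true_tracks = truth,
                    velocity_function = function(pts_um)
                      scene_velocity(scene$fields, pts_um),
                    expected_density_mm2 = scene$n_particles / area_mm2),
       scene = scene)
}

render_frame <- function(pos_um, sigma_um, scene, H, W) {
  g <- scene$geometry
  img <- matrix(scene$background_level, H, W)
  if (scene$speckle_sd > 0)
    img <- img + matrix(stats::rnorm(H * W, 0, scene$speckle_sd), H, W)
  if (nrow(pos_um)) {
    pr <- pos_um[, 1] / g$pixel_height_um + 0.5
    pc <- pos_um[, 2] / g$pixel_width_um + 0.5
    sr <- sigma_um / g$pixel_height_um
    sc <- sigma_um / g$pixel_width_um
    for (i in seq_len(nrow(pos_um))) {
      r0 <- max(1L, floor(pr[i] - 4 * sr[i])); r1 <- min(H, ceiling(pr[i] + 4 * sr[i]))
      c0 <- max(1L, floor(pc[i] - 4 * sc[i])); c1 <- min(W, ceiling(pc[i] + 4 * sc[i]))
      if (r0 > r1 || c0 > c1) next
      rr <- r0:r1; cc <- c0:c1
      gr <- exp(-(rr - pr[i])^2 / (2 * sr[i]^2))
      gc <- exp(-(cc - pc[i])^2 / (2 * sc[i]^2))
      img[rr, cc] <- img[rr, cc] + scene$particle_amplitude * outer(gr, gc)
    }
  }
  pmax(img, 0)
}

#' Write the ground truth of a simulation as delimited text
#'
#' One row per particle-frame: `track_id, frame, row_um, col_um`.
#'
#' @param truth the `truth` element returned by [simulate_video()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth$true_tracks, path, row.names = FALSE)
  invisible(path)
}

#' Write a scene specification as a YAML config
#'
#' @param scene a [scene_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  fl <- lapply(scene$fields, function(f)
    list(kind = f$kind, center_um = f$center_um,
         core_radius_um = f$core_radius_um, omega_rad_s = f$omega_rad_s))
  yaml::write_yaml(list(
    outline_row_um = as.numeric(scene$outline[, 1]),
    outline_col_um = as.numeric(scene$outline[, 2]),
    fields = fl, n_particles = scene$n_particles,
    diameter_range_um = scene$diameter_range_um,
    psf_sigma_um = scene$psf_sigma_um,
    background_level = scene$background_level, speckle_sd = scene$speckle_sd,
    particle_amplitude = scene$particle_amplitude, n_frames = scene$n_frames,
    pixel_height_um = scene$geometry$pixel_height_um,
    pixel_width_um = scene$geometry$pixel_width_um,
    frame_interval_s = scene$geometry$frame_interval_s,
    diffusion_sd = scene$diffusion_sd, appear_rate = scene$appear_rate,
    vanish_rate = scene$vanish_rate, canvas_hw_um = scene$canvas_hw_um,
    seed = scene$seed), path)
  invisible(path)
}

#' Read a scene specification written by [write_scene()]
#'
#' @param path YAML path.
#' @return A [scene_spec()].
#' @export
read_scene <- function(path) {
  y <- yaml::read_yaml(path)
  fields <- lapply(y$fields, function(f)
    flow_field_spec(f$kind, f$center_um, f$core_radius_um, f$omega_rad_s))
  scene_spec(roi_outline(cbind(y$outline_row_um, y$outline_col_um), "um"),
             fields, n_particles = y$n_particles,
             diameter_range_um = y$diameter_range_um,
             psf_sigma_um = y$psf_sigma_um,
             background_level = y$background_level, speckle_sd = y$speckle_sd,
             particle_amplitude = y$particle_amplitude, n_frames = y$n_frames,
             geometry = pixel_geometry(y$pixel_height_um, y$pixel_width_um,
                                       y$frame_interval_s),
             diffusion_sd = y$diffusion_sd, appear_rate = y$appear_rate,
             vanish_rate = y$vanish_rate, canvas_hw_um = y$canvas_hw_um,
             seed = y$seed)
}

#' Specify a 3D ventricle phantom
#'
#' Chambers are axis-aligned ellipsoids in (z, y, x) micrometre
#' coordinates (z dorsal-ventral, y anterior-posterior, x left-right),
#' required to be pairwise disjoint (checked on bounding boxes).
#' Consecutive chambers are joined by a cylindrical aqueduct of radius
#' `aqueduct_radius_um` along the segment between their centres;
#' radius 0 encodes aqueductal stenosis (no connection). The analytic
#' volume is the sum of ellipsoid volumes plus, for each open aqueduct,
#' a cylinder spanning the gap between the two ellipsoid surfaces.
#'
#' @param chambers list of numeric length-6 vectors
#'   `(cz, cy, cx, az, ay, ax)`: centre and semi-axes in um.
#' @param aqueduct_radius_um aqueduct radius in um, >= 0 (0 = stenosed).
#' @param lumen_level,tissue_level intensities, `lumen_level < tissue_level`.
#' @param noise_sd additive Gaussian noise SD.
#' @param voxel_dims_um (z, y, x) voxel pitch in um.
#' @param seed integer seed for the noise.
#' @return An object of class `volume_phantom_spec`.
#' @export
volume_phantom_spec <- function(chambers, aqueduct_radius_um = 0,
                                lumen_level = 20, tissue_level = 120,
                                noise_sd = 0, voxel_dims_um = c(5, 5, 5),
                                seed = 1L) {
  chambers <- lapply(chambers, as.numeric)
  if (!length(chambers) || any(vapply(chambers, length, 1L) != 6L))
    stop("each chamber is (cz, cy, cx, az, ay, ax)")
  if (aqueduct_radius_um < 0) stop("aqueduct_radius_um must be >= 0")
  if (lumen_level >= tissue_level) stop("lumen_level must be < tissue_level")
  if (any(voxel_dims_um <= 0)) stop("voxel dims must be positive")
  if (length(chambers) > 1) {
    for (i in seq_len(length(chambers) - 1L)) for (j in (i + 1):length(chambers)) {
      a <- chambers[[i]]; b <- chambers[[j]]
      if (all(abs(a[1:3] - b[1:3]) <= a[4:6] + b[4:6]))
        stop("chambers overlap (bounding boxes intersect)")
    }
  }
  structure(list(chambers = chambers, aqueduct_radius_um = aqueduct_radius_um,
                 lumen_level = lumen_level, tissue_level = tissue_level,
                 noise_sd = noise_sd, voxel_dims_um = as.numeric(voxel_dims_um),
                 seed = as.integer(seed)),
            class = "volume_phantom_spec")
}

#' Build a 3D ventricle phantom with analytic ground truth
#'
#' @param spec a [volume_phantom_spec()].
#' @return A list: `volume` (an [oct_volume()] with noise applied),
#'   `lumen_mask` (noiseless logical Z x Y x X ground-truth mask),
#'   `true_volume_mm3` (analytic lumen volume), `spec`.
#' @export
build_volume_phantom <- function(spec) {
  stopifnot(inherits(spec, "volume_phantom_spec"))
  vd <- spec$voxel_dims_um
  ch <- do.call(rbind, spec$chambers)
  margin <- 4 * vd
  lo <- pmax(0, apply(ch[, 1:3, drop = FALSE] - ch[, 4:6, drop = FALSE], 2, min) - margin)
  hi <- apply(ch[, 1:3, drop = FALSE] + ch[, 4:6, drop = FALSE], 2, max) + margin
  dims <- ceiling((hi - lo) / vd)
  zc <- lo[1] + (seq_len(dims[1]) - 0.5) * vd[1]
  yc <- lo[2] + (seq_len(dims[2]) - 0.5) * vd[2]
  xc <- lo[3] + (seq_len(dims[3]) - 0.5) * vd[3]
  Z <- array(zc, dims)
  Y <- array(rep(yc, each = dims[1]), dims)
  X <- array(rep(xc, each = dims[1] * dims[2]), dims)
  mask <- array(FALSE, dims)
  for (i in seq_len(nrow(ch))) {
    e <- ch[i, ]
    mask <- mask | (((Z - e[1]) / e[4])^2 + ((Y - e[2]) / e[5])^2 +
                      ((X - e[3]) / e[6])^2 <= 1)
  }
  true_vol_um3 <- sum(apply(ch, 1, function(e) 4 / 3 * pi * e[4] * e[5] * e[6]))
  if (spec$aqueduct_radius_um > 0 && nrow(ch) > 1) {
    for (i in seq_len(nrow(ch) - 1L)) {
      a <- ch[i, 1:3]; b <- ch[i + 1, 1:3]
      u <- (b - a); L <- sqrt(sum(u^2)); u <- u / L
      # distance from each centre to its ellipsoid surface along u
      ta <- 1 / sqrt(sum((u / ch[i, 4:6])^2))
      tb <- 1 / sqrt(sum((u / ch[i + 1, 4:6])^2))
      gap <- max(L - ta - tb, 0)
      true_vol_um3 <- true_vol_um3 + pi * spec$aqueduct_radius_um^2 * gap
      # voxel membership: radial distance to the segment axis
      t_par <- (Z - a[1]) * u[1] + (Y - a[2]) * u[2] + (X - a[3]) * u[3]
      d2 <- (Z - a[1] - t_par * u[1])^2 + (Y - a[2] - t_par * u[2])^2 +
        (X - a[3] - t_par * u[3])^2
      mask <- mask | (d2 <= spec$aqueduct_radius_um^2 & t_par >= 0 & t_par <= L)
    }
  }
  vox <- array(spec$tissue_level, dims)
  vox[mask] <- spec$lumen_level
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vox <- vox + array(stats::rnorm(length(vox), 0, spec$noise_sd), dims)
  }
  list(volume = oct_volume(vox, vd), lumen_mask = mask,
       true_volume_mm3 = true_vol_um3 / 1e9, origin_um = lo, spec = spec)
}

#' Voxel index of a physical position in a phantom
#'
#' The phantom grid is cropped to the chambers' bounding box plus a
#' margin, so physical (z, y, x) micrometre positions must be mapped
#' through the grid origin to get voxel indices (e.g. for seeding
#' [region_grow()] at a chamber centre).
#'
#' @param phantom result of [build_volume_phantom()].
#' @param pt_um numeric (z, y, x) position in um (or a matrix of rows).
#' @return Integer voxel indices (1-based), same shape as `pt_um`.
#' @export
phantom_voxel <- function(phantom, pt_um) {
  pt_um <- matrix(pt_um, ncol = 3)
  idx <- sweep(pt_um, 2, phantom$origin_um)
  idx <- sweep(idx, 2, phantom$volume$voxel_dims_um, `/`)
  matrix(as.integer(ceiling(pmax(idx, 1e-9))), ncol = 3)
}

#' Convenience two-chamber phantom specification
#'
#' Two spherical chambers along the anterior-posterior (y) axis joined
#' by a cerebral-aqueduct cylinder; `aqueduct_radius_um = 0` produces
#' the stenosed topology (two disconnected lumen components).
#'
#' @param aqueduct_radius_um aqueduct radius, um (0 = stenosis).
#' @param radii_um the two chamber radii, um.
#' @param gap_um surface-to-surface gap along y, um.
#' @param ... passed to [volume_phantom_spec()].
#' @return A [volume_phantom_spec()].
#' @export
two_chamber_phantom_spec <- function(aqueduct_radius_um = 20,
                                     radii_um = c(100, 80), gap_um = 60, ...) {
  r1 <- radii_um[1]; r2 <- radii_um[2]
  c1 <- c(150, 150, 150)
  c2 <- c(150, 150 + r1 + gap_um + r2, 150)
  volume_phantom_spec(list(c(c1, r1, r1, r1), c(c2, r2, r2, r2)),
                      aqueduct_radius_um = aqueduct_radius_um, ...)
}
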