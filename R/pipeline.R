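#' Default pipeline configuration
#'
#' Flat list of every tunable stage parameter with its default:
#' tracking (detector mode, radius, percentile, (m0, m2) cutoff,
#' max displacement, link range), flow mapping (window, outlier
#' percentile, heatmap bin), registration (outline points, magnitude
#' scaling), volumetry (tolerance, connectivity) and the global seed.
#' Values are validated against each operation's preconditions by
#' [validate_config()].
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(mode = "feature_point", radius_px = 3, intensity_percentile = 0.5,
       cutoff = 0.1, hdome_h = NULL, max_disp = 10, link_range = 2,
       window_px = 10, outlier_percentile = 97, bin_px = 10,
       n_points = 100, scale_magnitudes = TRUE,
       tolerance = NULL, connectivity = 6, seed = 1L)
}

#' Validate a pipeline configuration
#'
#' @param config a named list; missing entries are filled from
#'   [default_config()].
#' @return The completed config, invisibly; errors on invalid values.
#' @export
validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config)
  stopifnot(cfg$mode %in% c("feature_point", "hdome"),
            cfg$radius_px >= 1,
            cfg$intensity_percentile > 0, cfg$intensity_percentile < 100,
            cfg$max_disp > 0, cfg$link_range >= 1,
            cfg$window_px >= 1, cfg$bin_px >= 1,
            cfg$outlier_percentile > 0, cfg$outlier_percentile <= 100,
            cfg$n_points >= 3, cfg$connectivity %in% c(6, 26))
  invisible(cfg)
}

log_line <- function(con, ...) {
  msg <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 paste0(...))
  writeLines(msg, con)
}

#' Run the flow-velocimetry pipeline end to end
#'
#' Executes anisotropy removal, per-frame particle detection, trajectory
#' linking, ROI restriction, windowed flow-velocity mapping with
#' outlier rejection, particle counting, density heatmapping and
#' flow-field segmentation, writing every intermediate artifact plus a
#' parameter log and a summary to `out_dir`. Identical inputs, config
#' and seed produce identical outputs.
#'
#' @param video an [oct_video()] or path to a TIFF readable by
#'   [read_video_tiff()].
#' @param roi a [roi_outline()] in pixel coordinates of the
#'   anisotropy-corrected image, or a path readable by [read_roi()].
#' @param config named list of parameters (see [default_config()]).
#' @param out_dir output directory (created if missing), or `NULL` to
#'   skip writing artifacts.
#' @return A list of class `pipeline_result`: `video`, `detections`,
#'   `tracks`, `roi`, `counts`, `velocities`, `grid`, `heatmap`,
#'   `regions`, `config`, `summary` (data frame of per-region polarity
#'   and mean speed plus global density).
#' @export
run_pipeline <- function(video, roi, config = list(), out_dir = NULL) {
  cfg <- validate_config(config)
  if (is.character(video)) video <- read_video_tiff(video)
  stopifnot(inherits(video, "oct_video"))
  if (is.character(roi)) roi <- read_roi(roi)
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "pipeline.log"), "w")
    on.exit(close(log_con))
    log_line(log_con, "ventriflow ", as.character(utils::packageVersion("ventriflow")))
    log_line(log_con, "config: ", paste(names(cfg), vapply(cfg, function(x)
      paste(format(x), collapse = ","), ""), sep = "=", collapse = " "))
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    if (!is.null(log_con)) log_line(log_con, "stage ", name, " done")
    res
  }
  video <- stage("preprocess", remove_anisotropy(video))
  g <- video$geometry
  detections <- stage("detect", {
    if (cfg$mode == "feature_point")
      detect_video(video, "feature_point", radius_px = cfg$radius_px,
                   intensity_percentile = cfg$intensity_percentile,
                   cutoff = cfg$cutoff)
    else
      detect_video(video, "hdome",
                   h = if (is.null(cfg$hdome_h)) 2 * stats::sd(video$frames)
                       else cfg$hdome_h)
  })
  tracks <- stage("link", link_tracks(detections, max_disp = cfg$max_disp,
                                      link_range = cfg$link_range))
  mask <- stage("roi", roi_mask(roi, dim(video$frames)[2:3], g))
  tracks_roi <- stage("roi_filter", filter_tracks_by_roi(tracks, mask))
  counts <- stage("counts",
                  particle_counts(detections, mask,
                                  n_frames = dim(video$frames)[1]))
  vel <- stage("velocities", tracks_to_velocities(tracks_roi, g))
  grid <- stage("flow_grid", {
    gr <- window_average(vel, cfg$window_px, roi_bbox(mask), g)
    remove_outliers(gr, cfg$outlier_percentile)
  })
  heat <- stage("heatmap", density_heatmap(detections, mask, cfg$bin_px,
                                           n_frames = dim(video$frames)[1]))
  regions <- stage("segment",
                   segment_flow_regions(grid, null_seed = cfg$seed))
  summary_df <- as.data.frame(regions)
  if (!is.null(out_dir)) {
    write_detections(detections, file.path(out_dir, "detections.csv"))
    write_tracks(tracks_roi, file.path(out_dir, "tracks_roi.csv"))
    write_flow_grid(grid, file.path(out_dir, "flow_grid.csv"))
    utils::write.csv(data.frame(frame = seq_along(counts$counts),
                                count = counts$counts),
                     file.path(out_dir, "particle_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_df, file.path(out_dir, "flow_regions.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(n_regions = nrow(summary_df),
                          polarity = summary_df$polarity,
                          mean_speed_um_s = summary_df$mean_speed_um_s,
                          mean_particle_count = counts$mean_count,
                          density_mm2 = counts$density_mm2),
                     file.path(out_dir, "summary.yml"))
    if (!is.null(log_con)) log_line(log_con, "wrote artifacts to ", out_dir)
  }
  structure(list(video = video, detections = detections, tracks = tracks_roi,
                 roi = mask, counts = counts, velocities = vel, grid = grid,
                 heatmap = heat, regions = regions, config = cfg,
                 summary = summary_df),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d flow regions, mean count %.1f, density %.1f / mm^2\n",
              nrow(x$summary), x$counts$mean_count, x$counts$density_mm2))
  if (nrow(x$summary))
    print(x$summary[, c("label", "polarity", "mean_speed_um_s", "n_cells")])
  invisible(x)
}

#' Simulate a phantom acquisition into a directory
#'
#' Writes a complete synthetic acquisition: the particle video as
#' multi-page TIFF with its geometry sidecar, the ground-truth tracks
#' as CSV, the scene specification as YAML and the ROI outline (pixel
#' coordinates) in the plain-text polygon format. The `stenosis` preset
#' instead writes a 3D two-chamber phantom with a closed aqueduct.
#'
#' @param preset `"wildtype"` (five-field 2D scene) or `"stenosis"`
#'   (3D phantom with aqueduct radius 0).
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param n_frames frames for the video presets.
#' @return The output directory, invisibly.
#' @export
simulate_scene_dir <- function(preset = c("wildtype", "stenosis"), seed = 1L,
                               out_dir, n_frames = 300) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (preset == "wildtype") {
    scene <- wildtype_scene(seed = seed, n_frames = n_frames)
    sim <- simulate_video(scene)
    write_video_tiff(sim$video, file.path(out_dir, "video.tif"))
    write_ground_truth(sim$truth, file.path(out_dir, "truth_tracks.csv"))
    write_scene(scene, file.path(out_dir, "scene.yml"))
    write_roi(outline_um_to_px(scene$outline, scene$geometry),
              file.path(out_dir, "roi.txt"))
  } else {
    spec <- two_chamber_phantom_spec(aqueduct_radius_um = 0, noise_sd = 5,
                                     seed = seed)
    ph <- build_volume_phantom(spec)
    write_volume_tiff(ph$volume, file.path(out_dir, "volume.tif"))
    yaml::write_yaml(list(true_volume_mm3 = ph$true_volume_mm3,
                          aqueduct_radius_um = spec$aqueduct_radius_um),
                     file.path(out_dir, "phantom_truth.yml"))
  }
  invisible(out_dir)
}
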