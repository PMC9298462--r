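#' Pipeline configuration
#'
#' All stage parameters with their field defaults in one validated list:
#' speed of sound 1500 m/s, 1 m localization grid, 30 fixes per hour for QC,
#' 5 m occupancy bins smoothed with sigma 2.5 m, alpha-shape shrink 0.5,
#' 30-minute segments with 50 percent overlap, 4 principal components, and a
#' 1.5 percent merger-score cut.
#'
#' @param n_fish number of simulated fish.
#' @param n_days days per fish.
#' @param seed master RNG seed; each stage derives its own stream from it.
#' @param c_sound speed of sound (m/s).
#' @param grid fine localization grid spacing (m).
#' @param min_per_hour QC threshold, fixes per full daytime hour.
#' @param bin occupancy bin size (m).
#' @param sigma occupancy smoothing sd (m).
#' @param shrink alpha-shape shrink factor.
#' @param segment_length segment length (min).
#' @param overlap segment overlap fraction.
#' @param k principal components retained.
#' @param threshold merger-score cut threshold.
#' @param linkage agglomeration linkage method.
#' @param array_spacing receiver lattice spacing (m).
#' @param offset_sd,drift_sd receiver clock error scales (s, s/s).
#' @param night_dropout nighttime detection-probability multiplier.
#' @param clock_window_s clock-model window (s).
#' @param sim extra arguments passed to [sim_config()] (e.g. `home_extent`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_fish = 3, n_days = 14, seed = 1L,
                            c_sound = 1500, grid = 1, min_per_hour = 30,
                            bin = 5, sigma = 2.5, shrink = 0.5,
                            segment_length = 30, overlap = 0.5,
                            k = 4, threshold = 0.015, linkage = "ward",
                            array_spacing = 45, offset_sd = 0.25,
                            drift_sd = 5e-7, night_dropout = 0.5,
                            clock_window_s = 21600, sim = list()) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_fish >= 1, cfg$n_days >= 1, cfg$c_sound > 0, cfg$grid > 0,
            cfg$min_per_hour >= 0, cfg$bin > 0, cfg$sigma >= 0,
            cfg$shrink >= 0, cfg$shrink <= 1, cfg$segment_length > 0,
            cfg$overlap >= 0, cfg$overlap < 1, cfg$k >= 1, cfg$k <= 13,
            cfg$threshold > 0, is.list(cfg$sim))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected rather than silently ignored.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline on simulated fish
#'
#' Executes every stage in order — simulate, localize (clock sync, grouping,
#' DToA), prep (QC + 1-minute interpolation), home range and occupancy,
#' segment features, and behavioral clustering — for each fish, writing the
#' stage outputs and a manifest to `out_dir` when given.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; created if missing.
#' @param quiet suppress per-stage messages.
#' @return Invisibly, a list with `array`, `config` and a per-fish list of
#'   stage results (`traj`, `fixes`, `regular`, `home_range`, `occupancy`,
#'   `features`, `pca`, `clusters`, `occupancy_by_class`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  scfg0 <- do.call(sim_config, c(list(n_days = config$n_days,
                                      seed = config$seed), config$sim))
  half <- scfg0$home_extent / 2 + 20
  bounds <- c(scfg0$home_center[1] - half[1], scfg0$home_center[1] + half[1],
              scfg0$home_center[2] - half[2], scfg0$home_center[2] + half[2])
  array <- build_triangular_array(bounds, config$array_spacing)
  array <- randomize_clocks(array, offset_sd = config$offset_sd,
                            drift_sd = config$drift_sd,
                            seed = config$seed + 101L)
  duration <- config$n_days * 86400
  beacon_dets <- simulate_beacon_detections(array, duration,
                                            seed = config$seed + 202L,
                                            c_sound = config$c_sound)
  clock <- fit_clock_model(beacon_dets, array, window_s = config$clock_window_s,
                           c_sound = config$c_sound)
  say("clock model: ", length(clock$window_mid_s), " windows, reference ",
      clock$reference)
  span <- max(stats::dist(array$stations[, c("x", "y")]))
  dw <- sim_day_windows(scfg0)

  fish <- vector("list", config$n_fish)
  names(fish) <- sprintf("F%d", seq_len(config$n_fish))
  for (f in seq_len(config$n_fish)) {
    id <- names(fish)[f]
    scfg <- scfg0
    scfg$seed <- config$seed + 1000L * f
    traj <- simulate_trajectory(scfg, tag_id = id)
    dets <- simulate_detections(traj, array, seed = scfg$seed + 1L,
                                c_sound = config$c_sound,
                                night_dropout = config$night_dropout)
    say(id, ": ", nrow(dets), " detections")
    corr <- correct_detections(dets, clock)
    grouped <- group_transmissions(corr, array_span_m = span,
                                   c_sound = config$c_sound)
    fixes <- localize_fixes(grouped, array, grid = config$grid,
                            c_sound = config$c_sound)
    say(id, ": ", nrow(fixes), " fixes from ",
        length(unique(grouped$group_id)), " transmission groups")
    regular <- prep_trajectories(fixes, dw, min_per_hour = config$min_per_hour)
    qc <- attr(regular, "qc")
    say(id, ": ", length(qc$accepted), " days pass QC")
    if (nrow(regular) == 0) {
      fish[[f]] <- list(traj = traj, fixes = fixes, regular = regular)
      next
    }
    hr <- boundary_polygon(regular[, c("x", "y")], config$shrink)
    occ <- occupancy_map(regular, bin = config$bin, sigma = config$sigma)
    segs <- segment_daily(regular, dw, length_min = config$segment_length,
                          overlap = config$overlap)
    feats <- segment_features(segs, center = global_center(fixes[, c("x", "y")]))
    scaled <- normalize_features(feats)
    pca <- fit_pca(scaled, k = config$k)
    tree <- agglomerate(pca$scores, method = config$linkage)
    clus <- cut_by_merger_score(tree, threshold = config$threshold)
    clus <- label_and_merge(clus, feats)
    occ_cls <- class_occupancy(clus, segs)
    say(id, ": ", length(segs), " segments -> ", clus$n_classes, " classes")
    fish[[f]] <- list(traj = traj, fixes = fixes, regular = regular,
                      home_range = hr, occupancy = occ, segments = segs,
                      features = feats, pca = pca, clusters = clus,
                      occupancy_by_class = occ_cls)
  }

  res <- list(array = array, clock = clock, config = config, fish = fish)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  say(sprintf("pipeline finished in %.1f min",
              as.numeric(difftime(Sys.time(), t0, units = "mins"))))
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stations(res$array$stations, file.path(out_dir, "stations.csv"))
  write_stations(res$array$beacons, file.path(out_dir, "beacons.csv"))
  stages <- c("simulate", "localize", "prep", "homerange", "features",
              "cluster")
  files <- character()
  for (id in names(res$fish)) {
    fz <- res$fish[[id]]
    p <- function(s) file.path(out_dir, paste0(id, "_", s))
    write_trajectory(data.frame(day = fz$traj$t_min %/% 1440 + 1,
                                t_min = fz$traj$t_min, x = fz$traj$x,
                                y = fz$traj$y, flag = fz$traj$mode),
                     p("true_trajectory.csv"))
    write_fixes(fz$fixes, p("fixes.csv"))
    files <- c(files, p("true_trajectory.csv"), p("fixes.csv"))
    if (!is.null(fz$regular) && nrow(fz$regular) > 0) {
      write_trajectory(fz$regular, p("trajectory.csv"))
      files <- c(files, p("trajectory.csv"))
    }
    if (!is.null(fz$home_range)) {
      write_home_range_geojson(fz$home_range, p("home_range.geojson"))
      write_occupancy(fz$occupancy, p("occupancy.csv"))
      files <- c(files, p("home_range.geojson"), p("occupancy.csv"))
    }
    if (!is.null(fz$features)) {
      utils::write.csv(fz$features, p("features.csv"), row.names = FALSE)
      lab <- data.frame(day = fz$features$day,
                        start_min = fz$features$start_min,
                        class = fz$clusters$segment_class)
      utils::write.csv(lab, p("classes.csv"), row.names = FALSE)
      files <- c(files, p("features.csv"), p("classes.csv"))
    }
  }
  manifest <- list(package = "reeftrack",
                   version = as.character(utils::packageVersion("reeftrack")),
                   seed = res$config$seed,
                   stages = stages,
                   parameters = res$config[setdiff(names(res$config), "sim")],
                   files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
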