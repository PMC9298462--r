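# Plain-text readers/writers for the pipeline's interchange formats.
# All CSVs carry exact column names so round-trips are lossless.

#' Write / read a detection log
#'
#' CSV with header `receiver_id,tag_id,arrival_time_s,depth_m`.
#' @param dets detection data.frame.
#' @param path file path.
#' @export
write_detections <- function(dets, path) {
  utils::write.csv(dets[, c("receiver_id", "tag_id", "arrival_time_s",
                            "depth_m")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("receiver_id", "tag_id", "arrival_time_s", "depth_m")
  if (!all(need %in% names(d)))
    stop("detection file must have columns ", paste(need, collapse = ","))
  d[need]
}

#' Write / read a station or beacon table
#'
#' CSV with header `id,x_m,y_m,z_m` in local metric coordinates.
#' @param tab data.frame `id, x, y, z`.
#' @param path file path.
#' @export
write_stations <- function(tab, path) {
  utils::write.csv(data.frame(id = tab$id, x_m = tab$x, y_m = tab$y,
                              z_m = tab$z), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stations
#' @export
read_stations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(id = as.character(d$id), x = d$x_m, y = d$y_m, z = d$z_m,
             stringsAsFactors = FALSE)
}

#' Write / read position fixes
#'
#' CSV with header `tag_id,time_s,x_m,y_m,z_m,residual_s,n_receivers`.
#' @param fixes fix data.frame from [localize_fixes()].
#' @param path file path.
#' @export
write_fixes <- function(fixes, path) {
  utils::write.csv(data.frame(tag_id = fixes$tag_id, time_s = fixes$time_s,
                              x_m = fixes$x, y_m = fixes$y, z_m = fixes$z,
                              residual_s = fixes$residual_s,
                              n_receivers = fixes$n_receivers),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes
#' @export
read_fixes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(tag_id = as.character(d$tag_id), time_s = d$time_s,
             x = d$x_m, y = d$y_m, z = d$z_m, residual_s = d$residual_s,
             n_receivers = d$n_receivers, stringsAsFactors = FALSE)
}

#' Write / read a regular trajectory
#'
#' CSV with header `day,t_min,x_m,y_m,flag`.
#' @param traj `regular_trajectory` data.frame.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(data.frame(day = traj$day, t_min = traj$t_min,
                              x_m = traj$x, y_m = traj$y, flag = traj$flag),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(day = d$day, t_min = d$t_min, x = d$x_m, y = d$y_m,
                    flag = d$flag, stringsAsFactors = FALSE)
  class(out) <- c("regular_trajectory", "data.frame")
  out
}

#' Write a home range as GeoJSON
#'
#' Polygon in local metric coordinates; the CRS is declared in the feature
#' properties rather than as a projection, since telemetry arrays use local
#' survey frames.
#'
#' @param hr a `home_range`.
#' @param path file path.
#' @export
write_home_range_geojson <- function(hr, path) {
  close_ring <- function(r) {
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, , drop = FALSE])
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  }
  gj <- list(
    type = "Feature",
    properties = list(crs = "local-metres", method = hr$method,
                      area_m2 = hr$area,
                      shrink_factor = hr$shrink_factor %||% NA),
    geometry = list(type = "Polygon",
                    coordinates = lapply(hr$rings, close_ring)))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an occupancy grid as CSV plus a YAML sidecar
#'
#' The matrix CSV holds the raw dwell-time layer (rows = x bins); the sidecar
#' records the origin, bin size and smoothing parameters.
#'
#' @param grid an `occupancy_grid`.
#' @param path CSV path; the sidecar gets the same path with `.yaml` added.
#' @export
write_occupancy <- function(grid, path) {
  utils::write.table(grid$counts, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  yaml::write_yaml(list(origin_x = grid$origin[1], origin_y = grid$origin[2],
                        bin_m = grid$bin, sigma_m = grid$sigma,
                        total_minutes = grid$total_minutes),
                   paste0(path, ".yaml"))
  invisible(path)
}
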