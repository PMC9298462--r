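#' Median position of a fix set
#'
#' Coordinate-wise median of all of a fish's positions; the reference centre
#' used by the distance-from-centre and angle-from-centre segment features.
#'
#' @param xy data.frame or matrix with x and y in the first two columns.
#' @return numeric(2).
#' @export
global_center <- function(xy) {
  xy <- as.matrix(xy[, 1:2])
  c(stats::median(xy[, 1]), stats::median(xy[, 2]))
}

#' Cut daily trajectories into overlapping segments
#'
#' Windows of `length_min` minutes starting every
#' `length_min * (1 - overlap)` minutes from sunrise; a final partial window
#' is discarded. The 50 percent default overlap avoids phase-locking segment
#' boundaries to any periodicity in the behavior.
#'
#' @param traj a `regular_trajectory` (columns `day, t_min, x, y`).
#' @param day_windows data.frame `day, sunrise_min, sunset_min`.
#' @param length_min segment length (minutes).
#' @param overlap fractional overlap between consecutive segments.
#' @return A list of class `trajectory_segments`; each element has `day`,
#'   `start_min` (minutes after sunrise), and `pts` (a `(length_min + 1) x 2`
#'   matrix of 1-minute positions). Days shorter than one window contribute
#'   nothing (with a warning).
#' @export
segment_daily <- function(traj, day_windows, length_min = 30, overlap = 0.5) {
  stopifnot(length_min > 0, overlap >= 0, overlap < 1)
  step <- length_min * (1 - overlap)
  segs <- list()
  for (d in sort(unique(traj$day))) {
    td <- traj[traj$day == d, , drop = FALSE]
    td <- td[order(td$t_min), , drop = FALSE]
    daylen <- nrow(td) - 1L
    if (daylen < length_min) {
      warning("day ", d, " shorter than one segment window; skipped")
      next
    }
    starts <- seq(0, daylen - length_min, by = step)
    for (s in starts) {
      idx <- (s + 1):(s + length_min + 1)
      segs[[length(segs) + 1]] <- list(
        day = d, start_min = s,
        pts = as.matrix(td[idx, c("x", "y")]))
    }
  }
  attr(segs, "length_min") <- length_min
  attr(segs, "overlap") <- overlap
  attr(segs, "day_windows") <- day_windows
  class(segs) <- "trajectory_segments"
  segs
}

#' Compute the 13 segment features
#'
#' Geometric and temporal descriptors of one trajectory segment:
#' \describe{
#'   \item{D}{net displacement, first to last point (m)}
#'   \item{L}{path length, sum of step lengths (m)}
#'   \item{S}{straightness D/L, in \[0, 1\] (0 for a motionless segment)}
#'   \item{A}{convex-hull area of the segment (m^2; 0 if collinear)}
#'   \item{MS}{median per-minute displacement (m/min)}
#'   \item{rho}{distance of the segment centroid from the fish's global
#'     median position (m)}
#'   \item{DAC5, DAC10}{directional autocorrelation: mean cosine of the
#'     heading change across a 5- or 10-minute lag; steps shorter than
#'     `eps` carry no heading and are skipped (imputed 0 below 5 valid pairs)}
#'   \item{SAC5, SAC10}{Pearson autocorrelation of the per-minute speed
#'     series at lag 5 or 10 minutes (0 if speed variance is 0)}
#'   \item{DP}{day phase: segment midpoint position within the
#'     sunrise-sunset window, in \[0, 1\]}
#'   \item{theta}{cosine of the angle (from the east axis) of the centroid
#'     relative to the global median position (0 when the centroid sits on
#'     the centre)}
#'   \item{F}{focus 1 - 4A/(pi L^2); 1 for a motionless or perfectly
#'     straight segment, lower for space-filling loops}
#' }
#'
#' @param pts `(n x 2)` matrix of 1-minute positions.
#' @param center the fish's [global_center()].
#' @param start_min segment start, minutes after sunrise.
#' @param day_length_min sunset minus sunrise (minutes).
#' @param eps minimum step length carrying a defined heading (m).
#' @return Named numeric vector of the 13 features.
#' @export
compute_features <- function(pts, center, start_min, day_length_min,
                             eps = 0.01) {
  n <- nrow(pts)
  steps <- diff(pts)
  step_len <- sqrt(rowSums(steps^2))
  L <- sum(step_len)
  D <- sqrt(sum((pts[n, ] - pts[1, ])^2))
  S <- if (L > 0) D / L else 0
  A <- hull_area(pts)
  MS <- stats::median(step_len)
  centroid <- colMeans(pts)
  dv <- centroid - center
  rho <- sqrt(sum(dv^2))
  theta <- if (rho > 0) dv[1] / rho else 0
  Fv <- if (L > 0) 1 - 4 * A / (pi * L^2) else 1
  headings <- atan2(steps[, 2], steps[, 1])
  valid <- step_len > eps
  dac <- function(lag) {
    if (length(headings) <= lag) return(0)
    i <- seq_len(length(headings) - lag)
    ok <- valid[i] & valid[i + lag]
    if (sum(ok) < 5) return(0)
    mean(cos(headings[i + lag][ok] - headings[i][ok]))
  }
  sac <- function(lag) {
    if (length(step_len) <= lag) return(0)
    i <- seq_len(length(step_len) - lag)
    a <- step_len[i]; b <- step_len[i + lag]
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  mid <- start_min + (n - 1) / 2
  DP <- min(1, max(0, mid / day_length_min))
  c(D = D, L = L, S = S, A = A, MS = MS, rho = rho,
    DAC5 = dac(5), DAC10 = dac(10), SAC5 = sac(5), SAC10 = sac(10),
    DP = DP, theta = unname(theta), F = Fv)
}

hull_area <- function(pts) {
  u <- unique(pts)
  if (nrow(u) < 3) return(0)
  h <- grDevices::chull(u)
  if (length(h) < 3) return(0)
  abs(shoelace_area(u[h, , drop = FALSE]))
}

#' Feature matrix for a set of segments
#'
#' @param segments a `trajectory_segments` list from [segment_daily()].
#' @param center the fish's [global_center()]; computed from all segment
#'   points if omitted.
#' @return A data.frame (class `feature_matrix`) with id columns `day`,
#'   `start_min` and the 13 feature columns; `center` kept as an attribute.
#' @export
segment_features <- function(segments, center = NULL) {
  stopifnot(length(segments) > 0)
  if (is.null(center))
    center <- global_center(do.call(rbind, lapply(segments, `[[`, "pts")))
  dw <- attr(segments, "day_windows")
  rows <- lapply(segments, function(s) {
    dl <- if (!is.null(dw)) {
      i <- match(s$day, dw$day)
      dw$sunset_min[i] - dw$sunrise_min[i]
    } else max(s$start_min + nrow(s$pts) - 1, 1)
    data.frame(day = s$day, start_min = s$start_min,
               t(compute_features(s$pts, center, s$start_min, dl)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "center") <- center
  class(out) <- c("feature_matrix", "data.frame")
  out
}

feature_names <- function()
  c("D", "L", "S", "A", "MS", "rho", "DAC5", "DAC10", "SAC5", "SAC10",
    "DP", "theta", "F")

#' Scale features to unit standard deviation
#'
#' Divides each feature column by its standard deviation to obtain unit-free
#' measurements for clustering (centering is applied later, at the PCA
#' stage). Constant columns are set to zero and flagged.
#'
#' @param features a `feature_matrix`.
#' @return The scaled feature matrix; attributes `feature_sd` (the divisors)
#'   and `constant_features` (names of flagged columns).
#' @export
normalize_features <- function(features) {
  fn <- intersect(feature_names(), names(features))
  if (nrow(features) < 2) stop("need at least 2 segments to scale features")
  sds <- vapply(features[fn], stats::sd, numeric(1))
  out <- features
  flagged <- character()
  for (f in fn) {
    if (sds[f] > 0) {
      out[[f]] <- out[[f]] / sds[f]
    } else {
      out[[f]] <- 0
      flagged <- c(flagged, f)
    }
  }
  attr(out, "feature_sd") <- sds
  attr(out, "constant_features") <- flagged
  attr(out, "center") <- attr(features, "center")
  out
}

#' Majority true movement mode per segment
#'
#' For simulated data: the ground-truth mode occupying the most minutes of
#' each segment (used to validate behavioral classification).
#'
#' @param segments a `trajectory_segments` list.
#' @param traj the simulated `reef_trajectory` (with `mode` labels).
#' @param day_windows data.frame `day, sunrise_min, sunset_min`.
#' @return Character vector, one mode per segment.
#' @export
segment_true_modes <- function(segments, traj, day_windows) {
  vapply(segments, function(s) {
    i <- match(s$day, day_windows$day)
    t0 <- (s$day - 1) * 1440 + day_windows$sunrise_min[i] + s$start_min
    sel <- traj$t_min >= t0 & traj$t_min <= t0 + nrow(s$pts) - 1
    names(which.max(table(traj$mode[sel])))
  }, character(1))
}
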