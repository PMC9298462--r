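#' Default movement-mode parameter table
#'
#' Kinematic parameters for the four behavioral movement modes used by the
#' trajectory simulator: scanning (slow, tortuous coverage of a small patch),
#' dwelling (essentially stationary), fast ranging (rapid, directed transits)
#' and slow ranging (slower directed travel). Speeds are in metres per minute
#' on the 1-minute simulation grid; `kappa` is the concentration of the
#' wrapped-normal turning-angle distribution (larger = straighter);
#' `attraction_radius` (m) is the radius of a pull toward a local activity
#' centre (0 disables it).
#'
#' The defaults are plausible for a 25 cm reef herbivore working a fringing
#' reef; they are free parameters of the simulator, not field estimates.
#'
#' @param scanning,dwelling,fast_ranging,slow_ranging optional named numeric
#'   vectors with elements `mean_speed`, `speed_sd`, `kappa`,
#'   `attraction_radius` overriding the defaults for that mode.
#' @return A data.frame with one row per mode and columns `mode`,
#'   `mean_speed`, `speed_sd`, `kappa`, `attraction_radius`.
#' @export
movement_modes <- function(scanning = NULL, dwelling = NULL,
                           fast_ranging = NULL, slow_ranging = NULL) {
  defs <- list(
    scanning     = c(mean_speed = 2.0,  speed_sd = 0.8,  kappa = 1,  attraction_radius = 12),
    dwelling     = c(mean_speed = 0.2,  speed_sd = 0.15, kappa = 0,  attraction_radius = 3),
    fast_ranging = c(mean_speed = 16.0, speed_sd = 4.0,  kappa = 20, attraction_radius = 0),
    slow_ranging = c(mean_speed = 6.0,  speed_sd = 2.0,  kappa = 8,  attraction_radius = 0)
  )
  over <- list(scanning = scanning, dwelling = dwelling,
               fast_ranging = fast_ranging, slow_ranging = slow_ranging)
  for (m in names(defs)) {
    if (!is.null(over[[m]])) {
      stopifnot(all(names(over[[m]]) %in% names(defs[[m]])))
      defs[[m]][names(over[[m]])] <- over[[m]]
    }
  }
  out <- data.frame(mode = names(defs), do.call(rbind, defs),
                    row.names = NULL, stringsAsFactors = FALSE)
  validate_modes(out)
  out
}

validate_modes <- function(modes) {
  need <- c("scanning", "dwelling", "fast_ranging", "slow_ranging")
  if (!setequal(modes$mode, need) || nrow(modes) != 4L)
    stop("exactly one parameter row per mode (", paste(need, collapse = ", "),
         ") is required")
  if (any(modes$mean_speed < 0) || any(modes$speed_sd < 0) || any(modes$kappa < 0))
    stop("mean_speed, speed_sd and kappa must be non-negative")
  ms <- function(m) modes$mean_speed[modes$mode == m]
  if (!(ms("fast_ranging") > ms("slow_ranging") &&
        ms("slow_ranging") > ms("scanning")))
    stop("mode speeds must satisfy fast_ranging > slow_ranging > scanning")
  invisible(modes)
}

#' Simulation configuration
#'
#' Bundles the study-design parameters of the synthetic fish: the home-range
#' rectangle, the fixed nightly sleeping site, the per-minute Markov matrix
#' governing switches between the four movement modes, and the day window
#' (sunrise/sunset as minutes of the day) outside which the fish sits at the
#' sleeping site.
#'
#' @param home_center numeric(2), centre of the home range (m).
#' @param home_extent numeric(2), length and width of the home-range
#'   rectangle (m); default 200 x 50.
#' @param sleep_site numeric(2), sleeping-site position (m); must lie within
#'   the home range.
#' @param n_days number of simulated days.
#' @param transition row-stochastic 4x4 per-minute mode transition matrix with
#'   rows/cols ordered scanning, dwelling, fast_ranging, slow_ranging.
#' @param day_window numeric(2), sunrise and sunset in minutes of the day.
#' @param transmission_interval tag transmission interval, seconds.
#' @param init_mode mode at the first sunrise.
#' @param home_pull per-minute Ornstein-Uhlenbeck pull strength toward
#'   `home_center` (fraction of the offset removed per minute).
#' @param seed integer RNG seed.
#' @return A list of class `reef_sim_config`.
#' @export
sim_config <- function(home_center = c(0, 0),
                       home_extent = c(200, 50),
                       sleep_site = home_center + c(-home_extent[1] / 3, 0),
                       n_days = 14,
                       transition = default_transition(),
                       day_window = c(360, 1080),
                       transmission_interval = 10,
                       init_mode = "scanning",
                       home_pull = 0.02,
                       seed = 1L) {
  cfg <- list(home_center = home_center, home_extent = home_extent,
              sleep_site = sleep_site, n_days = n_days,
              transition = transition, day_window = day_window,
              transmission_interval = transmission_interval,
              init_mode = init_mode, home_pull = home_pull, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "reef_sim_config"
  cfg
}

#' @rdname sim_config
#' @param p_stay per-minute probability of remaining in the current mode.
#' @export
default_transition <- function(p_stay = 0.97) {
  m <- matrix((1 - p_stay) / 3, 4, 4)
  diag(m) <- p_stay
  dimnames(m) <- list(mode_names(), mode_names())
  m
}

mode_names <- function() c("scanning", "dwelling", "fast_ranging", "slow_ranging")

validate_sim_config <- function(cfg) {
  if (any(cfg$home_extent <= 0)) stop("home_extent must be strictly positive")
  if (!is.matrix(cfg$transition) || any(dim(cfg$transition) != 4L))
    stop("transition must be a 4x4 matrix")
  if (any(abs(rowSums(cfg$transition) - 1) > 1e-12) || any(cfg$transition < 0))
    stop("transition matrix must be row-stochastic")
  if (cfg$transmission_interval <= 0) stop("transmission_interval must be > 0")
  if (cfg$day_window[1] >= cfg$day_window[2]) stop("day_window must be increasing")
  if (!cfg$init_mode %in% mode_names()) stop("unknown init_mode")
  half <- cfg$home_extent / 2
  if (any(abs(cfg$sleep_site - cfg$home_center) > half))
    stop("sleep_site must lie inside the home range")
  invisible(cfg)
}

reflect_into <- function(v, lo, hi) {
  # reflect a coordinate back into [lo, hi]
  w <- hi - lo
  if (v < lo) v <- lo + min(lo - v, w)
  if (v > hi) v <- hi - min(v - hi, w)
  v
}

#' Simulate a fish trajectory with labeled movement modes
#'
#' Discrete-time (1-minute) correlated random walk. During the day window the
#' fish switches between four movement modes according to a per-minute Markov
#' chain; each mode has its own speed distribution, wrapped-normal turning
#' kernel and optional attraction toward a local activity centre (re-drawn at
#' each entry into the mode). A weak Ornstein-Uhlenbeck pull toward the
#' home-range centre plus reflection at the home-range rectangle keep the
#' track inside the range. At night the fish sits at the sleeping site with
#' sub-metre jitter. Depth is a bounded random walk in 0-15 m during the day
#' and near the sea floor at night.
#'
#' @param config a [sim_config()].
#' @param modes a [movement_modes()] table.
#' @param tag_id tag identifier recorded with the trajectory.
#' @return A data.frame of class `reef_trajectory` with columns `t_min`, `x`,
#'   `y`, `z`, `mode` (one row per minute) and the config stored as an
#'   attribute.
#' @export
simulate_trajectory <- function(config, modes = movement_modes(), tag_id = "F1") {
  validate_sim_config(config)
  validate_modes(modes)
  set.seed(config$seed)
  modes <- modes[match(mode_names(), modes$mode), ]

  n_min <- config$n_days * 1440L
  t_min <- 0:(n_min - 1L)
  mday <- t_min %% 1440L
  is_day <- mday >= config$day_window[1] & mday < config$day_window[2]

  lo <- config$home_center - config$home_extent / 2
  hi <- config$home_center + config$home_extent / 2

  pos <- config$sleep_site
  heading <- stats::runif(1, -pi, pi)
  mode_i <- match(config$init_mode, mode_names())
  local_center <- pos
  z <- 12

  X <- numeric(n_min); Y <- numeric(n_min); Z <- numeric(n_min)
  M <- integer(n_min)
  cum_p <- t(apply(config$transition, 1, cumsum))

  for (i in seq_len(n_min)) {
    if (is_day[i]) {
      if (i > 1L && !is_day[i - 1L]) {        # sunrise: leave the sleep site
        pos <- config$sleep_site
        local_center <- pos
      }
      new_mode <- findInterval(stats::runif(1), cum_p[mode_i, ]) + 1L
      if (new_mode > 4L) new_mode <- 4L
      if (new_mode != mode_i) local_center <- pos
      mode_i <- new_mode

      sp <- max(0, stats::rnorm(1, modes$mean_speed[mode_i], modes$speed_sd[mode_i]))
      kap <- modes$kappa[mode_i]
      dtheta <- if (kap > 0) stats::rnorm(1, 0, 1 / sqrt(kap)) else stats::runif(1, -pi, pi)
      heading <- heading + dtheta
      step <- sp * c(cos(heading), sin(heading))
      cand <- pos + step + config$home_pull * (config$home_center - pos)

      rad <- modes$attraction_radius[mode_i]
      if (rad > 0) {
        off <- cand - local_center
        d <- sqrt(sum(off^2))
        if (d > rad) cand <- cand - 0.5 * (d - rad) / d * off
      }
      newpos <- c(reflect_into(cand[1], lo[1], hi[1]),
                  reflect_into(cand[2], lo[2], hi[2]))
      disp <- newpos - pos
      # keep the turning kernel relative to the realized direction, so
      # reflections and attraction do not desynchronize the walk
      if (sum(disp^2) > 1e-12) heading <- atan2(disp[2], disp[1])
      pos <- newpos
      z <- reflect_into(z + stats::rnorm(1, 0, 0.5), 0, 15)
    } else {
      jit <- stats::rnorm(2, 0, 1)
      r <- sqrt(sum(jit^2))
      if (r > 8) jit <- jit * 8 / r          # stay well within 10 m of the site
      pos <- config$sleep_site + jit
      mode_i <- match("dwelling", mode_names())
      z <- reflect_into(12 + stats::rnorm(1, 0, 0.3), 0, 15)
    }
    X[i] <- pos[1]; Y[i] <- pos[2]; Z[i] <- z; M[i] <- mode_i
  }

  out <- data.frame(t_min = t_min, x = X, y = Y, z = Z,
                    mode = mode_names()[M], stringsAsFactors = FALSE)
  attr(out, "config") <- config
  attr(out, "tag_id") <- tag_id
  class(out) <- c("reef_trajectory", "data.frame")
  out
}

#' Build a triangular receiver array
#'
#' Lays acoustic receiver stations on an equilateral-triangle lattice covering
#' a rectangle (plus half a spacing of margin so that interior points are
#' always surrounded), and attaches synchronization beacons to a regular
#' subset of stations.
#'
#' @param bounds numeric(4): `c(xmin, xmax, ymin, ymax)` of the area to cover (m).
#' @param spacing lattice spacing between neighbouring stations (m).
#' @param z receiver mooring depth (m), recycled over stations.
#' @param beacon_every attach a sync beacon to every `beacon_every`-th station
#'   (0 = no beacons).
#' @param detection_range maximum tag detection distance (m).
#' @param timing_noise_sd standard deviation of arrival-time measurement
#'   noise (s).
#' @return A list of class `receiver_array` with elements `stations` and
#'   `beacons` (data.frames `id, x, y, z`), `detection_range`,
#'   `timing_noise_sd`, and zeroed `clock_offset` / `clock_drift` vectors
#'   (see [randomize_clocks()]).
#' @export
build_triangular_array <- function(bounds, spacing, z = 10, beacon_every = 2,
                                   detection_range = 70, timing_noise_sd = 0.002) {
  stopifnot(length(bounds) == 4, spacing > 0)
  w <- bounds[2] - bounds[1]; h <- bounds[4] - bounds[3]
  if (w <= 0 || h <= 0) stop("bounds are degenerate")
  if (spacing > max(w, h))
    stop("spacing exceeds the array bounds; a usable array needs >= 3 stations")

  dy <- spacing * sqrt(3) / 2
  ys <- seq(bounds[3] - dy / 2, bounds[4] + dy / 2 + 1e-9, by = dy)
  pts <- do.call(rbind, lapply(seq_along(ys), function(r) {
    xoff <- if (r %% 2 == 0) spacing / 2 else 0
    xs <- seq(bounds[1] - spacing / 2 + xoff, bounds[2] + spacing / 2 + 1e-9,
              by = spacing)
    cbind(xs, ys[r])
  }))
  n <- nrow(pts)
  if (n < 3) stop("array would have fewer than 3 stations")
  stations <- data.frame(id = sprintf("R%02d", seq_len(n)),
                         x = pts[, 1], y = pts[, 2], z = rep_len(z, n),
                         stringsAsFactors = FALSE)
  beacons <- if (beacon_every > 0) {
    idx <- seq(1, n, by = beacon_every)
    data.frame(id = sprintf("B%02d", seq_along(idx)),
               x = stations$x[idx], y = stations$y[idx], z = stations$z[idx],
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(), x = numeric(), y = numeric(), z = numeric())
  }
  arr <- list(stations = stations, beacons = beacons,
              detection_range = detection_range,
              timing_noise_sd = timing_noise_sd,
              clock_offset = stats::setNames(rep(0, n), stations$id),
              clock_drift = stats::setNames(rep(0, n), stations$id))
  class(arr) <- "receiver_array"
  arr
}

#' Assign random receiver clock errors
#'
#' Draws an initial clock offset and a linear drift rate for every station;
#' both are applied by [simulate_detections()] when stamping arrival times.
#'
#' @param array a `receiver_array`.
#' @param offset_sd standard deviation of the initial offsets (s).
#' @param drift_sd standard deviation of the drift rates (s/s).
#' @param seed RNG seed.
#' @export
randomize_clocks <- function(array, offset_sd = 0.25, drift_sd = 5e-7, seed = 1L) {
  set.seed(seed)
  n <- nrow(array$stations)
  array$clock_offset[] <- stats::rnorm(n, 0, offset_sd)
  array$clock_drift[] <- stats::rnorm(n, 0, drift_sd)
  array
}

det_probability <- function(d, range) {
  # 1 inside half range, linear falloff to 0 at range
  pmin(1, pmax(0, (range - d) / (range / 2)))
}

# Core detection engine shared by fish-tag and beacon simulation.
# tx: data.frame(t_s, x, y, z, tag_id, night)
detect_transmissions <- function(tx, array, c_sound, night_dropout, seed) {
  set.seed(seed)
  st <- array$stations
  n_tx <- nrow(tx); n_st <- nrow(st)
  if (n_tx == 0)
    return(data.frame(receiver_id = character(), tag_id = character(),
                      arrival_time_s = numeric(), depth_m = numeric()))
  out <- vector("list", n_st)
  night_mult <- ifelse(tx$night, night_dropout, 1)
  for (j in seq_len(n_st)) {
    d <- sqrt((tx$x - st$x[j])^2 + (tx$y - st$y[j])^2 + (tx$z - st$z[j])^2)
    p <- det_probability(d, array$detection_range) * night_mult
    hit <- stats::runif(n_tx) < p
    if (!any(hit)) next
    t_emit <- tx$t_s[hit]
    arr_t <- t_emit + d[hit] / c_sound +
      array$clock_offset[j] + array$clock_drift[j] * t_emit +
      stats::rnorm(sum(hit)) * array$timing_noise_sd
    out[[j]] <- data.frame(receiver_id = st$id[j], tag_id = tx$tag_id[hit],
                           arrival_time_s = arr_t, depth_m = tx$z[hit],
                           emission_s = t_emit, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(receiver_id = character(), tag_id = character(),
                      arrival_time_s = numeric(), depth_m = numeric()))
  out <- out[order(out$tag_id, out$arrival_time_s), , drop = FALSE]
  rownames(out) <- NULL
  truth <- out$emission_s
  out$emission_s <- NULL
  attr(out, "emission_s") <- truth
  out
}

#' Simulate tag detections at a receiver array
#'
#' Emits one tag transmission per `transmission_interval` at the (linearly
#' interpolated) true position, and logs an arrival at every station within
#' detection range that passes a distance-decaying detection draw. Arrival
#' times include travel time at the speed of sound, the station's clock offset
#' and drift, and Gaussian timing noise. Detections at night are additionally
#' thinned by `night_dropout` (sleeping fish are acoustically occluded).
#'
#' @param traj a `reef_trajectory` from [simulate_trajectory()].
#' @param array a `receiver_array`.
#' @param seed RNG seed for the detection draws and timing noise.
#' @param c_sound speed of sound in water (m/s).
#' @param night_dropout multiplier on detection probability at night.
#' @param jitter half-width of uniform transmission-time jitter (s).
#' @return A data.frame `receiver_id, tag_id, arrival_time_s, depth_m`, sorted
#'   by arrival time; true emission times are kept in attribute `emission_s`
#'   and the per-transmission truth table in attribute `truth`.
#' @export
simulate_detections <- function(traj, array, seed = 1L, c_sound = 1500,
                                night_dropout = 0.5, jitter = 0) {
  cfg <- attr(traj, "config")
  stopifnot(!is.null(cfg))
  set.seed(seed + 1000003L)
  interval <- cfg$transmission_interval
  t_s <- seq(0, max(traj$t_min) * 60, by = interval)
  if (jitter > 0) t_s <- t_s + stats::runif(length(t_s), -jitter, jitter)
  xs <- stats::approx(traj$t_min * 60, traj$x, xout = t_s, rule = 2)$y
  ys <- stats::approx(traj$t_min * 60, traj$y, xout = t_s, rule = 2)$y
  zs <- stats::approx(traj$t_min * 60, traj$z, xout = t_s, rule = 2)$y
  mday <- (t_s / 60) %% 1440
  night <- mday < cfg$day_window[1] | mday >= cfg$day_window[2]
  tx <- data.frame(t_s = t_s, x = xs, y = ys, z = zs,
                   tag_id = attr(traj, "tag_id") %||% "F1", night = night,
                   stringsAsFactors = FALSE)
  dets <- detect_transmissions(tx, array, c_sound, night_dropout, seed)
  attr(dets, "truth") <- tx[, c("t_s", "x", "y", "z")]
  dets
}

#' Simulate sync-beacon detections
#'
#' Beacons are stationary tags at known positions; each transmits on a fixed
#' interval (staggered across beacons to avoid simultaneous pings). No night
#' thinning is applied: moored beacons are not occluded by sleeping fish.
#'
#' @param array a `receiver_array` with beacons.
#' @param duration_s length of the record (s).
#' @param interval beacon transmission interval (s).
#' @param seed RNG seed.
#' @param c_sound speed of sound (m/s).
#' @return Detection data.frame in the same format as [simulate_detections()].
#' @export
simulate_beacon_detections <- function(array, duration_s, interval = 60,
                                       seed = 1L, c_sound = 1500) {
  b <- array$beacons
  if (nrow(b) == 0) stop("array has no beacons")
  tx <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
    t_s <- seq((i - 1) * interval / nrow(b), duration_s, by = interval)
    data.frame(t_s = t_s, x = b$x[i], y = b$y[i], z = b$z[i],
               tag_id = b$id[i], night = FALSE, stringsAsFactors = FALSE)
  }))
  detect_transmissions(tx, array, c_sound, night_dropout = 1, seed = seed + 7L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.reef_trajectory <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("Simulated reef-fish trajectory:", nrow(x), "minutes over",
      cfg$n_days, "days\n")
  cat("  home range", paste(cfg$home_extent, collapse = " x "),
      "m centred at", paste(round(cfg$home_center, 1), collapse = ", "), "\n")
  cat("  mode minutes:\n")
  print(table(x$mode))
  invisible(x)
}

#' @export
print.receiver_array <- function(x, ...) {
  cat("Receiver array:", nrow(x$stations), "stations,",
      nrow(x$beacons), "sync beacons; detection range",
      x$detection_range, "m\n")
  invisible(x)
}
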