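#' Sunrise/sunset window for a date and site
#'
#' NOAA-style solar geometry (Fourier series for declination and the equation
#' of time, zenith 90.833 degrees including refraction), accurate to about a
#' minute at mid latitudes — ample for trimming telemetry to daylight.
#'
#' @param date a `Date` (or something coercible to one).
#' @param lat,lon site latitude and longitude in decimal degrees
#'   (north/east positive).
#' @param tz_offset_hours offset of local clock time from UTC (hours).
#' @param override optional numeric(2) of explicit sunrise/sunset minutes of
#'   the day; returned verbatim when supplied.
#' @return A list with `date`, `sunrise_min` and `sunset_min` (minutes of the
#'   local day).
#' @export
solar_day_window <- function(date, lat, lon, tz_offset_hours = 0,
                             override = NULL) {
  date <- as.Date(date)
  if (!is.null(override)) {
    stopifnot(length(override) == 2, override[1] < override[2])
    return(list(date = date, sunrise_min = override[1],
                sunset_min = override[2]))
  }
  stopifnot(abs(lat) <= 90, abs(lon) <= 360)
  doy <- as.integer(strftime(date, "%j"))
  g <- 2 * pi / 365 * (doy - 1 + (12 - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  phi <- lat * pi / 180
  cos_ha <- cos(90.833 * pi / 180) / (cos(phi) * cos(decl)) -
    tan(phi) * tan(decl)
  if (cos_ha < -1 || cos_ha > 1)
    stop("sun does not rise/set on this date at this latitude")
  ha <- acos(cos_ha) * 180 / pi
  sunrise_utc <- 720 - 4 * (lon + ha) - eqtime
  sunset_utc <- 720 - 4 * (lon - ha) - eqtime
  list(date = date,
       sunrise_min = sunrise_utc + 60 * tz_offset_hours,
       sunset_min = sunset_utc + 60 * tz_offset_hours)
}

#' Day windows for a simulated study
#'
#' @param config a [sim_config()].
#' @return A data.frame `day, sunrise_min, sunset_min`, one row per simulated
#'   day (windows identical across days: the simulator uses a fixed window).
#' @export
sim_day_windows <- function(config) {
  data.frame(day = seq_len(config$n_days),
             sunrise_min = config$day_window[1],
             sunset_min = config$day_window[2])
}

fix_day <- function(time_s) floor(time_s / 86400) + 1L

#' Select days passing the detection-density quality control
#'
#' A day is accepted when every full daytime hour contains at least
#' `min_per_hour` position fixes; accepted days are then grouped into maximal
#' runs of contiguous dates. Nights are excluded by default because nighttime
#' detections are deliberately degraded (sleeping fish are occluded);
#' `daytime_only = FALSE` applies the rule to all 24 hours.
#'
#' @param fixes position-fix data.frame with a `time_s` column.
#' @param day_windows data.frame `day, sunrise_min, sunset_min`.
#' @param min_per_hour minimum fixes per full daytime hour.
#' @param daytime_only apply the rule to daytime hours only.
#' @param min_run minimum run length of contiguous accepted days.
#' @return A list: `accepted` (day numbers), `runs` (list of runs with length
#'   >= `min_run`), `runs_all` (all runs including singletons, useful for
#'   home-range analysis where larger gaps are allowed).
#' @export
select_qc_days <- function(fixes, day_windows, min_per_hour = 30,
                           daytime_only = TRUE, min_run = 2) {
  if (nrow(fixes) == 0)
    return(list(accepted = integer(), runs = list(), runs_all = list()))
  day <- fix_day(fixes$time_s)
  mday <- (fixes$time_s / 60) %% 1440
  accepted <- integer()
  for (i in seq_len(nrow(day_windows))) {
    d <- day_windows$day[i]
    if (daytime_only) {
      h0 <- ceiling(day_windows$sunrise_min[i] / 60)
      h1 <- floor(day_windows$sunset_min[i] / 60) - 1
    } else {
      h0 <- 0; h1 <- 23
    }
    if (h1 < h0) next
    sel <- day == d
    if (!any(sel)) next
    hr <- floor(mday[sel] / 60)
    counts <- tabulate(hr + 1L, nbins = 24L)
    if (all(counts[(h0:h1) + 1L] >= min_per_hour)) accepted <- c(accepted, d)
  }
  accepted <- sort(accepted)
  runs_all <- if (length(accepted)) {
    split(accepted, cumsum(c(1, diff(accepted) != 1)))
  } else list()
  runs <- Filter(function(r) length(r) >= min_run, runs_all)
  list(accepted = accepted, runs = unname(runs), runs_all = unname(runs_all))
}

#' Interpolate daytime fixes onto a 1-minute grid
#'
#' Linear interpolation of x and y (independently) onto the minute grid from
#' sunrise to sunset of one day. Grid points outside the observed fix span use
#' nearest-endpoint extrapolation and are flagged; grid points within half a
#' minute of an actual fix are flagged as observed.
#'
#' @param fixes position fixes (`time_s, x, y`) for one fish.
#' @param day day number (1-based simulation day, or index into
#'   `day_windows`).
#' @param day_window one row of a day-windows table (`sunrise_min`,
#'   `sunset_min`).
#' @return A data.frame `day, t_min, x, y, flag` (`t_min` absolute minutes
#'   since study start; flag one of "observed", "interpolated",
#'   "extrapolated"), or `NULL` (with a warning) if fewer than two daytime
#'   fixes exist.
#' @export
interpolate_to_minutes <- function(fixes, day, day_window) {
  t_min <- fixes$time_s / 60
  day0 <- (day - 1) * 1440
  lo <- day0 + day_window$sunrise_min
  hi <- day0 + day_window$sunset_min
  sel <- t_min >= lo & t_min <= hi
  if (sum(sel) < 2) {
    warning("day ", day, ": fewer than 2 daytime fixes; day dropped")
    return(NULL)
  }
  tf <- t_min[sel]; xf <- fixes$x[sel]; yf <- fixes$y[sel]
  grid <- seq(floor(lo), floor(lo) + floor(day_window$sunset_min -
                                             day_window$sunrise_min), by = 1)
  x <- stats::approx(tf, xf, xout = grid, rule = 2, ties = mean)$y
  y <- stats::approx(tf, yf, xout = grid, rule = 2, ties = mean)$y
  flag <- rep("interpolated", length(grid))
  flag[grid < min(tf) | grid > max(tf)] <- "extrapolated"
  near <- vapply(grid, function(g) any(abs(tf - g) <= 0.5), logical(1))
  flag[near & flag == "interpolated"] <- "observed"
  data.frame(day = day, t_min = grid, x = x, y = y, flag = flag,
             stringsAsFactors = FALSE)
}

#' Quality-control and interpolate a fix record into regular trajectories
#'
#' Applies [select_qc_days()] and [interpolate_to_minutes()] across days.
#'
#' @param fixes position fixes for one fish.
#' @param day_windows data.frame `day, sunrise_min, sunset_min`.
#' @inheritParams select_qc_days
#' @return A data.frame of class `regular_trajectory` (`day, t_min, x, y,
#'   flag`) covering all accepted days; the QC result is attached as attribute
#'   `qc`.
#' @export
prep_trajectories <- function(fixes, day_windows, min_per_hour = 30,
                              daytime_only = TRUE, min_run = 2) {
  qc <- select_qc_days(fixes, day_windows, min_per_hour = min_per_hour,
                       daytime_only = daytime_only, min_run = min_run)
  days <- unlist(qc$runs)
  out <- do.call(rbind, lapply(days, function(d) {
    interpolate_to_minutes(fixes, d,
                           day_windows[day_windows$day == d, , drop = FALSE])
  }))
  if (is.null(out))
    out <- data.frame(day = integer(), t_min = numeric(), x = numeric(),
                      y = numeric(), flag = character())
  attr(out, "qc") <- qc
  class(out) <- c("regular_trajectory", "data.frame")
  out
}
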