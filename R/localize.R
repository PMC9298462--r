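#' Fit a receiver clock model from sync-beacon detections
#'
#' Stationary beacons at known positions let receiver clock errors be
#' estimated: for a beacon transmission co-detected by two stations, the
#' observed arrival-time difference minus the geometrically predicted one
#' (range difference over the speed of sound) measures the difference of the
#' two stations' clock offsets. All such pairwise measurements within a time
#' window are combined in a network least-squares solve over the whole array
#' (a graph-Laplacian system with the reference station pinned at zero), so
#' offsets chain across the array even between stations that share no beacon
#' directly. Window solutions are interpolated linearly between window
#' midpoints and extrapolated along the outermost segments, so a linear
#' drift is tracked to the ends of the record.
#'
#' @param beacon_dets detection data.frame for the sync beacons
#'   (`receiver_id, tag_id, arrival_time_s, ...`).
#' @param array a `receiver_array` (positions of stations and beacons).
#' @param window_s window length for piecewise-constant offset estimation (s).
#' @param reference reference station id (its offset is defined as 0);
#'   default: the station with the most beacon detections.
#' @param c_sound speed of sound (m/s).
#' @return An object of class `clock_model`: per-station offset estimates at
#'   window midpoints, the reference id, and ids of stations that never heard
#'   a beacon or are disconnected from the reference's sync network
#'   (`flagged`, excluded from localization).
#' @export
fit_clock_model <- function(beacon_dets, array, window_s = 3600,
                            reference = NULL, c_sound = 1500) {
  st <- array$stations
  bc <- array$beacons
  d <- beacon_dets[beacon_dets$tag_id %in% bc$id, , drop = FALSE]
  if (nrow(d) == 0) stop("no beacon detections supplied")

  heard <- unique(d$receiver_id)
  flagged <- setdiff(st$id, heard)
  if (is.null(reference)) {
    tab <- table(d$receiver_id)
    reference <- names(tab)[which.max(tab)]
  }
  if (!reference %in% heard) stop("reference station heard no beacons")

  # group beacon pings into transmission events; uncorrected clocks, so allow
  # for offset+drift spread across stations while staying far below the
  # beacon transmission interval
  span <- max(stats::dist(st[, c("x", "y")])) / c_sound
  grp <- group_transmissions(d, gap_s = span + 5)

  brow <- match(grp$tag_id, bc$id)
  srow <- match(grp$receiver_id, st$id)
  geo <- sqrt((bc$x[brow] - st$x[srow])^2 + (bc$y[brow] - st$y[srow])^2 +
                (bc$z[brow] - st$z[srow])^2) / c_sound
  corr_t <- grp$arrival_time_s - geo     # arrival minus travel time

  # pairwise offset-difference observations: within each beacon event, pair
  # every detection with the event's first station
  gsplit <- split(seq_len(nrow(grp)), grp$group_id)
  obs <- lapply(gsplit, function(ix) {
    if (length(ix) < 2) return(NULL)
    piv <- ix[1]
    oth <- ix[-1]
    data.frame(i = srow[oth], j = srow[piv],
               v = corr_t[oth] - corr_t[piv],
               t = grp$arrival_time_s[piv], stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, obs)
  if (is.null(obs) || nrow(obs) == 0)
    stop("no beacon events detected by more than one station")

  ids <- st$id
  n <- length(ids)
  ref_i <- match(reference, ids)
  obs$win <- floor(obs$t / window_s)
  wins <- sort(unique(obs$win))
  mids <- numeric(length(wins))
  off <- matrix(NA_real_, nrow = n, ncol = length(wins),
                dimnames = list(ids, NULL))

  for (w in seq_along(wins)) {
    ow <- obs[obs$win == wins[w], , drop = FALSE]
    mids[w] <- mean(ow$t)
    L <- matrix(0, n, n)
    key <- (ow$i - 1L) * n + ow$j        # aggregate repeated edges
    cnt <- tapply(rep(1, nrow(ow)), key, sum)
    vsum <- tapply(ow$v, key, sum)
    kk <- as.integer(names(cnt))
    ii <- (kk - 1L) %/% n + 1L
    jj <- (kk - 1L) %% n + 1L
    for (r in seq_along(kk)) {
      L[ii[r], ii[r]] <- L[ii[r], ii[r]] + cnt[r]
      L[jj[r], jj[r]] <- L[jj[r], jj[r]] + cnt[r]
      L[ii[r], jj[r]] <- L[ii[r], jj[r]] - cnt[r]
      L[jj[r], ii[r]] <- L[jj[r], ii[r]] - cnt[r]
    }
    b <- numeric(n)
    bi <- tapply(ow$v, ow$i, sum)
    bj <- tapply(ow$v, ow$j, sum)
    b[as.integer(names(bi))] <- b[as.integer(names(bi))] + bi
    b[as.integer(names(bj))] <- b[as.integer(names(bj))] - bj
    present <- which(diag(L) > 0)
    if (!ref_i %in% present) next
    # keep only stations connected to the reference within this window
    comp <- connected_component(L, present, ref_i)
    keep <- setdiff(comp, ref_i)
    if (length(keep) == 0) { off[ref_i, w] <- 0; next }
    sol <- solve(L[keep, keep, drop = FALSE], b[keep])
    off[keep, w] <- sol
    off[ref_i, w] <- 0
  }

  never <- rowSums(!is.na(off)) == 0
  flagged <- union(flagged, ids[never])

  structure(list(stations = ids, reference = reference, flagged = flagged,
                 window_mid_s = mids, offsets = off, window_s = window_s),
            class = "clock_model")
}

connected_component <- function(L, present, start) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier, function(i)
      present[L[i, present] < 0])))
    frontier <- setdiff(nb, seen)
    seen <- c(seen, frontier)
  }
  sort(seen)
}

#' Evaluate the modeled clock offset
#'
#' @param model a `clock_model`.
#' @param receiver_id station ids (vectorized with `t_s`).
#' @param t_s times (s) at which to evaluate the offset.
#' @return Offsets in seconds; `NA` for flagged stations.
#' @export
clock_offset <- function(model, receiver_id, t_s) {
  out <- numeric(length(receiver_id))
  mids <- model$window_mid_s
  for (id in unique(receiver_id)) {
    sel <- receiver_id == id
    if (id %in% model$flagged || !id %in% model$stations) {
      out[sel] <- NA_real_
      next
    }
    o <- model$offsets[id, ]
    ok <- !is.na(o)
    if (!any(ok)) { out[sel] <- NA_real_; next }
    xs <- mids[ok]; ys <- o[ok]
    if (length(xs) == 1L) {
      out[sel] <- ys
    } else {
      t <- t_s[sel]
      v <- stats::approx(xs, ys, xout = t, rule = 2)$y
      # linear extrapolation along the outermost segments
      lo <- t < xs[1]
      if (any(lo)) {
        sl <- (ys[2] - ys[1]) / (xs[2] - xs[1])
        v[lo] <- ys[1] + sl * (t[lo] - xs[1])
      }
      m <- length(xs)
      hi <- t > xs[m]
      if (any(hi)) {
        sl <- (ys[m] - ys[m - 1]) / (xs[m] - xs[m - 1])
        v[hi] <- ys[m] + sl * (t[hi] - xs[m])
      }
      out[sel] <- v
    }
  }
  out
}

#' Apply a clock model to detections
#'
#' Subtracts the modeled per-station clock offset from arrival times and drops
#' detections from stations flagged as never having heard a beacon.
#'
#' @param dets detection data.frame.
#' @param model a `clock_model`.
#' @return The corrected detections (column `arrival_time_s` adjusted).
#' @export
correct_detections <- function(dets, model) {
  keep <- !dets$receiver_id %in% model$flagged
  out <- dets[keep, , drop = FALSE]
  out$arrival_time_s <- out$arrival_time_s -
    clock_offset(model, out$receiver_id, out$arrival_time_s)
  rownames(out) <- NULL
  out
}

#' Group detections into transmission events
#'
#' Single-linkage clustering of (clock-corrected) arrival times per tag: a new
#' group starts wherever the gap to the previous detection exceeds the maximum
#' acoustic travel-time across the array plus a guard. Groups with fewer than
#' three distinct receivers are retained but cannot be localized.
#'
#' @param dets detection data.frame sorted by arrival time (sorted internally
#'   if not).
#' @param gap_s gap threshold (s); if `NULL`, computed as
#'   `array_span_m / c_sound + guard_s`.
#' @param array_span_m maximum station separation (m).
#' @param c_sound speed of sound (m/s).
#' @param guard_s additional guard for timing noise (s).
#' @return `dets` with an added integer `group_id` column (unique across tags),
#'   sorted by tag and time.
#' @export
group_transmissions <- function(dets, gap_s = NULL, array_span_m = NULL,
                                c_sound = 1500, guard_s = 0.05) {
  if (nrow(dets) == 0) {
    dets$group_id <- integer(0)
    return(dets)
  }
  if (is.null(gap_s)) {
    stopifnot(!is.null(array_span_m))
    gap_s <- array_span_m / c_sound + guard_s
  }
  ord <- order(dets$tag_id, dets$arrival_time_s)
  d <- dets[ord, , drop = FALSE]
  new_tag <- c(TRUE, d$tag_id[-1] != d$tag_id[-nrow(d)])
  gap <- c(Inf, diff(d$arrival_time_s))
  d$group_id <- cumsum(new_tag | gap > gap_s)
  rownames(d) <- NULL
  # carry truth attributes through the reordering when present
  for (a in c("emission_s")) {
    v <- attr(dets, a)
    if (!is.null(v)) attr(d, a) <- v[ord]
  }
  attr(d, "truth") <- attr(dets, "truth")
  d
}

station_collinear <- function(xy, tol = 1e-6) {
  if (nrow(xy) < 3) return(TRUE)
  p <- xy[1, ]
  q <- xy[which.max((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2), ]
  v <- q - p
  nv <- sqrt(sum(v^2))
  if (nv < tol) return(TRUE)
  perp <- abs((xy[, 1] - p[1]) * v[2] - (xy[, 2] - p[2]) * v[1]) / nv
  max(perp) < tol
}

#' Localize transmission groups by DToA error-map minimization
#'
#' For every pair of receivers detecting the same transmission, the difference
#' of time of arrival constrains the source; the pairwise mismatch
#' `|(t_i - t_j) - (|x - r_i| - |x - r_j|)/c|` is evaluated on a horizontal
#' grid at the tag-reported depth, summed over all pairs, and minimized
#' (coarse-to-fine grid search plus sub-cell quadratic refinement). Groups
#' with fewer than `min_receivers` distinct stations, or with effectively
#' collinear stations (mirror-ambiguous geometry), are skipped.
#'
#' @param grouped clock-corrected detections with a `group_id` column (see
#'   [group_transmissions()]).
#' @param stations station table (`id, x, y, z`), or a `receiver_array`.
#' @param grid fine grid spacing (m).
#' @param c_sound speed of sound (m/s).
#' @param inflate margin added around the station bounding box (m).
#' @param coarse_factor coarse-stage spacing as a multiple of `grid`; 1
#'   disables the coarse stage (exhaustive fine grid).
#' @param aggregate `"abs"` (sum of absolute pairwise residuals, default) or
#'   `"sq"` (sum of squares).
#' @param min_receivers minimum distinct receivers per localizable group.
#' @return A data.frame of position fixes:
#'   `tag_id, time_s, x, y, z, residual_s, n_receivers`.
#' @export
localize_fixes <- function(grouped, stations, grid = 1, c_sound = 1500,
                           inflate = 50, coarse_factor = 8,
                           aggregate = c("abs", "sq"), min_receivers = 3) {
  aggregate <- match.arg(aggregate)
  if (inherits(stations, "receiver_array")) stations <- stations$stations
  if (nrow(grouped) == 0 || is.null(grouped$group_id))
    return(empty_fixes())

  srow <- match(grouped$receiver_id, stations$id)
  if (anyNA(srow)) stop("detections reference unknown stations")

  ord <- order(grouped$group_id)
  g <- grouped[ord, , drop = FALSE]
  srow <- srow[ord]

  ids <- g$group_id
  starts <- which(c(TRUE, ids[-1] != ids[-length(ids)]))
  ends <- c(starts[-1] - 1L, length(ids))

  nrec <- vapply(seq_along(starts), function(i)
    length(unique(g$receiver_id[starts[i]:ends[i]])), integer(1))
  ok <- nrec >= min_receivers
  if (any(ok)) {
    col_ok <- vapply(which(ok), function(i) {
      ix <- starts[i]:ends[i]
      !station_collinear(unique(cbind(stations$x[srow[ix]],
                                      stations$y[srow[ix]])))
    }, logical(1))
    ok[ok] <- col_ok
  }
  if (!any(ok)) return(empty_fixes())

  keep_groups <- which(ok)
  idx <- unlist(lapply(keep_groups, function(i) starts[i]:ends[i]))
  lens <- ends[keep_groups] - starts[keep_groups] + 1L
  grp_ptr <- c(0L, cumsum(lens))
  zt <- vapply(keep_groups, function(i)
    mean(g$depth_m[starts[i]:ends[i]]), numeric(1))

  bb <- c(min(stations$x) - inflate, max(stations$x) + inflate,
          min(stations$y) - inflate, max(stations$y) + inflate)
  res <- cpp_localize_batch(g$arrival_time_s[idx],
                            stations$x[srow[idx]], stations$y[srow[idx]],
                            stations$z[srow[idx]],
                            as.integer(grp_ptr), zt,
                            bb[1], bb[2], bb[3], bb[4], grid,
                            as.integer(coarse_factor), c_sound,
                            aggregate == "sq")

  # emission-time estimate: mean corrected arrival minus mean travel time
  time_s <- vapply(seq_along(keep_groups), function(i) {
    ix <- idx[(grp_ptr[i] + 1):grp_ptr[i + 1]]
    dts <- sqrt((res[i, 1] - stations$x[srow[ix]])^2 +
                  (res[i, 2] - stations$y[srow[ix]])^2 +
                  (zt[i] - stations$z[srow[ix]])^2)
    mean(g$arrival_time_s[ix]) - mean(dts) / c_sound
  }, numeric(1))

  data.frame(tag_id = g$tag_id[starts[keep_groups]],
             time_s = time_s,
             x = res[, 1], y = res[, 2], z = zt,
             residual_s = res[, 3],
             n_receivers = nrec[keep_groups],
             stringsAsFactors = FALSE)
}

empty_fixes <- function() {
  data.frame(tag_id = character(), time_s = numeric(), x = numeric(),
             y = numeric(), z = numeric(), residual_s = numeric(),
             n_receivers = integer(), stringsAsFactors = FALSE)
}

#' Localize a single transmission group
#'
#' Convenience wrapper around [localize_fixes()] for one group of detections.
#'
#' @param times corrected arrival times (s), one per detection.
#' @param receiver_ids station id per detection.
#' @param depth tag-reported depth (m).
#' @inheritParams localize_fixes
#' @return A one-row fix data.frame, or `NULL` if the group is not
#'   localizable.
#' @export
localize_dtoa <- function(times, receiver_ids, depth, stations, grid = 1,
                          c_sound = 1500, inflate = 50, coarse_factor = 8,
                          aggregate = "abs") {
  d <- data.frame(receiver_id = receiver_ids, tag_id = "tag",
                  arrival_time_s = times, depth_m = depth,
                  group_id = 1L, stringsAsFactors = FALSE)
  f <- localize_fixes(d, stations, grid = grid, c_sound = c_sound,
                      inflate = inflate, coarse_factor = coarse_factor,
                      aggregate = aggregate)
  if (nrow(f) == 0) NULL else f
}
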