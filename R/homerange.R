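triangle_circumradius <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2)); b <- sqrt(sum((p1 - p3)^2))
  cc <- sqrt(sum((p1 - p2)^2))
  ar <- abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
              (p3[1] - p1[1]) * (p2[2] - p1[2])) / 2
  if (ar <= .Machine$double.eps) return(Inf)
  a * b * cc / (4 * ar)
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1)
  sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2]) / 2
}

# union-find
uf_find <- function(par, i) {
  while (par[i] != i) i <- par[i]
  i
}

delaunay_triangles <- function(pts) {
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  t(vapply(tl, function(tr) as.integer(tr$ptNum), integer(3)))
}

#' Alpha-shape home-range boundary
#'
#' Concave boundary around a set of position fixes, built from the Delaunay
#' triangulation: triangles with circumradius above an alpha threshold are
#' removed, and the boundary of the remaining region is returned. The
#' `shrink_factor` selects alpha on a monotone scale between the convex hull
#' (shrink 0: all triangles kept) and the tightest alpha that still keeps a
#' single connected region containing every input point (shrink 1).
#'
#' @param points two-column matrix or data.frame of (x, y) fixes (m).
#' @param shrink_factor concavity, in \[0, 1\]; default 0.5.
#' @return An object of class `home_range`: `boundary` (outer ring, closed
#'   counter-clockwise matrix), `rings` (all boundary loops), `area` (m^2,
#'   exact area of the kept triangles), `shrink_factor`, `method = "alpha"`.
#' @export
boundary_polygon <- function(points, shrink_factor = 0.5) {
  stopifnot(shrink_factor >= 0, shrink_factor <= 1)
  pts <- unique(as.matrix(points[, 1:2]))
  storage.mode(pts) <- "double"
  if (nrow(pts) < 3 || station_collinear(pts, tol = 1e-9))
    stop("need at least 3 non-collinear points")

  tri <- delaunay_triangles(pts)
  n_tri <- nrow(tri)
  circ <- vapply(seq_len(n_tri), function(i)
    triangle_circumradius(pts[tri[i, 1], ], pts[tri[i, 2], ], pts[tri[i, 3], ]),
    numeric(1))
  areas <- vapply(seq_len(n_tri), function(i)
    abs(shoelace_area(pts[tri[i, ], ])), numeric(1))

  # feasibility of an alpha threshold: the kept triangles must cover every
  # point and form one edge-connected region
  feasible <- function(alpha) {
    keep <- which(circ <= alpha)
    if (length(keep) == 0) return(FALSE)
    if (!all(seq_len(nrow(pts)) %in% tri[keep, , drop = FALSE])) return(FALSE)
    par <- seq_along(keep)
    ek <- matrix(0L, 3 * length(keep), 2)
    for (m in seq_along(keep)) {
      v <- sort(tri[keep[m], ])
      ek[3 * m - 2, ] <- c(v[1], v[2])
      ek[3 * m - 1, ] <- c(v[1], v[3])
      ek[3 * m, ] <- c(v[2], v[3])
    }
    key <- ek[, 1] * (nrow(pts) + 1) + ek[, 2]
    owner <- rep(seq_along(keep), each = 3)
    sp <- split(owner, key)
    for (grp in sp) {
      if (length(grp) == 2) {
        r1 <- uf_find(par, grp[1]); r2 <- uf_find(par, grp[2])
        if (r1 != r2) par[r1] <- r2
      }
    }
    roots <- vapply(seq_along(keep), function(i) uf_find(par, i), integer(1))
    length(unique(roots)) == 1
  }

  cand <- sort(unique(circ[is.finite(circ)]), decreasing = TRUE)
  if (length(cand) == 0) stop("degenerate triangulation")
  # binary search for the smallest feasible candidate (feasibility is
  # monotone: raising alpha only adds triangles)
  lo <- 1L; hi <- length(cand)
  if (!feasible(cand[1])) stop("triangulation not connected at the hull alpha")
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (feasible(cand[mid])) lo <- mid else hi <- mid - 1L
  }
  feas <- cand[seq_len(lo)]                 # descending, all feasible
  pick <- feas[1 + round(shrink_factor * (length(feas) - 1))]
  keep <- which(circ <= pick)

  rings <- boundary_rings(pts, tri[keep, , drop = FALSE])
  ring_area <- vapply(rings, shoelace_area, numeric(1))
  outer_i <- which.max(abs(ring_area))
  outer <- rings[[outer_i]]
  if (shoelace_area(outer) < 0) outer <- outer[rev(seq_len(nrow(outer))), ]

  structure(list(boundary = outer, rings = rings,
                 area = sum(areas[keep]), shrink_factor = shrink_factor,
                 alpha = pick, n_points = nrow(pts), method = "alpha"),
            class = "home_range")
}

# Extract closed boundary loops (edges used by exactly one kept triangle).
boundary_rings <- function(pts, tri) {
  if (nrow(tri) == 0) stop("no triangles kept")
  e <- rbind(tri[, c(1, 2)], tri[, c(1, 3)], tri[, c(2, 3)])
  e <- t(apply(e, 1, sort))
  key <- paste(e[, 1], e[, 2])
  once <- names(which(table(key) == 1))
  be <- e[key %in% once, , drop = FALSE]
  # chain edges into loops via vertex adjacency
  adj <- split(rep(seq_len(nrow(be)), 2), c(be[, 1], be[, 2]))
  used <- rep(FALSE, nrow(be))
  rings <- list()
  for (start in seq_len(nrow(be))) {
    if (used[start]) next
    loop <- c(be[start, 1], be[start, 2])
    used[start] <- TRUE
    repeat {
      v <- loop[length(loop)]
      nxt <- adj[[as.character(v)]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      eidx <- nxt[1]
      used[eidx] <- TRUE
      w <- setdiff(be[eidx, ], v)
      if (length(w) == 0) w <- v
      if (w == loop[1]) break
      loop <- c(loop, w)
    }
    rings[[length(rings) + 1]] <- pts[loop, , drop = FALSE]
  }
  rings
}

#' Kernel-density home range
#'
#' Gaussian-kernel utilization distribution on a grid; the home range is the
#' smallest region enclosing the stated probability mass (isopleth), found by
#' thresholding the density at the level where cumulative sorted cell mass
#' reaches the isopleth.
#'
#' @param points two-column matrix of (x, y) fixes.
#' @param bandwidth Gaussian kernel standard deviation (m); default: normal
#'   reference (Silverman) rule, averaged over the two axes.
#' @param isopleth probability mass enclosed (default 0.95).
#' @param n grid resolution per axis.
#' @return A `home_range` object (`method = "kde"`) with the thresholded grid
#'   kept for overlap computations; `area` is the total area of cells above
#'   the isopleth level.
#' @export
kde_home_range <- function(points, bandwidth = NULL, isopleth = 0.95, n = 128) {
  pts <- as.matrix(points[, 1:2])
  if (nrow(pts) < 10) stop("need at least 10 points")
  if (is.null(bandwidth))
    bandwidth <- mean(c(MASS::bandwidth.nrd(pts[, 1]),
                        MASS::bandwidth.nrd(pts[, 2]))) / 4
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  pad <- 4 * bandwidth
  lims <- c(range(pts[, 1]) + c(-pad, pad), range(pts[, 2]) + c(-pad, pad))
  k <- MASS::kde2d(pts[, 1], pts[, 2], h = 4 * bandwidth, n = n, lims = lims)
  cell <- diff(k$x[1:2]) * diff(k$y[1:2])
  mass <- as.vector(k$z) * cell
  mass <- mass / sum(mass)
  o <- order(mass, decreasing = TRUE)
  cum <- cumsum(mass[o])
  level <- as.vector(k$z)[o][which(cum >= isopleth)[1]]
  mask <- k$z >= level
  cl <- grDevices::contourLines(k$x, k$y, k$z, levels = level)
  rings <- lapply(cl, function(r) cbind(r$x, r$y))
  outer_i <- if (length(rings)) which.max(vapply(rings, function(r)
    abs(shoelace_area(r)), numeric(1))) else integer(0)
  structure(list(boundary = if (length(outer_i)) rings[[outer_i]] else NULL,
                 rings = rings, area = sum(mask) * cell,
                 bandwidth = bandwidth, isopleth = isopleth,
                 grid = list(x = k$x, y = k$y, mask = mask),
                 n_points = nrow(pts), method = "kde"),
            class = "home_range")
}

#' Point-in-range test
#'
#' Even-odd test of points against all boundary loops of a home range.
#'
#' @param hr a `home_range`.
#' @param points two-column matrix of query points.
#' @return Logical vector.
#' @export
hr_contains <- function(hr, points) {
  bnd <- do.call(rbind, lapply(hr$rings, function(r)
    rbind(r, r[1, , drop = FALSE], c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  pts <- as.matrix(points[, 1:2, drop = FALSE])
  mgcv::in.out(bnd, pts)
}

#' Intersection-over-union of two home ranges
#'
#' Rasterizes both ranges on a common grid of cell centres and computes the
#' Jaccard overlap of the resulting masks.
#'
#' @param a,b `home_range` objects.
#' @param cell raster cell size (m).
#' @return IoU in \[0, 1\].
#' @export
hr_iou <- function(a, b, cell = 1) {
  bb <- function(h) {
    r <- do.call(rbind, h$rings)
    c(range(r[, 1]), range(r[, 2]))
  }
  ba <- bb(a); bbx <- bb(b)
  xs <- seq(min(ba[1], bbx[1]), max(ba[2], bbx[2]), by = cell)
  ys <- seq(min(ba[3], bbx[3]), max(ba[4], bbx[4]), by = cell)
  g <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  ina <- hr_contains(a, g)
  inb <- hr_contains(b, g)
  un <- sum(ina | inb)
  if (un == 0) return(0)
  sum(ina & inb) / un
}

#' Dwell-time occupancy map
#'
#' Deposits one minute of dwell time per trajectory sample into square bins,
#' smooths with a truncated (4 sigma) Gaussian kernel renormalized at the
#' edges so total dwell time is conserved, and adds a log10 display layer.
#'
#' @param traj a `regular_trajectory` (or any data.frame with `x`, `y`).
#' @param bin bin side length (m); default 5.
#' @param sigma Gaussian smoothing standard deviation (m); default 2.5.
#' @param eps offset added before taking log10 for display (minutes).
#' @return An object of class `occupancy_grid`: `origin`, `bin`, matrices
#'   `counts`, `smoothed`, `display` (x along rows), `total_minutes`.
#' @export
occupancy_map <- function(traj, bin = 5, sigma = 2.5, eps = 1e-3) {
  stopifnot(nrow(traj) > 0)
  ox <- floor(min(traj$x) / bin) * bin
  oy <- floor(min(traj$y) / bin) * bin
  ix <- floor((traj$x - ox) / bin) + 1L
  iy <- floor((traj$y - oy) / bin) + 1L
  nx <- max(ix); ny <- max(iy)
  counts <- matrix(0, nx, ny)
  for (i in seq_along(ix)) counts[ix[i], iy[i]] <- counts[ix[i], iy[i]] + 1

  rad <- ceiling(4 * sigma / bin)
  off <- -rad:rad
  kern <- outer(stats::dnorm(off, sd = sigma / bin),
                stats::dnorm(off, sd = sigma / bin))
  sm <- matrix(0, nx, ny)
  nz <- which(counts > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(nz))) {
    i <- nz[r, 1]; j <- nz[r, 2]
    xi <- pmax(1, i - rad):pmin(nx, i + rad)
    yj <- pmax(1, j - rad):pmin(ny, j + rad)
    kk <- kern[xi - i + rad + 1, yj - j + rad + 1, drop = FALSE]
    sm[xi, yj] <- sm[xi, yj] + counts[i, j] * kk / sum(kk)
  }
  structure(list(origin = c(ox, oy), bin = bin, sigma = sigma,
                 counts = counts, smoothed = sm,
                 display = log10(sm + eps), total_minutes = sum(counts)),
            class = "occupancy_grid")
}

#' Home-range stability between study epochs
#'
#' Alpha-shape boundaries over the first and last `k` days and their
#' intersection-over-union.
#'
#' @param traj a `regular_trajectory` with a `day` column.
#' @param first_k_days,last_k_days number of days in each epoch.
#' @param shrink_factor passed to [boundary_polygon()].
#' @return A list with `first`, `last` (`home_range` objects) and `iou`.
#' @export
range_stability <- function(traj, first_k_days = 3, last_k_days = first_k_days,
                            shrink_factor = 0.5) {
  days <- sort(unique(traj$day))
  if (length(days) < first_k_days + last_k_days)
    stop("need at least first_k_days + last_k_days distinct days")
  d1 <- days[seq_len(first_k_days)]
  d2 <- days[seq(length(days) - last_k_days + 1, length(days))]
  hr1 <- boundary_polygon(traj[traj$day %in% d1, c("x", "y")], shrink_factor)
  hr2 <- boundary_polygon(traj[traj$day %in% d2, c("x", "y")], shrink_factor)
  list(first = hr1, last = hr2, iou = hr_iou(hr1, hr2))
}

#' Sleeping-site summary
#'
#' Geometric median (Weiszfeld iteration) of nighttime fixes and the radius
#' containing 95 percent of them.
#'
#' @param fixes position fixes (`time_s, x, y`).
#' @param day_windows data.frame `day, sunrise_min, sunset_min`.
#' @return A list `center` (x, y), `radius95` (m), `n` (night fixes used).
#' @export
sleeping_site <- function(fixes, day_windows) {
  mday <- (fixes$time_s / 60) %% 1440
  day <- fix_day(fixes$time_s)
  i <- match(day, day_windows$day)
  night <- is.na(i) | mday < day_windows$sunrise_min[i] |
    mday >= day_windows$sunset_min[i]
  p <- cbind(fixes$x[night], fixes$y[night])
  if (nrow(p) == 0) stop("no nighttime fixes")
  ctr <- colMeans(p)
  for (it in 1:100) {
    d <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
    d <- pmax(d, 1e-9)
    new <- c(sum(p[, 1] / d), sum(p[, 2] / d)) / sum(1 / d)
    if (sum((new - ctr)^2) < 1e-12) { ctr <- new; break }
    ctr <- new
  }
  d <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2)
  list(center = ctr, radius95 = unname(stats::quantile(d, 0.95)), n = nrow(p))
}

#' @export
print.home_range <- function(x, ...) {
  cat("Home range (", x$method, "): area ", round(x$area, 1), " m^2 from ",
      x$n_points, " points\n", sep = "")
  invisible(x)
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat("Occupancy grid:", nrow(x$counts), "x", ncol(x$counts), "bins of",
      x$bin, "m;", x$total_minutes, "minutes of dwell time\n")
  invisible(x)
}

#' @export
plot.occupancy_grid <- function(x, ...) {
  xs <- x$origin[1] + (seq_len(nrow(x$display)) - 0.5) * x$bin
  ys <- x$origin[2] + (seq_len(ncol(x$display)) - 0.5) * x$bin
  graphics::image(xs, ys, x$display, xlab = "x (m)", ylab = "y (m)",
                  main = "log10 occupancy (min)", asp = 1, ...)
  invisible(x)
}

#' @export
plot.home_range <- function(x, add = FALSE, ...) {
  if (!add)
    graphics::plot(x$boundary, type = "n", xlab = "x (m)", ylab = "y (m)",
                   asp = 1)
  for (r in x$rings)
    graphics::polygon(r[, 1], r[, 2], ...)
  invisible(x)
}
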