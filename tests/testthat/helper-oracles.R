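# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain-R brute force, closed forms, and direct
# simulations.

# Exhaustive fine-grid DToA argmin (no coarse stage, no refinement).
brute_force_dtoa <- function(times, sx, sy, sz, z_tag, bbox, spacing,
                             c_sound = 1500) {
  xs <- seq(bbox[1], bbox[2], by = spacing)
  ys <- seq(bbox[3], bbox[4], by = spacing)
  best <- c(NA, NA); best_e <- Inf
  for (py in ys) for (px in xs) {
    d <- sqrt((px - sx)^2 + (py - sy)^2 + (z_tag - sz)^2)
    e <- 0
    k <- length(times)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      e <- e + abs((times[i] - times[j]) - (d[i] - d[j]) / c_sound)
    if (e < best_e) { best_e <- e; best <- c(px, py) }
  }
  list(xy = best, err = best_e)
}

# Direct Markov-chain simulation of mode labels (no movement model).
markov_modes <- function(P, n_steps, init, seed) {
  set.seed(seed)
  cum <- t(apply(P, 1, cumsum))
  s <- integer(n_steps)
  s[1] <- init
  for (i in 2:n_steps) {
    s[i] <- findInterval(runif(1), cum[s[i - 1], ]) + 1L
    if (s[i] > nrow(P)) s[i] <- nrow(P)
  }
  s
}

# Mean dwell (sojourn) times of a run-length encoded state sequence.
dwell_times <- function(states) {
  r <- rle(states)
  split(r$lengths, r$values)
}

# Naive O(n^3) agglomerative clustering with Ward.D2-equivalent
# (minimum-variance) merge costs, via Lance-Williams on squared distances.
naive_ward_tree <- function(X) {
  n <- nrow(X)
  D2 <- as.matrix(dist(X))^2
  size <- rep(1, n)
  active <- seq_len(n)
  id <- -seq_len(n)              # hclust convention: negatives are leaves
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a >= b) next
      i <- active[a]; j <- active[b]
      if (D2[i, j] < best_d) { best_d <- D2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(best_d)
    merges[step, ] <- sort(c(id[i], id[j]))
    for (k in active) {
      if (k == i || k == j) next
      # Lance-Williams update for Ward on squared Euclidean distances
      D2[i, k] <- D2[k, i] <-
        ((size[i] + size[k]) * D2[i, k] + (size[j] + size[k]) * D2[j, k] -
           size[k] * D2[i, j]) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  list(merge = merges, height = heights)
}

# Brute-force covariance eigendecomposition PCA.
eigen_pca <- function(X) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  list(values = ev$values, vectors = ev$vectors,
       var_frac = ev$values / sum(ev$values))
}

# Day length (hours) from a coarse independent solar model: declination from
# the standard 23.44 deg sine approximation, hour angle with -0.833 deg
# altitude at rise/set.
coarse_day_length_h <- function(date, lat) {
  doy <- as.integer(strftime(as.Date(date), "%j"))
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  phi <- lat * pi / 180
  cos_ha <- (sin(-0.833 * pi / 180) - sin(phi) * sin(decl)) /
    (cos(phi) * cos(decl))
  2 * acos(pmin(1, pmax(-1, cos_ha))) * 180 / pi / 15
}

# Adjusted Rand index between two labelings, straight from the
# Hubert-Arabie formula (no package code).
ari <- function(a, b) {
  t <- table(a, b)
  n <- sum(t)
  sij <- sum(choose(t, 2))
  ai <- sum(choose(rowSums(t), 2))
  bj <- sum(choose(colSums(t), 2))
  e <- ai * bj / choose(n, 2)
  m <- (ai + bj) / 2
  if (m == e) return(1)
  (sij - e) / (m - e)
}

# Tiny default study used by several tests (cheap: 2 days, 1 fish).
make_tiny_study <- function(seed = 42, n_days = 2) {
  scfg <- sim_config(n_days = n_days, seed = seed)
  half <- scfg$home_extent / 2 + 20
  bounds <- c(scfg$home_center[1] - half[1], scfg$home_center[1] + half[1],
              scfg$home_center[2] - half[2], scfg$home_center[2] + half[2])
  array <- build_triangular_array(bounds, 45)
  traj <- simulate_trajectory(scfg)
  list(config = scfg, array = array, traj = traj,
       day_windows = sim_day_windows(scfg))
}
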