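# helpers ---------------------------------------------------------------

grid_traj <- function(n_min, x, y, day = 1, t0 = 0) {
  data.frame(day = day, t_min = t0 + 0:n_min,
             x = rep_len(x, n_min + 1), y = rep_len(y, n_min + 1))
}

dw1 <- function(sunrise = 0, sunset = 600)
  data.frame(day = 1, sunrise_min = sunrise, sunset_min = sunset)

# segmentation ----------------------------------------------------------

test_that("a 600-minute day cuts into 39 half-overlapping segments", {
  tr <- grid_traj(600, x = 1:601, y = 0)
  segs <- segment_daily(tr, dw1(), length_min = 30, overlap = 0.5)
  # arithmetic oracle: floor((600 - 30) / 15) + 1 starts at 0, 15, ..., 570
  expect_length(segs, floor((600 - 30) / 15) + 1)
  expect_equal(vapply(segs, `[[`, numeric(1), "start_min"), seq(0, 570, 15))
  expect_true(all(vapply(segs, function(s) nrow(s$pts), integer(1)) == 31L))
  # consecutive segments share exactly their overlapping half of the grid
  expect_equal(segs[[2]]$pts[1:16, ], segs[[1]]$pts[16:31, ])
})

test_that("zero overlap starts segments at multiples of the window length", {
  tr <- grid_traj(600, x = 1:601, y = 0)
  segs <- segment_daily(tr, dw1(), length_min = 30, overlap = 0)
  starts <- vapply(segs, `[[`, numeric(1), "start_min")
  expect_true(all(starts %% 30 == 0))
  expect_length(segs, 20)
})

test_that("a day shorter than one window yields no segments, with a warning", {
  tr <- grid_traj(29, x = 1:30, y = 0)
  expect_warning(segs <- segment_daily(tr, dw1(0, 29)), "shorter")
  expect_length(segs, 0)
})

# feature identities ----------------------------------------------------

test_that("a straight east path has the collinear feature identities", {
  pts <- cbind(0:30, rep(0, 31))           # 30 m east at 1 m/min
  f <- compute_features(pts, center = c(-10, 0), start_min = 0,
                        day_length_min = 720)
  expect_equal(f[["D"]], 30)
  expect_equal(f[["L"]], 30)
  expect_equal(f[["S"]], 1)
  expect_equal(f[["A"]], 0)
  expect_equal(f[["MS"]], 1)
  expect_equal(f[["F"]], 1)
  expect_equal(f[["DAC5"]], 1)
  expect_equal(f[["DAC10"]], 1)
  # centroid (15, 0) is due east of the center: theta = cos(0) = 1
  expect_equal(f[["theta"]], 1)
  expect_equal(f[["rho"]], 25)
})

test_that("a closed loop returning to its start has zero straightness", {
  sq <- rbind(cbind(0:10, 0), cbind(10, 1:10), cbind(9:0, 10), cbind(0, 9:0))
  f <- compute_features(sq, c(0, 0), 0, 720)
  expect_equal(f[["D"]], 0)
  expect_equal(f[["S"]], 0)
  expect_equal(f[["L"]], 40)
  expect_equal(f[["A"]], 100)
})

test_that("a full circle's focus approaches 1 - 1/pi^2", {
  r <- 20
  circle <- function(n) {
    th <- seq(0, 2 * pi, length.out = n + 1)
    cbind(r * cos(th), r * sin(th))
  }
  f <- compute_features(circle(600), c(0, 0), 0, 720)
  # geometric oracle: dense polygonal evaluation of A and L
  dense <- circle(20000)
  L_o <- sum(sqrt(rowSums(diff(dense)^2)))
  A_o <- abs(sum(dense[-1, 1] * dense[-nrow(dense), 2] -
                   dense[-nrow(dense), 1] * dense[-1, 2]) / 2)
  expect_lt(abs(f[["F"]] - (1 - 4 * A_o / (pi * L_o^2))), 1e-4)
  expect_lt(abs(f[["F"]] - (1 - 1 / pi^2)), 1e-3)
  expect_lt(f[["S"]], 1e-9)
})

test_that("hand-computed features of a tiny L-shaped path are reproduced", {
  pts <- rbind(c(0, 0), c(3, 0), c(3, 4))
  f <- compute_features(pts, c(0, 0), start_min = 100, day_length_min = 720)
  expect_equal(f[["D"]], 5)
  expect_equal(f[["L"]], 7)
  expect_equal(f[["S"]], 5 / 7)
  expect_equal(f[["A"]], 6)                 # right triangle 3 x 4
  expect_equal(f[["MS"]], 3.5)              # median of steps 3, 4
  centroid <- c(2, 4 / 3)
  expect_equal(f[["rho"]], sqrt(sum(centroid^2)))
  expect_equal(f[["theta"]], centroid[1] / sqrt(sum(centroid^2)))
  # DP: midpoint of a 3-point segment starting at minute 100
  expect_equal(f[["DP"]], (100 + 1) / 720)
})

test_that("a motionless segment is maximally focused, not undefined", {
  pts <- matrix(5, nrow = 31, ncol = 2)
  f <- compute_features(pts, c(0, 0), 0, 720)
  expect_equal(f[["S"]], 0)
  expect_equal(f[["F"]], 1)
  expect_equal(f[["MS"]], 0)
  expect_equal(f[["DAC5"]], 0)              # no step carries a heading
  expect_equal(f[["SAC5"]], 0)              # zero speed variance
  expect_false(anyNA(f))
})

test_that("feature bounds hold on a thousand random segments", {
  set.seed(88)
  for (i in 1:1000) {
    pts <- cbind(cumsum(rnorm(31, sd = 3)), cumsum(rnorm(31, sd = 3)))
    f <- compute_features(pts, c(0, 0), 0, 720)
    expect_gte(f[["L"]], f[["D"]])
    expect_true(f[["S"]] >= 0 && f[["S"]] <= 1)
    expect_gte(f[["A"]], 0)
    expect_lte(f[["F"]], 1)
    expect_true(f[["DP"]] >= 0 && f[["DP"]] <= 1)
    expect_true(all(abs(f[c("DAC5", "DAC10", "SAC5", "SAC10",
                            "theta")]) <= 1 + 1e-12))
    expect_false(anyNA(f))
  }
})

test_that("rigid motions leave the geometric features unchanged", {
  set.seed(41)
  pts <- cbind(cumsum(rnorm(31, 1)), cumsum(rnorm(31, 0.3)))
  center <- c(-20, 5)
  phi <- 0.85; shift <- c(120, -60)
  R <- rbind(c(cos(phi), -sin(phi)), c(sin(phi), cos(phi)))
  pts2 <- sweep(pts %*% t(R), 2, shift, `+`)
  center2 <- as.numeric(R %*% center + shift)
  f1 <- compute_features(pts, center, 0, 720)
  f2 <- compute_features(pts2, center2, 0, 720)
  inv <- c("D", "L", "S", "A", "MS", "rho", "DAC5", "DAC10",
           "SAC5", "SAC10", "DP", "F")
  expect_equal(f1[inv], f2[inv], tolerance = 1e-9)
  # theta is measured from the fixed east axis, so rotation changes it
  expect_false(isTRUE(all.equal(f1[["theta"]], f2[["theta"]])))
})

test_that("speed autocorrelation matches a direct Pearson computation", {
  set.seed(9)
  pts <- cbind(cumsum(runif(31, 0.5, 3)), 0)
  f <- compute_features(pts, c(0, 0), 0, 720)
  sp <- sqrt(rowSums(diff(pts)^2))
  for (lag in c(5, 10)) {
    i <- seq_len(length(sp) - lag)
    expect_equal(f[[paste0("SAC", lag)]], cor(sp[i], sp[i + lag]),
                 tolerance = 1e-12)
  }
})

test_that("directional autocorrelation ignores sub-epsilon steps", {
  # alternating: one 1-m east step, one 1-mm jiggle; only real steps count
  n <- 30
  dx <- rep(c(1, 1e-3), n / 2)
  pts <- cbind(cumsum(c(0, dx)), 0)
  f <- compute_features(pts, c(0, 0), 0, 720)
  # all valid headings are due east: perfect correlation despite the jiggles
  expect_equal(f[["DAC10"]], 1)
})

# global center and matrix assembly -------------------------------------

test_that("the global center is the coordinate-wise median of all fixes", {
  xy <- cbind(c(1, 2, 100), c(5, -50, 6))
  expect_equal(global_center(xy), c(2, 5))
})

test_that("the feature matrix has one well-formed row per segment", {
  set.seed(6)
  tr <- grid_traj(120, x = cumsum(rnorm(121)), y = cumsum(rnorm(121)))
  segs <- segment_daily(tr, dw1(0, 120))
  fm <- segment_features(segs)
  expect_equal(nrow(fm), length(segs))
  expect_true(all(feature_names() %in% names(fm)))
  expect_false(anyNA(fm))
  # the stored center is the median of all segment points
  expect_equal(attr(fm, "center"),
               global_center(do.call(rbind, lapply(segs, `[[`, "pts"))))
})

test_that("scaling yields unit standard deviations and flags constants", {
  set.seed(14)
  tr <- grid_traj(240, x = cumsum(rnorm(241, 1)), y = cumsum(rnorm(241)))
  segs <- segment_daily(tr, dw1(0, 240))
  fm <- segment_features(segs)
  sc <- normalize_features(fm)
  sds <- vapply(sc[feature_names()], sd, numeric(1))
  varying <- setdiff(feature_names(), attr(sc, "constant_features"))
  expect_true(all(abs(sds[varying] - 1) < 1e-12))
  # recomputation oracle: scaled column = raw column / its raw SD
  expect_equal(sc$MS, fm$MS / sd(fm$MS), tolerance = 1e-12)
  # constant column -> zeros plus a flag
  const <- data.frame(D = c(1, 3, 5), L = c(2, 2, 2))
  nc <- normalize_features(const)
  expect_equal(nc$L, c(0, 0, 0))
  expect_equal(attr(nc, "constant_features"), "L")
  expect_equal(sd(nc$D), 1, tolerance = 1e-12)
  expect_error(normalize_features(const[1, ]), "at least 2")
})

test_that("majority true modes are recovered for constructed segments", {
  dw <- data.frame(day = 1, sunrise_min = 360, sunset_min = 1080)
  rt <- data.frame(day = 1, t_min = 360:420, x = 0, y = 0)
  segs <- segment_daily(rt, dw)
  traj <- data.frame(t_min = 360:420,
                     mode = c(rep("scanning", 31), rep("dwelling", 30)))
  expect_equal(segment_true_modes(segs, traj, dw),
               c("scanning", "scanning", "dwelling"))
})

test_that("median speed separates the four simulated movement modes", {
  cfg <- sim_config(n_days = 6, seed = 11)
  tr <- simulate_trajectory(cfg)
  dw <- sim_day_windows(cfg)
  day <- tr$t_min %% 1440 >= 360 & tr$t_min %% 1440 < 1080
  rt <- data.frame(day = tr$t_min[day] %/% 1440 + 1,
                   t_min = tr$t_min[day], x = tr$x[day], y = tr$y[day])
  segs <- segment_daily(rt, dw)
  fm <- segment_features(segs)
  modes <- segment_true_modes(segs, tr, dw)
  ms <- tapply(fm$MS, modes, mean)
  expect_gt(ms[["fast_ranging"]], ms[["slow_ranging"]])
  expect_gt(ms[["slow_ranging"]], ms[["scanning"]])
  expect_gt(ms[["scanning"]], ms[["dwelling"]])
})
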