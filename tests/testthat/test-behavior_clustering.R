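# helpers ---------------------------------------------------------------

four_blobs <- function(n_per = 50, sd = 0.3, seed = 7) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  X <- do.call(rbind, lapply(1:4, function(i)
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))))
  list(X = X, blob = rep(1:4, each = n_per))
}

# a valid hclust object built by hand (8 leaves, known merge heights)
toy_tree <- function() {
  structure(list(
    merge = rbind(c(-1, -2), c(-3, -4), c(-5, -6), c(-7, -8),
                  c(1, 2), c(3, 4), c(5, 6)),
    height = c(1, 1, 1, 1, 2, 2, 10),
    order = 1:8, labels = NULL, method = "ward.D2"),
    class = "hclust")
}

mode_partition <- function(modes)
  structure(list(labels = as.integer(factor(
    modes, levels = c("dwelling", "scanning", "slow_ranging",
                      "fast_ranging"))),
    n_classes = 4L, threshold = 0.015, sensitivity = NULL, tree = NULL,
    class_names = NULL), class = "cluster_result")

sim_mode_features <- function() {
  cfg <- sim_config(n_days = 6, seed = 11)
  tr <- simulate_trajectory(cfg)
  dw <- sim_day_windows(cfg)
  day <- tr$t_min %% 1440 >= 360 & tr$t_min %% 1440 < 1080
  rt <- data.frame(day = tr$t_min[day] %/% 1440 + 1,
                   t_min = tr$t_min[day], x = tr$x[day], y = tr$y[day])
  segs <- segment_daily(rt, dw)
  list(fm = segment_features(segs), modes = segment_true_modes(segs, tr, dw),
       segs = segs)
}

# agglomeration ----------------------------------------------------------

test_that("the merge tree matches a naive Lance-Williams Ward oracle", {
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2)
  tree <- agglomerate(X)
  orc <- naive_ward_tree(X)
  expect_equal(tree$height, orc$height, tolerance = 1e-8)
  expect_equal(t(apply(tree$merge, 1, sort)), t(apply(orc$merge, 1, sort)))
})

test_that("trivial trees have hand-computable heights", {
  two <- agglomerate(rbind(c(0, 0), c(3, 4)))
  expect_equal(two$height, 5)
  dup <- agglomerate(rbind(c(1, 1), c(1, 1), c(5, 5)))
  expect_equal(dup$height[1], 0)
  expect_error(agglomerate(matrix(0, 1, 2)), "at least 2")
  expect_error(agglomerate(matrix(c(1, NA, 2, 3), 2, 2)), "non-finite")
})

# principal components ---------------------------------------------------

test_that("the PCA matches a covariance eigendecomposition oracle", {
  set.seed(33)
  X <- matrix(rnorm(600), 50, 12) %*% matrix(rnorm(144), 12, 12)
  p <- fit_pca(X, k = 4)
  orc <- eigen_pca(X)
  expect_equal(p$var_frac, orc$var_frac, tolerance = 1e-9)
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-12)
  # loadings agree once both are put in the same sign convention
  for (j in 1:4) {
    v <- orc$vectors[, j]
    v <- v * sign(v[which.max(abs(v))])
    expect_equal(unname(p$loadings[, j]), v, tolerance = 1e-9)
  }
  # scores reproduce the centered projection
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_equal(unname(p$scores), unname(Xc %*% p$loadings),
               tolerance = 1e-9)
})

test_that("data confined to a plane loads onto two components", {
  set.seed(8)
  B <- matrix(rnorm(26), 13, 2)
  X <- matrix(rnorm(400), 200, 2) %*% t(B)     # rank-2 13-column data
  p <- fit_pca(X, k = 4)
  expect_gt(sum(p$var_frac[1:2]), 0.99)
  expect_error(fit_pca(X, k = 14), "exceed")
  X[1, 1] <- NA
  expect_error(fit_pca(X), "non-finite")
})

# merger-score cut -------------------------------------------------------

test_that("four well-separated blobs yield four classes at any threshold", {
  b <- four_blobs()
  res <- cut_by_merger_score(agglomerate(b$X))
  expect_equal(res$n_classes, 4L)
  expect_true(all(res$sensitivity == 4L))
  expect_equal(names(res$sensitivity), c("1%", "1.5%", "2%", "3%"))
  # each blob maps to exactly one class and vice versa
  tab <- table(res$labels, b$blob)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(length(unique(res$labels)), 4L)
})

test_that("an unclustered Gaussian cloud is never split into many classes", {
  set.seed(1)
  X <- matrix(rnorm(4000), 2000, 2)
  res <- suppressWarnings(cut_by_merger_score(agglomerate(X)))
  expect_lte(res$n_classes, 3L)
  expect_true(all(res$sensitivity <= 3L))
})

test_that("a tree with no significant jump is one class, with a warning", {
  b <- four_blobs()
  tree <- agglomerate(b$X)
  expect_warning(res <- cut_by_merger_score(tree, threshold = 0.9),
                 "one class")
  expect_equal(res$n_classes, 1L)
  expect_true(all(res$labels == 1L))
})

test_that("the cut of a hand-built tree is computed by hand", {
  tree <- toy_tree()
  # heights 1,1,1,1,2,2,10: increments/sum(18) = 0,0,0,1/18,0,8/18
  # first score above 1.5% is the 4th -> cut before merge 4 of 7 -> 4 classes
  res <- cut_by_merger_score(tree, threshold = 0.015)
  expect_equal(res$n_classes, 4L)
  expect_equal(res$labels, rep(1:4, each = 2))
  # above 1/18 but below 8/18 only the last merge counts -> 2 classes
  res2 <- cut_by_merger_score(tree, threshold = 0.1)
  expect_equal(res2$n_classes, 2L)
  expect_equal(res2$labels, rep(1:2, each = 4))
})

# labeling and merging ---------------------------------------------------

test_that("auto-labels agree with the majority true mode of each class", {
  s <- sim_mode_features()
  res <- label_and_merge(mode_partition(s$modes), s$fm)
  # class i was built from true mode i; compare assigned names to truth
  truth <- c("dwelling", "scanning", "slow ranging", "fast ranging")
  expect_gte(sum(res$class_names == truth), 3)
  expect_equal(res$segment_class, res$class_names[res$labels])
})

test_that("merging two classes unions them and reduces the count by one", {
  s <- sim_mode_features()
  res0 <- mode_partition(s$modes)
  res <- label_and_merge(res0, s$fm, merge_pairs = list(c(2, 3)))
  expect_equal(res$n_classes, 3L)
  # the union is exactly the old pair; no other boundary moved
  expect_true(all(res$labels[res0$labels %in% c(2, 3)] ==
                    res$labels[which(res0$labels == 2)[1]]))
  same_old <- outer(res0$labels, res0$labels, `==`)
  same_new <- outer(res$labels, res$labels, `==`)
  expect_true(all(same_new[same_old]))     # merging never splits
  expect_error(label_and_merge(res0, s$fm, merge_pairs = list(c(1, 9))),
               "nonexistent")
})

test_that("class naming is invariant to permuting the class numbers", {
  s <- sim_mode_features()
  res1 <- label_and_merge(mode_partition(s$modes), s$fm)
  perm <- c(3L, 1L, 4L, 2L)
  res2p <- mode_partition(s$modes)
  res2p$labels <- perm[res2p$labels]
  res2 <- label_and_merge(res2p, s$fm)
  expect_equal(res2$segment_class, res1$segment_class)
})

# class occupancy --------------------------------------------------------

test_that("daily class fractions are conserved and hand-checkable", {
  dw <- data.frame(day = 1, sunrise_min = 0, sunset_min = 60)
  rt <- data.frame(day = 1, t_min = 0:60, x = 0, y = 0)
  segs <- segment_daily(rt, dw)          # starts 0, 15, 30
  occ <- class_occupancy(c("A", "B", "A"), segs)
  expect_equal(occ$daily$A + occ$daily$B, 1, tolerance = 1e-12)
  # hand weighting: minutes 0-14 A, 15-29 half A half B, 30-44 half B half
  # A, 45-59 A -> A = 45/60, B = 15/60
  expect_equal(occ$daily$A, 45 / 60, tolerance = 1e-12)
  expect_equal(occ$daily$B, 15 / 60, tolerance = 1e-12)
})

test_that("occupancy fractions sum to one on simulated segments", {
  s <- sim_mode_features()
  res <- label_and_merge(mode_partition(s$modes), s$fm)
  occ <- class_occupancy(res, s$segs)
  tot <- rowSums(occ$daily[occ$classes])
  expect_true(all(abs(tot - 1) < 1e-9))
})

test_that("stability standard errors match a direct computation", {
  mk_days <- function(classes) {
    dw <- data.frame(day = seq_along(classes), sunrise_min = 0,
                     sunset_min = 30)
    rt <- do.call(rbind, lapply(seq_along(classes), function(d)
      data.frame(day = d, t_min = 0:30, x = 0, y = 0)))
    segment_daily(rt, dw)                # one segment per day
  }
  # one class only: SE exactly zero
  occ1 <- class_occupancy(rep("A", 8), mk_days(rep("A", 8)), group_size = 4)
  expect_equal(unname(occ1$se), 0)
  expect_equal(occ1$n_groups, 2L)
  # days 1-4 all A, days 5-8 all B: group means for A are 1 and 0, so
  # SE = sd(c(1, 0)) / sqrt(2) = 0.5
  cls <- rep(c("A", "B"), each = 4)
  occ2 <- class_occupancy(cls, mk_days(cls), group_size = 4)
  expect_equal(unname(occ2$se), c(0.5, 0.5))
  # fewer than two groups: no stability estimate
  occ3 <- class_occupancy(rep("A", 3), mk_days(rep("A", 3)), group_size = 4)
  expect_equal(occ3$n_groups, 0L)
  expect_true(all(is.na(occ3$se)))
})

test_that("the clustering stage is deterministic given its inputs", {
  b <- four_blobs()
  r1 <- cut_by_merger_score(agglomerate(b$X))
  r2 <- cut_by_merger_score(agglomerate(b$X))
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$sensitivity, r2$sensitivity)
})
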