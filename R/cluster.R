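#' Principal-component analysis of the scaled feature matrix
#'
#' Column-centered PCA (eigendecomposition of the covariance of the scaled
#' features, via SVD). Since the features were already divided by their
#' standard deviations this is correlation-matrix PCA. The sign of each
#' component is fixed so the loading with the largest magnitude is positive,
#' making results reproducible across platforms.
#'
#' @param scaled a scaled `feature_matrix` from [normalize_features()], or a
#'   plain numeric matrix.
#' @param k number of components to retain (default 4).
#' @return An object of class `reef_pca`: `loadings` (13 x k), `var_frac`
#'   (all components' variance fractions), `k`, `scores` (n x k), `center`
#'   (column means removed).
#' @export
fit_pca <- function(scaled, k = 4) {
  X <- if (is.data.frame(scaled))
    as.matrix(scaled[, intersect(feature_names(), names(scaled))])
  else as.matrix(scaled)
  if (!all(is.finite(X))) stop("feature matrix contains non-finite values")
  if (k > ncol(X)) stop("k cannot exceed the number of features")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  rot <- sweep(p$rotation, 2, flip, `*`)
  sco <- sweep(p$x, 2, flip, `*`)
  vf <- p$sdev^2 / sum(p$sdev^2)
  structure(list(loadings = rot[, seq_len(k), drop = FALSE],
                 var_frac = vf, k = k,
                 scores = sco[, seq_len(k), drop = FALSE],
                 center = p$center),
            class = "reef_pca")
}

#' @export
print.reef_pca <- function(x, ...) {
  cat("PCA of", nrow(x$loadings), "features;", x$k, "components explain",
      sprintf("%.1f%%", 100 * sum(x$var_frac[seq_len(x$k)])),
      "of the variance\n")
  cat("  per-component:",
      paste(sprintf("%.1f%%", 100 * x$var_frac[seq_len(x$k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Agglomerative clustering of segment scores
#'
#' Hierarchical merge tree on Euclidean distances between the
#' principal-component scores.
#'
#' @param scores numeric matrix (rows = segments), e.g. `pca$scores`.
#' @param method linkage: `"ward"` (default, Ward's minimum-variance on
#'   Euclidean distances, i.e. `ward.D2`), `"single"`, `"average"` or
#'   `"complete"`.
#' @return An `hclust` tree.
#' @export
agglomerate <- function(scores, method = c("ward", "single", "average",
                                           "complete")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("scores contain non-finite values")
  if (nrow(scores) < 2) stop("need at least 2 segments")
  hm <- if (method == "ward") "ward.D2" else method
  stats::hclust(stats::dist(scores), method = hm)
}

merger_n_classes <- function(heights, threshold) {
  m <- length(heights)
  if (m < 2) return(1L)
  total <- sum(heights)
  if (total <= 0) return(1L)
  score <- diff(heights) / total
  i <- which(score > threshold)[1]
  if (is.na(i)) 1L else (m + 1L) - i
}

#' Cut an agglomerative tree by the merger score
#'
#' Converts the merge tree into flat classes. Following the merges in order,
#' each step's merger score is the jump in merge height from the previous
#' step, normalized by the summed height of all merges; the cut is placed at
#' the first step whose score exceeds the threshold, so every cluster still
#' separate at that point becomes a class. If no score exceeds the threshold
#' the tree is one class (with a warning). A sensitivity report over
#' thresholds 1, 1.5, 2 and 3 percent is always attached, since the class
#' count should not depend delicately on the threshold.
#'
#' @param tree an `hclust` tree.
#' @param threshold normalized merge-height increment threshold
#'   (default 0.015).
#' @param sensitivity thresholds for the sensitivity report.
#' @return An object of class `cluster_result`: `labels` (integer per
#'   segment), `n_classes`, `threshold`, `sensitivity` (named integer vector
#'   of class counts), and the `tree`.
#' @export
cut_by_merger_score <- function(tree, threshold = 0.015,
                                sensitivity = c(0.01, 0.015, 0.02, 0.03)) {
  stopifnot(inherits(tree, "hclust"))
  h <- tree$height
  n <- merger_n_classes(h, threshold)
  if (n == 1L)
    warning("no merge-height increment exceeds the threshold; one class")
  labels <- stats::cutree(tree, k = n)
  sens <- vapply(sensitivity, function(th) merger_n_classes(h, th), integer(1))
  names(sens) <- paste0(100 * sensitivity, "%")
  structure(list(labels = unname(labels), n_classes = n,
                 threshold = threshold, sensitivity = sens, tree = tree,
                 class_names = NULL),
            class = "cluster_result")
}

#' Name behavioral classes and apply manual merges
#'
#' Auto-names classes from their mean features: the class with the lowest
#' median speed is dwelling and the highest is fast ranging; among the rest,
#' the class with the largest mean net displacement is slow ranging and the
#' others are scanning. Optional user-reviewed merges (pairs of class names
#' or numbers) correct over-splitting; merging never changes the underlying
#' partition boundaries, only unions classes.
#'
#' @param result a `cluster_result`.
#' @param features the (unscaled) `feature_matrix` for the same segments.
#' @param merge_pairs optional list of length-2 vectors; each merges its
#'   second class into its first.
#' @return The updated `cluster_result` with `class_names` (one per class)
#'   and `segment_class` (name per segment).
#' @export
label_and_merge <- function(result, features, merge_pairs = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  labs <- result$labels
  if (!is.null(merge_pairs)) {
    for (pr in merge_pairs) {
      pr <- as.integer(pr)
      if (!all(pr %in% labs)) stop("merge of nonexistent class")
      labs[labs == pr[2]] <- pr[1]
    }
    labs <- match(labs, sort(unique(labs)))   # compact labels
  }
  k <- length(unique(labs))
  ms <- vapply(seq_len(k), function(cl) mean(features$MS[labs == cl]),
               numeric(1))
  dd <- vapply(seq_len(k), function(cl) mean(features$D[labs == cl]),
               numeric(1))
  nm <- rep("scanning", k)
  ord <- order(ms)
  nm[ord[1]] <- "dwelling"
  if (k >= 2) nm[ord[k]] <- "fast ranging"
  mid <- setdiff(seq_len(k), c(ord[1], ord[k]))
  if (length(mid) >= 1) {
    slow <- mid[which.max(dd[mid])]
    nm[mid] <- "scanning"
    nm[slow] <- "slow ranging"
  }
  result$labels <- labs
  result$n_classes <- k
  result$class_names <- nm
  result$segment_class <- nm[labs]
  result
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Agglomerative clustering:", x$n_classes, "classes at",
      sprintf("%.1f%%", 100 * x$threshold), "merger-score cut\n")
  cat("  sensitivity:",
      paste(names(x$sensitivity), "->", x$sensitivity, collapse = ", "), "\n")
  if (!is.null(x$class_names)) {
    cat("  classes:\n")
    print(table(x$segment_class))
  }
  invisible(x)
}

#' Per-day class occupancy and its stability
#'
#' Time-division of each day between behavioral classes. Because neighbouring
#' segments overlap 50 percent, each minute is weighted by the set of
#' segments covering it (a minute covered by two segments of different
#' classes contributes half to each), so per-day fractions sum to exactly 1.
#' Stability is the per-class standard error of the fractions across
#' consecutive-day groups.
#'
#' @param result a labeled `cluster_result` (after [label_and_merge()]), or
#'   any vector of class names per segment.
#' @param segments the `trajectory_segments` the labels refer to.
#' @param group_size days per consecutive-day group for the stability
#'   standard errors.
#' @return An object of class `class_occupancy`: `daily` (data.frame of
#'   per-day fractions per class), `se` and `se_pct` (per-class standard
#'   error across day groups, absolute and percent of the mean), and
#'   `n_groups`.
#' @export
class_occupancy <- function(result, segments, group_size = 4) {
  cls <- if (inherits(result, "cluster_result")) {
    if (is.null(result$segment_class))
      as.character(result$labels)
    else result$segment_class
  } else as.character(result)
  stopifnot(length(cls) == length(segments))
  len <- attr(segments, "length_min") %||% 30
  days <- vapply(segments, `[[`, numeric(1), "day")
  starts <- vapply(segments, `[[`, numeric(1), "start_min")
  classes <- sort(unique(cls))

  daily <- lapply(sort(unique(days)), function(d) {
    di <- which(days == d)
    dl <- max(starts[di]) + len
    mins <- 0:(dl - 1)
    w <- matrix(0, length(mins), length(classes),
                dimnames = list(NULL, classes))
    cover <- matrix(FALSE, length(mins), length(di))
    for (j in seq_along(di)) {
      s <- starts[di[j]]
      cover[mins >= s & mins < s + len, j] <- TRUE
    }
    ncov <- rowSums(cover)
    for (j in seq_along(di)) {
      cl <- cls[di[j]]
      sel <- cover[, j]
      w[sel, cl] <- w[sel, cl] + 1 / ncov[sel]
    }
    frac <- colSums(w) / length(mins)
    data.frame(day = d, t(frac), check.names = FALSE)
  })
  daily <- do.call(rbind, daily)

  ndays <- nrow(daily)
  ng <- ndays %/% group_size
  if (ng >= 2) {
    gi <- rep(seq_len(ng), each = group_size)
    gmeans <- vapply(classes, function(cl)
      tapply(daily[[cl]][seq_len(ng * group_size)], gi, mean), numeric(ng))
    se <- apply(gmeans, 2, stats::sd) / sqrt(ng)
    mu <- colMeans(gmeans)
    se_pct <- ifelse(mu > 0, 100 * se / mu, NA_real_)
  } else {
    se <- stats::setNames(rep(NA_real_, length(classes)), classes)
    se_pct <- se
    ng <- 0L
  }
  structure(list(daily = daily, se = se, se_pct = se_pct,
                 n_groups = ng, group_size = group_size,
                 classes = classes),
            class = "class_occupancy")
}

#' @export
print.class_occupancy <- function(x, ...) {
  cat("Class occupancy over", nrow(x$daily), "days\n")
  cat("  mean daily fractions:\n")
  mu <- colMeans(x$daily[x$classes])
  print(round(mu, 3))
  if (x$n_groups >= 2) {
    cat("  stability SE (% of mean) across", x$n_groups, "groups of",
        x$group_size, "days:\n")
    print(round(x$se_pct, 1))
  }
  invisible(x)
}
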