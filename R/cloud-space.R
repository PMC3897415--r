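# Within/between treecloud distance estimation, all-pairs matrices and
# non-metric multidimensional scaling of treecloud space.

#' Mean distance between (or within) treeclouds
#'
#' Estimates the mean and SD of the tree-to-tree distance between two
#' treeclouds by subsampling tree pairs. With `mode = "all_cross_pairs"`,
#' `n_trees` trees are drawn from each cloud without replacement and all
#' cross pairs are evaluated (the protocol used when building all-pairs
#' matrices); with `mode = "random_pairs"`, `n_pairs` tree pairs are drawn
#' with replacement (the protocol used for the statistical tests). The
#' within-cloud case (`b` missing or identical to `a`) excludes self-pairs.
#'
#' @param a,b `tree_cloud` objects on the same leaf set; omit `b` for the
#'   within-cloud spread.
#' @param metric one of [treecloud_metrics()].
#' @param n_trees trees subsampled per cloud in `all_cross_pairs` mode.
#' @param mode `"all_cross_pairs"` or `"random_pairs"`.
#' @param n_pairs number of pairs in `random_pairs` mode.
#' @param seed integer seed making the subsample reproducible.
#' @return object of class `cloud_dist_estimate`: list with `cloud_a`,
#'   `cloud_b`, `metric`, `mean`, `sd`, `n_pairs`, `seed`, and the raw
#'   `distances`.
#' @export
cloud_distance <- function(a, b = a, metric = "symmetric", n_trees = 100,
                           mode = c("all_cross_pairs", "random_pairs"),
                           n_pairs = 1000, seed = 1) {
  mode <- match.arg(mode)
  metric <- match.arg(metric, treecloud_metrics())
  within <- identical(a, b)
  na <- n_trees(a); nb <- n_trees(b)
  if (mode == "all_cross_pairs") {
    if (n_trees > na || n_trees > nb)
      stopf("n_trees (%d) exceeds cloud size (%d, %d)", n_trees, na, nb)
    idx <- withr::with_seed(as.integer(seed), list(
      ia = sample.int(na, n_trees), ib = sample.int(nb, n_trees)))
    if (within) {
      pairs <- which(upper.tri(matrix(0, n_trees, n_trees)), arr.ind = TRUE)
      ia <- idx$ia[pairs[, 1]]; ib <- idx$ia[pairs[, 2]]
    } else {
      grid <- expand.grid(i = seq_len(n_trees), j = seq_len(n_trees))
      ia <- idx$ia[grid$i]; ib <- idx$ib[grid$j]
    }
  } else {
    if (n_pairs < 2) stopf("n_pairs must be >= 2")
    idx <- withr::with_seed(as.integer(seed), {
      ia <- sample.int(na, n_pairs, replace = TRUE)
      ib <- sample.int(nb, n_pairs, replace = TRUE)
      if (within && na > 1L) {
        while (any(same <- ia == ib))
          ib[same] <- sample.int(nb, sum(same), replace = TRUE)
      }
      list(ia = ia, ib = ib)
    })
    ia <- idx$ia; ib <- idx$ib
  }
  if (length(ia) < 1L) stopf("no pairs to evaluate")
  d <- cloud_pair_distances(a, b, ia, ib, metric)
  structure(list(cloud_a = a$cloud_id, cloud_b = b$cloud_id, metric = metric,
                 mean = mean(d), sd = if (length(d) > 1L) sd(d) else NA_real_,
                 n_pairs = length(d),
                 seed = as.integer(seed), distances = d),
            class = "cloud_dist_estimate")
}

#' @export
print.cloud_dist_estimate <- function(x, ...) {
  cat(sprintf("%s distance %s ~ %s: mean %.4g, sd %.4g (%d pairs)\n",
              x$metric, x$cloud_a, x$cloud_b, x$mean, x$sd, x$n_pairs))
  invisible(x)
}

#' All-pairs treecloud distance matrix
#'
#' Mean subsampled distances between every pair of treeclouds under one
#' metric, with per-cloud within-cloud means on the diagonal.
#'
#' @param clouds list of `tree_cloud` objects on a common leaf set.
#' @inheritParams cloud_distance
#' @return object of class `cloud_dist_matrix`: list with `cloud_ids`,
#'   `source_kinds`, `metric`, `means` (symmetric matrix, diagonal =
#'   within-cloud means), `sds`, and `provenance`.
#' @export
all_pairs_matrix <- function(clouds, metric = "symmetric", n_trees = 100,
                             mode = "all_cross_pairs", n_pairs = 1000,
                             seed = 1) {
  if (length(clouds) < 2L) stopf("need at least 2 clouds")
  ids <- vapply(clouds, function(cl) cl$cloud_id, "")
  if (anyDuplicated(ids)) stopf("duplicate cloud ids")
  n <- length(clouds)
  n_trees <- min(n_trees, min(vapply(clouds, n_trees_of, 0L)))
  seeds <- matrix(derive_seeds(seed, n * n), n, n)
  means <- sds <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      est <- cloud_distance(clouds[[i]], clouds[[j]], metric = metric,
                            n_trees = n_trees, mode = mode,
                            n_pairs = n_pairs, seed = seeds[i, j])
      means[i, j] <- means[j, i] <- est$mean
      sds[i, j] <- sds[j, i] <- est$sd
    }
  }
  structure(list(cloud_ids = ids,
                 source_kinds = vapply(clouds, function(cl) cl$source_kind, ""),
                 metric = metric, means = means, sds = sds,
                 provenance = list(n_trees_subsampled = n_trees, mode = mode,
                                   n_pairs = n_pairs, seed = as.integer(seed))),
            class = "cloud_dist_matrix")
}

n_trees_of <- function(cl) n_trees(cl)

#' @export
print.cloud_dist_matrix <- function(x, ...) {
  cat(sprintf("%d x %d treecloud distance matrix (%s metric)\n",
              nrow(x$means), ncol(x$means), x$metric))
  invisible(x)
}

#' Write a treecloud distance matrix as CSV
#' @param x a `cloud_dist_matrix`.
#' @param path output CSV path (cloud ids as header and first column).
#' @return `path`, invisibly.
#' @export
write_dist_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x$means), path, row.names = TRUE)
  invisible(path)
}

#' Embed a treecloud distance matrix in 2-D by NMMDS
#'
#' Non-metric multidimensional scaling (Kruskal stress-1 with isotonic
#' regression of embedded against observed distances, ties unconstrained)
#' of the between-cloud mean distances, via [vegan::monoMDS()]. Within-cloud
#' means on the diagonal are excluded from the ordination. Each restart
#' starts from an independent random configuration; the solution with the
#' lowest stress is returned.
#'
#' @param x a `cloud_dist_matrix`.
#' @param dims embedding dimension (2 for display).
#' @param n_restarts number of random restarts.
#' @param seed integer seed.
#' @return object of class `treecloud_nmds`: `points` (clouds x dims, row
#'   names = cloud ids), `stress` (fraction in `[0, 1]`), `r_squared`
#'   (squared Pearson correlation of observed vs embedded distances),
#'   `seed`, `n_restarts`, `source_kinds`.
#' @export
nmds_embed <- function(x, dims = 2, n_restarts = 20, seed = 1) {
  if (!all(is.finite(x$means))) stopf("non-finite distance matrix entries")
  d <- stats::as.dist(x$means)
  n <- nrow(x$means)
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- withr::with_seed(seeds[r], {
      init <- matrix(stats::rnorm(n * dims), n, dims)
      vegan::monoMDS(d, y = init, k = dims, model = "global")
    })
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  pts <- best$points
  rownames(pts) <- x$cloud_ids
  emb <- as.vector(stats::dist(pts))
  obs <- as.vector(d)
  structure(list(points = pts, stress = best$stress,
                 r_squared = stats::cor(obs, emb)^2,
                 seed = as.integer(seed), n_restarts = n_restarts,
                 metric = x$metric, source_kinds = x$source_kinds),
            class = "treecloud_nmds")
}

#' @export
print.treecloud_nmds <- function(x, ...) {
  cat(sprintf("NMMDS of %d treeclouds (%s): stress %.3f, r^2 %.3f\n",
              nrow(x$points), x$metric, x$stress, x$r_squared))
  invisible(x)
}

#' Plot an NMMDS embedding of treecloud space
#'
#' Gene clouds as filled points, randomized clouds in grey, the reference
#' cloud as a star.
#'
#' @param x a `treecloud_nmds`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.treecloud_nmds <- function(x, ...) {
  kind <- x$source_kinds
  col <- ifelse(kind == "randomized", "grey60", "black")
  pch <- ifelse(kind == "reference", 8L, 16L)
  graphics::plot(x$points[, 1], x$points[, 2], col = col, pch = pch,
                 xlab = "NMMDS 1", ylab = "NMMDS 2",
                 main = sprintf("%s (stress %.2f)", x$metric, x$stress), ...)
  invisible(x)
}
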