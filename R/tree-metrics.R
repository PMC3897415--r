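# Pairwise tree distances: symmetric (RF topology), branch-length RF,
# exact MAST / SPR surrogate, and Ge's gamma.

# cpp argument marshalling -----------------------------------------------

# Align the two trees on a common canonical label order and return the
# pieces the C++ layer needs.
pair_args <- function(t1, t2) {
  t1 <- as_unrooted(t1); t2 <- as_unrooted(t2)
  check_leaf_sets(t1, t2)
  labs <- ref_labels(t1)
  list(t1 = t1, t2 = t2, labs = labs,
       e1 = t1$edge, e2 = t2$edge,
       m1 = match(t1$tip.label, labs), m2 = match(t2$tip.label, labs),
       l1 = as.numeric(t1$edge.length %||% rep(0, nrow(t1$edge))),
       l2 = as.numeric(t2$edge.length %||% rep(0, nrow(t2$edge))))
}

# per-cloud argument lists for batch calls
cloud_args <- function(cloud, labs) {
  list(edges = lapply(cloud$trees, `[[`, "edge"),
       lens = lapply(cloud$trees, function(t)
         as.numeric(t$edge.length %||% rep(0, nrow(t$edge)))),
       maps = lapply(cloud$trees, function(t) match(t$tip.label, labs)))
}

metric_code <- function(metric) {
  switch(metric,
         symmetric = list(code = 0L, rescale = FALSE),
         rf_absolute = list(code = 1L, rescale = FALSE),
         rf_squared = list(code = 2L, rescale = FALSE),
         rf_rescaled = list(code = 1L, rescale = TRUE),
         stopf("unknown metric '%s'", metric))
}

#' Supported tree-to-tree distance metrics
#'
#' `"symmetric"`: Robinson-Foulds topology distance, the number of
#' non-trivial bipartitions present in exactly one of the two trees.
#' `"rf_absolute"` / `"rf_squared"`: branch-length Robinson-Foulds distance
#' accumulated over the union of splits of both trees (trivial splits
#' included), a split absent from one tree contributing its full length;
#' either absolute differences or squared differences. `"rf_rescaled"`:
#' `rf_absolute` after rescaling every tree to total treelength 1.
#' @return character vector of metric names.
#' @export
treecloud_metrics <- function() {
  c("symmetric", "rf_absolute", "rf_squared", "rf_rescaled")
}

# distances ---------------------------------------------------------------

#' Symmetric (Robinson-Foulds topology) distance
#'
#' Number of non-trivial splits present in exactly one of the two trees.
#' Zero iff the unrooted topologies are identical; at most `2(n - 3)` for
#' binary trees.
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return non-negative integer.
#' @export
symmetric_distance <- function(t1, t2) {
  a <- pair_args(t1, t2)
  as.integer(.cloud_pair_distances_cpp(
    list(a$e1), list(a$l1), list(a$m1), list(a$e2), list(a$l2), list(a$m2),
    1L, 1L, length(a$labs), 0L, FALSE, FALSE))
}

#' Branch-length Robinson-Foulds distance
#'
#' Accumulates branch-length differences over the union of splits of the
#' two trees (trivial splits matched by leaf); a split absent from one tree
#' contributes its full length. The default convention sums absolute
#' differences; `"squared"` sums squared differences.
#'
#' @param t1,t2 `phylo` objects on the same leaf set, with branch lengths.
#' @param convention `"absolute"` (default) or `"squared"`.
#' @param rescale if `TRUE`, rescale each tree to unit total treelength
#'   first.
#' @return non-negative real.
#' @export
branch_length_distance <- function(t1, t2,
                                   convention = c("absolute", "squared"),
                                   rescale = FALSE) {
  convention <- match.arg(convention)
  if (is.null(t1$edge.length) || is.null(t2$edge.length))
    stopf("both trees need branch lengths")
  a <- pair_args(t1, t2)
  .cloud_pair_distances_cpp(
    list(a$e1), list(a$l1), list(a$m1), list(a$e2), list(a$l2), list(a$m2),
    1L, 1L, length(a$labs), if (convention == "absolute") 1L else 2L,
    rescale, FALSE)
}

#' Maximum agreement subtree size
#'
#' Size of the largest leaf subset on which the two (unrooted) trees induce
#' identical topologies, computed exactly by dynamic programming over
#' rooted subtree pairs across all leaf rootings. Polytomies are handled
#' via maximum-weight matching of child subtrees (agreement is strict
#' isomorphism of the restricted trees).
#'
#' @param t1,t2 `phylo` objects on the same leaf set.
#' @return integer in `[3, n_leaves]`; equals `n_leaves` iff the
#'   topologies are identical.
#' @export
mast_size <- function(t1, t2) {
  a <- pair_args(t1, t2)
  .mast_pair_cpp(a$e1, a$m1, a$e2, a$m2, length(a$labs))
}

#' SPR-surrogate (MAST) distance
#'
#' `n_leaves - mast_size(t1, t2)`: the number of leaves that must be removed
#' to bring the two topologies into agreement. Used as a computable
#' surrogate for the (NP-hard) SPR distance when screening for horizontal
#' transfer; zero iff identical topologies.
#'
#' @inheritParams mast_size
#' @return non-negative integer, at most `n_leaves - 3`.
#' @export
spr_surrogate_distance <- function(t1, t2) {
  length(t1$tip.label) - mast_size(t1, t2)
}

#' Ge's gamma statistic for a pair of trees
#'
#' The normalized symmetric distance minus the normalized SPR-surrogate
#' distance: `gamma = d_S / (m + n) - d_M / (x - 3)`, where `d_S` is the
#' symmetric distance, `d_M = x - mast_size` the SPR surrogate, `m` and `n`
#' the internal-branch counts of the two trees and `x` the number of taxa.
#' High gamma (large overall incongruence removable by few
#' prune-and-regraft events) is the signature of horizontal transfer.
#'
#' @param t1,t2 `phylo` objects on the same leaf set of at least 4 taxa.
#' @return object of class `ge_gamma`: list with `d_s`, `d_m`, `m`, `n`,
#'   `x`, `gamma`.
#' @export
ge_gamma <- function(t1, t2) {
  x <- length(t1$tip.label)
  if (x < 4L) stopf("gamma needs at least 4 taxa")
  a <- pair_args(t1, t2)
  g <- .gamma_pairs_cpp(list(a$e1), list(a$m1), list(a$e2), list(a$m2),
                        1L, 1L, x, FALSE)
  d_s <- g[1, 1]; mast <- g[1, 2]; m <- g[1, 3]; n <- g[1, 4]
  d_m <- x - mast
  structure(list(d_s = d_s, d_m = d_m, m = m, n = n, x = x,
                 gamma = d_s / (m + n) - d_m / (x - 3)),
            class = "ge_gamma")
}

#' @export
print.ge_gamma <- function(x, ...) {
  cat(sprintf(
    "Ge's gamma: %.4f  (d_S = %d, d_M = %d, m = %d, n = %d, x = %d)\n",
    x$gamma, x$d_s, x$d_m, x$m, x$n, x$x))
  invisible(x)
}

# batch gamma over sampled pairs of two clouds; returns a data.frame
gamma_pairs <- function(cloud_a, cloud_b, ia, ib) {
  labs <- ref_labels(cloud_a$trees[[1]])
  if (!setequal(labs, cloud_b$trees[[1]]$tip.label))
    stopf("clouds '%s' and '%s' have different leaf sets",
          cloud_a$cloud_id, cloud_b$cloud_id)
  x <- length(labs)
  same <- identical(cloud_a, cloud_b)
  ca <- cloud_args(cloud_a, labs)
  cb <- if (same) ca else cloud_args(cloud_b, labs)
  g <- .gamma_pairs_cpp(ca$edges, ca$maps, cb$edges, cb$maps,
                        as.integer(ia), as.integer(ib), x, same)
  d_m <- x - g[, 2]
  data.frame(d_s = g[, 1], d_m = d_m, m = g[, 3], n = g[, 4], x = x,
             gamma = g[, 1] / (g[, 3] + g[, 4]) - d_m / (x - 3))
}

# batch distances over sampled pairs of two clouds
cloud_pair_distances <- function(cloud_a, cloud_b, ia, ib, metric) {
  labs <- ref_labels(cloud_a$trees[[1]])
  if (!setequal(labs, cloud_b$trees[[1]]$tip.label))
    stopf("clouds '%s' and '%s' have different leaf sets",
          cloud_a$cloud_id, cloud_b$cloud_id)
  mc <- metric_code(metric)
  same <- identical(cloud_a, cloud_b)
  ca <- cloud_args(cloud_a, labs)
  cb <- if (same) ca else cloud_args(cloud_b, labs)
  .cloud_pair_distances_cpp(ca$edges, ca$lens, ca$maps,
                            cb$edges, cb$lens, cb$maps,
                            as.integer(ia), as.integer(ib),
                            length(labs), mc$code, mc$rescale, same)
}
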