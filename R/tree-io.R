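# Treecloud construction, file I/O, rescaling and tip randomization.

#' Construct a treecloud
#'
#' A treecloud is an ordered collection of trees sampled from one Bayesian
#' posterior (one gene family, a concatenated reference alignment, or a
#' randomized null), all sharing the same leaf set.
#'
#' @param trees a `multiPhylo` object (or list of `phylo`); trees are stored
#'   unrooted since all distances used here are unrooted.
#' @param cloud_id character identifier for the cloud.
#' @param source_kind one of `"gene"`, `"reference"`, `"randomized"`,
#'   `"synthetic"`.
#' @param metadata optional named list (e.g. `alignment_length`).
#' @return an object of class `tree_cloud`.
#' @export
tree_cloud <- function(trees, cloud_id,
                       source_kind = c("gene", "reference", "randomized",
                                       "synthetic"),
                       metadata = list()) {
  source_kind <- match.arg(source_kind)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (!inherits(trees, "multiPhylo")) {
    if (!is.list(trees) || !all(vapply(trees, inherits, TRUE, "phylo")))
      stopf("'trees' must be a multiPhylo or a list of phylo objects")
    class(trees) <- "multiPhylo"
  }
  if (length(trees) == 0L) stopf("cloud '%s' is empty", cloud_id)
  trees <- structure(lapply(trees, as_unrooted), class = "multiPhylo")
  labs <- sort(trees[[1]]$tip.label)
  if (length(labs) > .MAX_TAXA) stopf("at most %d taxa supported", .MAX_TAXA)
  for (i in seq_along(trees)) {
    li <- sort(trees[[i]]$tip.label)
    if (length(li) != length(labs) || any(li != labs))
      stopf("tree %d of cloud '%s' has a different leaf set", i, cloud_id)
  }
  structure(list(trees = trees, cloud_id = as.character(cloud_id),
                 source_kind = source_kind, metadata = metadata),
            class = "tree_cloud")
}

#' @export
print.tree_cloud <- function(x, ...) {
  cat(sprintf("treecloud '%s' (%s): %d trees, %d taxa, mean treelength %.4g\n",
              x$cloud_id, x$source_kind, n_trees(x),
              length(x$trees[[1]]$tip.label), mean(tree_lengths(x))))
  invisible(x)
}

#' Number of trees in a cloud
#' @param cloud a `tree_cloud`.
#' @return integer count.
#' @export
n_trees <- function(cloud) length(cloud$trees)

#' Total treelength of every tree in a cloud
#' @param cloud a `tree_cloud`.
#' @return numeric vector of per-tree total branch lengths.
#' @export
tree_lengths <- function(cloud) {
  .tree_total_lengths_cpp(lapply(cloud$trees, function(t)
    as.numeric(t$edge.length %||% 0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a posterior tree sample from file
#'
#' Reads a NEXUS tree file (MrBayes `.t` conventions: translate block,
#' `tree gen.N = [&U] ...`) or a plain multi-Newick file (one tree per
#' line), removes a leading burn-in fraction in file order, and returns a
#' treecloud. Rooted/unrooted annotations are ignored: all trees are
#' treated as unrooted.
#'
#' @param path file path.
#' @param format `"auto"` (sniff `#NEXUS` header), `"nexus"` or `"newick"`.
#' @param burnin_fraction fraction in `[0, 1)` of initial samples to drop;
#'   the cloud keeps the last `ceiling((1 - burnin_fraction) * n)` trees.
#' @param cloud_id identifier; defaults to the file base name.
#' @param source_kind passed to [tree_cloud()].
#' @return a `tree_cloud`.
#' @export
read_tree_samples <- function(path, format = c("auto", "nexus", "newick"),
                              burnin_fraction = 0, cloud_id = NULL,
                              source_kind = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (!is.numeric(burnin_fraction) || burnin_fraction < 0 ||
      burnin_fraction >= 1)
    stopf("burnin_fraction must be in [0, 1)")
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- if (format == "nexus") {
    tr <- ape::read.nexus(path)
    if (inherits(tr, "phylo")) c(tr) else tr
  } else {
    read_multi_newick(path)
  }
  n <- length(trees)
  drop <- floor(burnin_fraction * n)
  if (drop >= n) stopf("no trees left after burn-in (%d of %d dropped)", drop, n)
  trees <- trees[(drop + 1L):n]
  class(trees) <- "multiPhylo"
  tree_cloud(trees, cloud_id %||% sub("\\.[^.]*$", "", basename(path)),
             source_kind = source_kind)
}

# one tree per line; report the offending line on parse failure
read_multi_newick <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) stopf("no trees in %s", path)
  trees <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    tr <- tryCatch(suppressWarnings(ape::read.tree(text = lines[keep[k]])),
                   error = function(e) NULL)
    if (is.null(tr) || !inherits(tr, "phylo"))
      stopf("unparseable Newick at line %d of %s", keep[k], path)
    trees[[k]] <- tr
  }
  structure(trees, class = "multiPhylo")
}

#' Write a treecloud as multi-Newick
#'
#' @param cloud a `tree_cloud`.
#' @param path output file; one Newick string per line.
#' @return `path`, invisibly.
#' @export
write_tree_samples <- function(cloud, path) {
  ape::write.tree(cloud$trees, file = path)
  invisible(path)
}

#' Manifest of a collection of treeclouds
#'
#' @param clouds list of `tree_cloud` objects.
#' @return data frame with `cloud_id`, `source_kind`, `n_trees`, `n_taxa`,
#'   `mean_treelength`.
#' @export
cloud_manifest <- function(clouds) {
  data.frame(
    cloud_id = vapply(clouds, function(cl) cl$cloud_id, ""),
    source_kind = vapply(clouds, function(cl) cl$source_kind, ""),
    n_trees = vapply(clouds, n_trees, 0L),
    n_taxa = vapply(clouds, function(cl) length(cl$trees[[1]]$tip.label), 0L),
    mean_treelength = vapply(clouds, function(cl) mean(tree_lengths(cl)), 0),
    stringsAsFactors = FALSE)
}

#' Rescale a tree to unit total treelength
#'
#' Divides every branch length by the total treelength so that the rescaled
#' total is 1. Used before branch-length distance comparisons so that
#' between-tree distances are not dominated by overall substitution rate.
#'
#' @param tree a `phylo` with branch lengths.
#' @return the rescaled `phylo`.
#' @export
rescale_to_unit_length <- function(tree) {
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  tot <- sum(tree$edge.length)
  if (!is.finite(tot) || tot <= 0) stopf("total treelength must be > 0")
  tree$edge.length <- tree$edge.length / tot
  tree
}

#' Randomly permute all tip labels of a tree
#'
#' Destroys phylogenetic signal while preserving the unlabeled topology and
#' the multiset of branch lengths; used to build "no phylogenetic signal"
#' null treeclouds.
#'
#' @param tree a `phylo` with at least 4 leaves.
#' @param seed integer seed; the permutation is deterministic given the seed.
#' @return the relabeled `phylo`.
#' @export
shuffle_tip_labels <- function(tree, seed) {
  n <- length(tree$tip.label)
  if (n < 4L) stopf("need at least 4 leaves")
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  tree$tip.label <- tree$tip.label[perm]
  tree
}

#' Exchange the labels of random leaf pairs
#'
#' Applies `n_switches` successive exchanges of the labels of two uniformly
#' chosen distinct leaves, giving partial randomization of phylogenetic
#' signal; `n_switches = 0` returns the tree unchanged, and `n_switches`
#' on the order of the taxon count approaches complete randomization.
#'
#' @param tree a `phylo`.
#' @param n_switches non-negative integer number of pairwise label exchanges.
#' @param seed integer seed.
#' @return the relabeled `phylo`.
#' @export
partial_shuffle <- function(tree, n_switches, seed) {
  if (n_switches < 0) stopf("n_switches must be >= 0")
  if (n_switches == 0) return(tree)
  n <- length(tree$tip.label)
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n_switches)) {
      ij <- sample.int(n, 2L)
      tree$tip.label[ij] <- tree$tip.label[rev(ij)]
    }
  })
  tree
}

#' Tip-randomize every tree of a cloud
#'
#' Applies an independent full tip-label permutation to each tree, producing
#' the randomized null cloud used by the centrality and treeishness
#' analyses.
#'
#' @param cloud a `tree_cloud`.
#' @param seed integer seed.
#' @param cloud_id identifier for the randomized cloud; default appends
#'   `"_rand"`.
#' @return a `tree_cloud` with `source_kind = "randomized"`.
#' @export
shuffle_cloud <- function(cloud, seed, cloud_id = NULL) {
  seeds <- derive_seeds(seed, n_trees(cloud))
  trees <- lapply(seq_along(cloud$trees), function(i)
    shuffle_tip_labels(cloud$trees[[i]], seeds[i]))
  tree_cloud(trees, cloud_id %||% paste0(cloud$cloud_id, "_rand"),
             source_kind = "randomized", metadata = cloud$metadata)
}
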