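# Shared fixtures and independent oracles. The oracles below are written
# against the split-set definition of tree distances and the subset
# definition of agreement subtrees, deliberately sharing no code with the
# package's C++ implementations.

nwk <- function(text) ape::read.tree(text = text)

random_binary <- function(n, seed, lengths = TRUE) {
  withr::with_seed(seed, {
    tr <- ape::unroot(ape::rtree(n, br = if (lengths) stats::runif else NULL))
    tr
  })
}

# --- split oracle (label-set based, pure R) ------------------------------

# descendant tip labels below each edge, by recursive traversal
edge_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], below), use.names = FALSE)
  }
  lapply(tree$edge[, 2], below)
}

# canonical signature of a split: the side not containing the
# alphabetically first label, sorted and collapsed
split_sig <- function(tips, all_labels) {
  anchor <- min(all_labels)
  side <- if (anchor %in% tips) setdiff(all_labels, tips) else tips
  paste(sort(side), collapse = "|")
}

oracle_splits <- function(tree) {
  labs <- sort(tree$tip.label)
  sets <- edge_tip_sets(tree)
  sig <- vapply(sets, split_sig, "", all_labels = labs)
  len <- tree$edge.length
  if (is.null(len)) len <- rep(0, length(sig))
  # merge duplicate signatures (rooted representations)
  agg <- tapply(len, sig, sum)
  size <- vapply(strsplit(names(agg), "|", fixed = TRUE), length, 0L)
  data.frame(sig = names(agg), len = as.numeric(agg),
             nontrivial = pmin(size, length(labs) - size) >= 2,
             stringsAsFactors = FALSE)
}

oracle_symmetric <- function(t1, t2) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  a <- s1$sig[s1$nontrivial]; b <- s2$sig[s2$nontrivial]
  length(setdiff(a, b)) + length(setdiff(b, a))
}

oracle_branch_length <- function(t1, t2, squared = FALSE) {
  s1 <- oracle_splits(t1); s2 <- oracle_splits(t2)
  all_sig <- union(s1$sig, s2$sig)
  l1 <- s1$len[match(all_sig, s1$sig)]; l1[is.na(l1)] <- 0
  l2 <- s2$len[match(all_sig, s2$sig)]; l2[is.na(l2)] <- 0
  if (squared) sum((l1 - l2)^2) else sum(abs(l1 - l2))
}

# --- MAST oracle: exhaustive subset enumeration (n <= 8) -----------------

# splits as bitmasks over the canonical (sorted) label order
mask_splits <- function(tree, labs) {
  sets <- edge_tip_sets(tree)
  n <- length(labs)
  masks <- vapply(sets, function(s)
    sum(2^(match(s, labs) - 1)), 0)
  unique(masks)
}

# do the two trees agree when restricted to the leaf subset `sub` (mask)?
agree_on_subset <- function(m1, m2, sub, n) {
  size <- function(m) sum(bitwAnd(rep(1, n), floor(m / 2^(0:(n - 1)))))
  k <- size(sub)
  restrict <- function(masks) {
    r <- vapply(masks, function(m) bitwAnd(m, sub), 0)
    sz <- vapply(r, size, 0)
    keep <- pmin(sz, k - sz) >= 2
    r <- r[keep]
    # normalize to the side without the lowest set bit of sub
    low <- 2^(which(floor(sub / 2^(0:(n - 1))) %% 2 == 1)[1] - 1)
    r <- vapply(r, function(m) if (bitwAnd(m, low) > 0)
      bitwAnd(sub, bitwXor(sub, m)) else m, 0)
    sort(unique(r))
  }
  identical(restrict(m1), restrict(m2))
}

oracle_mast <- function(t1, t2) {
  labs <- sort(t1$tip.label)
  n <- length(labs)
  stopifnot(n <= 8, setequal(labs, t2$tip.label))
  m1 <- mask_splits(t1, labs)
  m2 <- mask_splits(t2, labs)
  subsets <- 0:(2^n - 1)
  sizes <- vapply(subsets, function(s)
    sum(floor(s / 2^(0:(n - 1))) %% 2), 0)
  for (k in sort(unique(sizes), decreasing = TRUE)) {
    for (s in subsets[sizes == k]) {
      if (agree_on_subset(m1, m2, s, n)) return(k)
    }
  }
  0L
}

# --- misc ----------------------------------------------------------------

identical_cloud <- function(tree, n, id = "c", kind = "gene") {
  tree_cloud(rep(c(tree), n), cloud_id = id, source_kind = kind)
}

write_newick_lines <- function(trees, path) {
  writeLines(vapply(trees, ape::write.tree, ""), path)
}
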