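# Simulation of treecloud datasets with controlled congruence structure:
# a species tree, posterior-like gene clouds (NNI jitter + lognormal
# branch-length noise), HGT-perturbed clouds and tip-randomized clouds.

#' Simulation configuration
#'
#' Defaults emulate the design of a 28-genome core-gene study: 28 taxa,
#' 1000-tree posterior samples per cloud, moderate topological jitter
#' (1 expected NNI move per sampled tree), lognormal multiplicative
#' branch-length noise (sigma 0.3), and heavy-tailed branch lengths that
#' concentrate treelength on a few branches as real posteriors do.
#'
#' @param n_taxa number of taxa (>= 4).
#' @param n_genes number of gene treeclouds.
#' @param n_trees_per_cloud posterior sample size per cloud.
#' @param topo_jitter_rate expected NNI moves per posterior sample (>= 0).
#' @param bl_noise_sigma lognormal SD of multiplicative branch-length noise.
#' @param bl_distribution `"heavy_tailed_mixture"` (default) or
#'   `"exponential"`.
#' @param hgt_fraction fraction of genes whose central tree is perturbed by
#'   SPR transfer events.
#' @param n_spr_per_hgt_gene leaf prune-and-regraft moves per HGT gene.
#' @param seed master integer seed; all component streams derive from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_taxa = 28, n_genes = 40,
                              n_trees_per_cloud = 1000,
                              topo_jitter_rate = 1, bl_noise_sigma = 0.3,
                              bl_distribution = c("heavy_tailed_mixture",
                                                  "exponential"),
                              hgt_fraction = 0, n_spr_per_hgt_gene = 1,
                              seed = 1) {
  bl_distribution <- match.arg(bl_distribution)
  if (n_taxa < 4) stopf("n_taxa must be >= 4")
  if (n_taxa > .MAX_TAXA) stopf("at most %d taxa supported", .MAX_TAXA)
  if (topo_jitter_rate < 0 || bl_noise_sigma < 0)
    stopf("rates must be >= 0")
  if (hgt_fraction < 0 || hgt_fraction > 1)
    stopf("hgt_fraction must be in [0, 1]")
  if (n_spr_per_hgt_gene < 1) stopf("n_spr_per_hgt_gene must be >= 1")
  structure(list(n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes),
                 n_trees_per_cloud = as.integer(n_trees_per_cloud),
                 topo_jitter_rate = topo_jitter_rate,
                 bl_noise_sigma = bl_noise_sigma,
                 bl_distribution = bl_distribution,
                 hgt_fraction = hgt_fraction,
                 n_spr_per_hgt_gene = as.integer(n_spr_per_hgt_gene),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# branch-length draws; the mixture puts ~15% of branches on a long scale
# so that a few branches carry most of the treelength
draw_branch_lengths <- function(n, distribution) {
  switch(distribution,
         exponential = rexp(n, rate = 10),
         heavy_tailed_mixture = {
           long <- runif(n) < 0.15
           ifelse(long, rexp(n, rate = 2), rexp(n, rate = 50))
         })
}

#' Simulate a species tree
#'
#' Random unrooted binary tree with positive branch lengths from the
#' chosen distribution.
#'
#' @param n_taxa number of taxa (>= 4).
#' @param bl_distribution `"heavy_tailed_mixture"` or `"exponential"`.
#' @param seed integer seed.
#' @return an unrooted `phylo` with tip labels `t01, t02, ...`.
#' @export
simulate_species_tree <- function(n_taxa,
                                  bl_distribution = "heavy_tailed_mixture",
                                  seed = 1) {
  if (n_taxa < 4) stopf("n_taxa must be >= 4")
  withr::with_seed(as.integer(seed), {
    tr <- ape::unroot(ape::rtree(n_taxa, br = NULL,
                                 tip.label = sprintf("t%02d", seq_len(n_taxa))))
    tr$edge.length <- draw_branch_lengths(nrow(tr$edge), bl_distribution)
    # strictly positive lengths
    tr$edge.length <- pmax(tr$edge.length, 1e-8)
    tr
  })
}

#' Simulate a posterior-like treecloud around a central tree
#'
#' Stand-in for an MCMC posterior sample: each sampled tree is the central
#' tree after `K ~ Poisson(topo_jitter_rate)` random NNI moves, with
#' independent lognormal multiplicative noise on every branch length.
#' `topo_jitter_rate = 0, bl_noise_sigma = 0` reproduces the central tree
#' exactly.
#'
#' @param central a `phylo`.
#' @param n_trees posterior sample size.
#' @param topo_jitter_rate expected NNI moves per sample.
#' @param bl_noise_sigma lognormal sigma of branch-length noise.
#' @param seed integer seed.
#' @param cloud_id,source_kind passed to [tree_cloud()].
#' @return a `tree_cloud`.
#' @export
simulate_posterior_cloud <- function(central, n_trees = 1000,
                                     topo_jitter_rate = 1,
                                     bl_noise_sigma = 0.3, seed = 1,
                                     cloud_id = "posterior",
                                     source_kind = "gene") {
  central <- as_unrooted(central)
  trees <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_trees), function(i) {
      k <- rpois(1L, topo_jitter_rate)
      tr <- if (k > 0) phangorn::rNNI(central, moves = k) else central
      if (bl_noise_sigma > 0)
        tr$edge.length <- tr$edge.length *
          rlnorm(length(tr$edge.length), meanlog = -bl_noise_sigma^2 / 2,
                 sdlog = bl_noise_sigma)
      tr
    })
  })
  tree_cloud(trees, cloud_id, source_kind = source_kind)
}

#' Apply horizontal-transfer-like SPR moves to a tree
#'
#' Each move prunes one uniformly chosen leaf and regrafts it at a
#' uniformly chosen position on another edge, mimicking the topological
#' effect of replacing one genome's copy of a gene by a laterally
#' transferred ortholog. Leaf-level moves guarantee
#' `spr_surrogate_distance(input, output) <= n_spr`.
#'
#' @param tree a `phylo` with branch lengths and >= 4 leaves.
#' @param n_spr number of moves (>= 1).
#' @param seed integer seed.
#' @return the perturbed unrooted `phylo` (same leaf set, topology changed).
#' @export
apply_hgt <- function(tree, n_spr = 1, seed = 1) {
  if (n_spr < 1) stopf("n_spr must be >= 1")
  tree <- as_unrooted(tree)
  if (length(tree$tip.label) < 4L) stopf("need at least 4 leaves")
  withr::with_seed(as.integer(seed), {
    out <- tree
    for (k in seq_len(n_spr)) {
      for (try in 1:20) {
        cand <- move_one_leaf(out)
        if (symmetric_distance(cand, out) > 0) break
      }
      out <- cand
    }
    out
  })
}

# prune a random leaf and regraft on a random edge; uses the caller's RNG
move_one_leaf <- function(tree) {
  leaf <- sample(tree$tip.label, 1L)
  tip_id <- match(leaf, tree$tip.label)
  pend <- tree$edge.length[tree$edge[, 2] == tip_id]
  rest <- ape::drop.tip(tree, leaf)
  e <- sample.int(nrow(rest$edge), 1L)
  pos <- runif(1L, 0.05, 0.95) * rest$edge.length[e]
  new <- phytools::bind.tip(rest, leaf, edge.length = pend,
                            where = rest$edge[e, 2], position = pos)
  as_unrooted(new)
}

#' Simulate a full treecloud dataset
#'
#' Draws a species tree, a reference treecloud around it, and per-gene
#' posterior clouds. Each gene's central tree is the species tree after a
#' per-gene draw of `Poisson(topo_jitter_rate)` NNI moves (individual
#' genes deviate from the organismal history even without transfer); a
#' fraction `hgt_fraction` of genes additionally have their central tree
#' perturbed by `n_spr_per_hgt_gene` transfer events. The reference cloud
#' is centered on the species tree itself. Fully reproducible from the
#' config's master seed.
#'
#' @param config a [simulation_config()].
#' @return list with `clouds` (gene `tree_cloud`s), `reference` (the
#'   reference `tree_cloud`), `species_tree`, `truth` (data frame:
#'   `cloud_id`, `is_hgt`, `n_spr_applied`), `central_trees` (named list of
#'   per-gene central `phylo`s) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- derive_seeds(config$seed, 3L + 3L * config$n_genes)
  # every gene deviates from the organismal tree by at least one move
  # (no real gene posterior is centered exactly on the species tree);
  # a zero jitter rate keeps the fully degenerate, exactly-congruent case
  center_jitter <- withr::with_seed(seeds[3] %% 1000000L + 1L, {
    k <- rpois(config$n_genes, config$topo_jitter_rate)
    if (config$topo_jitter_rate > 0) k + 1L else k
  })
  species <- simulate_species_tree(config$n_taxa, config$bl_distribution,
                                   seed = seeds[1])
  reference <- simulate_posterior_cloud(
    species, n_trees = config$n_trees_per_cloud,
    topo_jitter_rate = config$topo_jitter_rate,
    bl_noise_sigma = config$bl_noise_sigma, seed = seeds[2],
    cloud_id = "reference", source_kind = "reference")
  n_hgt <- round(config$hgt_fraction * config$n_genes)
  is_hgt <- rep(FALSE, config$n_genes)
  if (n_hgt > 0)
    is_hgt[withr::with_seed(seeds[3],
                            sample.int(config$n_genes, n_hgt))] <- TRUE
  ids <- sprintf("gene_%03d", seq_len(config$n_genes))
  centrals <- vector("list", config$n_genes)
  clouds <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    central <- species
    if (center_jitter[g] > 0)
      central <- withr::with_seed(seeds[3L + g],
                                  phangorn::rNNI(central,
                                                 moves = center_jitter[g]))
    if (is_hgt[g])
      central <- apply_hgt(central, n_spr = config$n_spr_per_hgt_gene,
                           seed = seeds[3L + g] %% 1000000L + 7L)
    centrals[[g]] <- central
    clouds[[g]] <- simulate_posterior_cloud(
      central, n_trees = config$n_trees_per_cloud,
      topo_jitter_rate = config$topo_jitter_rate,
      bl_noise_sigma = config$bl_noise_sigma,
      seed = seeds[3L + config$n_genes + g],
      cloud_id = ids[g], source_kind = "gene")
  }
  names(centrals) <- ids
  truth <- data.frame(cloud_id = ids, is_hgt = is_hgt,
                      n_spr_applied = ifelse(is_hgt,
                                             config$n_spr_per_hgt_gene, 0L),
                      stringsAsFactors = FALSE)
  list(clouds = clouds, reference = reference, species_tree = species,
       truth = truth, central_trees = centrals, config = config)
}

#' Write a simulated dataset to disk
#'
#' Multi-Newick file per cloud, truth table TSV, and the configuration as
#' JSON for reproducibility.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in c(dataset$clouds, list(dataset$reference)))
    write_tree_samples(cl, file.path(dir, paste0(cl$cloud_id, ".nwk")))
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE)
  manifest <- cloud_manifest(c(dataset$clouds, list(dataset$reference)))
  manifest$path <- file.path(dir, paste0(manifest$cloud_id, ".nwk"))
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
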