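# Centrality, treeishness, Welch/overlap screens and the gamma HGT test.

make_dist_matrix <- function(means, kinds = NULL) {
  ids <- rownames(means)
  structure(list(cloud_ids = ids,
                 source_kinds = kinds %||% rep("gene", nrow(means)),
                 metric = "symmetric", means = means, sds = means * 0,
                 provenance = list()), class = "cloud_dist_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("centrality p-values are rank/n and respect the grid", {
  expect_equal(centrality_p_value(1, 379), 1 / 379)
  expect_equal(round(centrality_p_value(1, 379), 4), 0.0026)
  expect_equal(round(centrality_p_value(1, 354), 4), 0.0028)
  expect_equal(centrality_p_value(354, 354), 1)
  expect_error(centrality_p_value(0, 10), "rank")

  # matrix-based test: focal with smallest mean ranks first
  n <- 12
  ids <- c("ref", paste0("g", 1:(n - 1)))
  withr::with_seed(5, {
    m <- matrix(runif(n * n, 10, 20), n, n, dimnames = list(ids, ids))
    m[1, ] <- m[, 1] <- runif(n, 1, 2)  # focal close to everything
    m <- (m + t(m)) / 2
    diag(m) <- 0
  })
  res <- centrality_test(make_dist_matrix(m), focal = "ref")
  expect_equal(res$focal_rank, 1L)
  expect_equal(res$n_clouds_in_null, n - 1L)
  expect_equal(res$p_value, 1 / (n - 1))
  # p always lies on the grid k/N
  expect_true(res$p_value * res$n_clouds_in_null %% 1 < 1e-12)

  # focal with the largest mean gets p = 1
  m2 <- m
  m2[1, ] <- m2[, 1] <- 100
  diag(m2) <- 0
  res2 <- centrality_test(make_dist_matrix(m2), focal = "ref")
  expect_equal(res2$p_value, 1)
  expect_error(centrality_test(make_dist_matrix(m), focal = "nope"),
               "not found")
})

test_that("centrality on clouds ranks a central reference first", {
  sp <- simulate_species_tree(12, seed = 44)
  ref <- simulate_posterior_cloud(sp, 30, topo_jitter_rate = 0.5, seed = 1,
                                  cloud_id = "ref", source_kind = "reference")
  genes <- lapply(1:6, function(i)
    simulate_posterior_cloud(sp, 30, topo_jitter_rate = 2, seed = 10 + i,
                             cloud_id = paste0("g", i)))
  res <- centrality_test(c(genes, list(ref)), focal = "ref",
                         n_pairs = 150, seed = 3)
  expect_equal(res$focal_rank, 1L)
  expect_equal(res$p_value, 1 / 6)
})

test_that("treeishness recovers its defining limits and arithmetic", {
  expect_equal(round(tau_from_means(16.86, 49.42), 2), 0.66)
  expect_equal(round(tau_from_means(0.58, 1.64), 2), 0.65)
  expect_equal(tau_from_means(0, 5), 1)
  expect_error(tau_from_means(1, 0), "degenerate")

  tails <- tau_tail_probs(0.66, 0.13)
  expect_equal(round(tails$p_ge_1, 3), 0.004)
  expect_lt(tails$p_le_0, 1e-6)

  # gene clouds identical to the reference: tau = 1
  tr <- random_binary(10, seed = 9)
  ref <- identical_cloud(tr, 8, id = "ref", kind = "reference")
  gene <- identical_cloud(tr, 8, id = "g1")
  rand <- shuffle_cloud(ref, seed = 2)
  res <- treeishness(list(gene), ref, list(rand), n_triplets = 200, seed = 1)
  expect_equal(res$tau_from_means, 1)
  expect_equal(res$mean_gene_ref_distance, 0)
  # reported components reproduce tau
  expect_equal(res$tau_from_means,
               1 - res$mean_gene_ref_distance / res$mean_ref_random_distance)

  # fully randomized "gene" clouds have tau ~ 0
  rand_gene <- shuffle_cloud(ref, seed = 7, cloud_id = "rg")
  res0 <- treeishness(list(rand_gene), ref, list(rand), n_triplets = 400,
                      seed = 2)
  expect_lt(abs(res0$tau_from_means), 0.15)
  expect_error(treeishness(list(gene), ref, list(), seed = 1), "empty")
})

test_that("treeishness decreases as partial randomization grows", {
  sp <- simulate_species_tree(14, seed = 77)
  ref <- simulate_posterior_cloud(sp, 25, seed = 1, cloud_id = "ref",
                                  source_kind = "reference")
  rand <- shuffle_cloud(ref, seed = 3)
  tau_at <- function(k) {
    seeds <- 500 + seq_len(25)
    trees <- lapply(seq_len(25), function(i)
      partial_shuffle(ref$trees[[i]], k, seed = seeds[i]))
    g <- tree_cloud(trees, paste0("shuf", k))
    treeishness(list(g), ref, list(rand), n_triplets = 300,
                seed = 11)$tau_from_means
  }
  taus <- vapply(c(0, 2, 6, 14), tau_at, 0)
  expect_gt(taus[1], 0.8)            # unshuffled: near 1
  expect_true(all(diff(taus) < 0.1)) # declining, up to MC noise
  expect_lt(taus[4], 0.35)           # near-complete randomization: near 0
})

test_that("Welch within/between screen flags shifted distributions", {
  sp <- simulate_species_tree(12, seed = 10)
  gene <- simulate_posterior_cloud(sp, 40, topo_jitter_rate = 0.5, seed = 2,
                                   cloud_id = "g")
  far <- simulate_posterior_cloud(apply_hgt(sp, 3, seed = 5), 40,
                                  topo_jitter_rate = 0.5, seed = 3,
                                  cloud_id = "ref", source_kind = "reference")
  row <- within_between_test(gene, far, n_pairs = 300, seed = 1,
                             n_tests_for_bonferroni = 379)
  expect_gt(row$between_mean, row$within_mean)
  expect_lt(row$welch_p_one_tailed, 0.05 / 379)
  expect_true(row$bonferroni_significant)
  expect_identical(row$bonferroni_significant,
                   row$welch_p_one_tailed < 0.05 / 379)

  # same posterior for gene and reference: no real shift, p not small
  twin <- simulate_posterior_cloud(sp, 40, topo_jitter_rate = 0.5, seed = 6,
                                   cloud_id = "twin",
                                   source_kind = "reference")
  row2 <- within_between_test(gene, twin, n_pairs = 300, seed = 2)
  expect_gt(row2$welch_p_one_tailed, 0.001)

  # degenerate zero-variance clouds: p = 1 by convention
  tr <- random_binary(8, seed = 3)
  cst <- identical_cloud(tr, 20, id = "c")
  row3 <- within_between_test(cst, identical_cloud(tr, 20, id = "r"),
                              n_pairs = 50, seed = 1)
  expect_equal(row3$welch_p_one_tailed, 1)
})

test_that("the 92/8 percentile overlap rule is boundary-inclusive", {
  expect_false(overlap_test(1:50, 101:150))   # disjoint: no overlap
  expect_true(overlap_test(1:50, 1:50))       # identical: overlap
  expect_error(overlap_test(1:5, 1:50), "13")

  # abutting exactly at the two percentiles: still overlap
  within <- 1:100
  q92 <- unname(quantile(within, 0.92, type = 7))  # = 1 + 0.92 * 99
  between <- (q92 - 0.08 * 99) + (0:99)  # its 8th percentile equals q92
  q8 <- unname(quantile(between, 0.08, type = 7))
  expect_equal(q8, q92, tolerance = 1e-9)
  expect_true(overlap_test(within, between))
  # nudge the between sample up: no overlap
  expect_false(overlap_test(within, between + 0.01))
})

test_that("gamma HGT screen is calibrated under the null and powered", {
  sp <- simulate_species_tree(16, seed = 20)
  post <- simulate_posterior_cloud(sp, 240, seed = 21, cloud_id = "post")
  # gene and reference clouds drawn from the same posterior sample
  gene <- tree_cloud(post$trees[1:120], "g")
  twin <- tree_cloud(post$trees[121:240], "ref", source_kind = "reference")
  null_res <- gamma_hgt_test(gene, twin, n_null = 400, n_between = 400,
                             seed = 23)
  # same-posterior clouds: ~ alpha of between gammas extreme
  expect_lt(null_res$count_extreme / 400, 0.12)
  expect_gt(null_res$binomial_p, 0.01)
  # binomial p is recomputable from the count
  expect_equal(null_res$binomial_p,
               pbinom(null_res$count_extreme - 1L, 400, 0.05,
                      lower.tail = FALSE))

  # reference perturbed by one transfer: many extreme gammas
  hgt_ref <- simulate_posterior_cloud(apply_hgt(sp, 1, seed = 30), 120,
                                      seed = 24, cloud_id = "href",
                                      source_kind = "reference")
  hgt_res <- gamma_hgt_test(gene, hgt_ref, n_null = 400, n_between = 400,
                            seed = 25)
  expect_gt(hgt_res$count_extreme, 3 * 0.05 * 400)
  expect_lt(hgt_res$binomial_p, 1e-6)

  expect_error(gamma_hgt_test(identical_cloud(sp, 1), twin, seed = 1),
               "2 trees")
})

test_that("incongruence report assembles one row per gene", {
  sp <- simulate_species_tree(10, seed = 60)
  genes <- lapply(1:3, function(i)
    simulate_posterior_cloud(sp, 30, seed = 60 + i,
                             cloud_id = paste0("g", i)))
  ref <- simulate_posterior_cloud(sp, 30, seed = 70, cloud_id = "ref",
                                  source_kind = "reference")
  rep <- incongruence_report(genes, ref, n_pairs = 100, gamma_n_null = 100,
                             gamma_n_between = 100, seed = 5)
  expect_equal(nrow(rep), 3L)
  expect_true(all(c("welch_p_one_tailed", "overlap", "gamma_binomial_p")
                  %in% names(rep)))
  expect_true(all(rep$gamma_count_extreme >= 0 & rep$gamma_count_extreme <= 100))
  # deterministic given the seed
  rep2 <- incongruence_report(genes, ref, n_pairs = 100, gamma_n_null = 100,
                              gamma_n_between = 100, seed = 5)
  expect_identical(rep, rep2)
})
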