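# Cloud-to-cloud distance estimation, all-pairs matrices and NMMDS.

test_that("cloud_distance handles degenerate and within-cloud cases", {
  tr <- random_binary(8, seed = 1)
  same <- identical_cloud(tr, 10)
  est <- cloud_distance(same, metric = "symmetric", n_trees = 10, seed = 1)
  expect_equal(est$mean, 0)
  expect_equal(est$sd, 0)

  # two singleton clouds: mean equals the single pairwise distance
  a <- identical_cloud(tr, 1, id = "a")
  b <- identical_cloud(shuffle_tip_labels(tr, 4), 1, id = "b")
  est1 <- cloud_distance(a, b, metric = "symmetric", n_trees = 1, seed = 1)
  expect_equal(est1$mean, symmetric_distance(tr, b$trees[[1]]))
  expect_equal(est1$n_pairs, 1L)

  expect_error(cloud_distance(a, b, mode = "random_pairs", n_pairs = 1),
               "n_pairs")
  expect_error(cloud_distance(same, n_trees = 50), "exceeds")
  mism <- identical_cloud(random_binary(7, seed = 2), 3, id = "m")
  expect_error(cloud_distance(same, mism, n_trees = 1), "leaf sets")
})

test_that("cloud_distance is seed-reproducible and mode-consistent", {
  sp <- simulate_species_tree(12, seed = 9)
  cl1 <- simulate_posterior_cloud(sp, 40, seed = 1, cloud_id = "g1")
  cl2 <- simulate_posterior_cloud(sp, 40, seed = 2, cloud_id = "g2")
  e1 <- cloud_distance(cl1, cl2, n_trees = 20, seed = 5)
  e2 <- cloud_distance(cl1, cl2, n_trees = 20, seed = 5)
  expect_identical(e1$distances, e2$distances)
  r1 <- cloud_distance(cl1, cl2, mode = "random_pairs", n_pairs = 200,
                       seed = 5)
  # the two subsampling protocols estimate the same quantity
  expect_equal(e1$mean, r1$mean, tolerance = 0.2 * e1$mean + 0.5)
  # within-cloud random pairs never pair a tree with itself: positive
  # distances for a cloud of 40 distinct jittered trees is not guaranteed,
  # but the sampler must never return the diagonal
  w <- cloud_distance(cl1, mode = "random_pairs", n_pairs = 100, seed = 3)
  expect_equal(w$n_pairs, 100L)
})

test_that("doubling the pair count shrinks the SE of the mean ~ sqrt(2)", {
  sp <- simulate_species_tree(10, seed = 30)
  cl1 <- simulate_posterior_cloud(sp, 60, seed = 31, cloud_id = "a")
  cl2 <- simulate_posterior_cloud(sp, 60, seed = 32, cloud_id = "b")
  means_at <- function(n_pairs) vapply(1:40, function(s)
    cloud_distance(cl1, cl2, mode = "random_pairs", n_pairs = n_pairs,
                   seed = 1000 + s)$mean, 0)
  ratio <- sd(means_at(50)) / sd(means_at(200))
  # expect ~ sqrt(4) = 2 for a 4x pair count, allow Monte-Carlo slack
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 3.0)
})

test_that("all-pairs matrix is symmetric with within-cloud diagonal", {
  tr <- random_binary(8, seed = 2)
  clouds <- lapply(1:3, function(i) identical_cloud(tr, 5, id = paste0("c", i)))
  m <- all_pairs_matrix(clouds, metric = "symmetric", n_trees = 5, seed = 1)
  expect_true(all(m$means == 0))
  expect_identical(dim(m$means), c(3L, 3L))

  sp <- simulate_species_tree(10, seed = 3)
  clouds2 <- lapply(1:4, function(i)
    simulate_posterior_cloud(sp, 30, seed = i, cloud_id = paste0("g", i)))
  m2 <- all_pairs_matrix(clouds2, metric = "rf_rescaled", n_trees = 15,
                         seed = 2)
  expect_identical(m2$means, t(m2$means))
  expect_true(all(is.finite(m2$means)))
  # rescaled-RF bound: the sum of two unit treelengths
  expect_lte(max(m2$means), 2.0)
})

test_that("label-shuffled clouds are mutually approximately equidistant", {
  sp <- simulate_species_tree(20, seed = 8)
  base <- simulate_posterior_cloud(sp, 30, seed = 1, cloud_id = "g")
  shuf <- lapply(1:4, function(i)
    shuffle_cloud(base, seed = 100 + i, cloud_id = paste0("r", i)))
  m <- all_pairs_matrix(shuf, metric = "symmetric", n_trees = 15, seed = 3)
  off <- m$means[upper.tri(m$means)]
  # near the 2(n-3) ceiling and within a few percent of each other
  expect_gt(min(off), 0.85 * 2 * (20 - 3))
  expect_lt((max(off) - min(off)) / mean(off), 0.1)
})

test_that("NMMDS embeds planar configurations with near-zero stress", {
  ids <- c("a", "b", "c")
  tri <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
                dimnames = list(ids, ids))
  mat <- structure(list(cloud_ids = ids, source_kinds = rep("gene", 3),
                        metric = "symmetric", means = tri, sds = tri * 0,
                        provenance = list()), class = "cloud_dist_matrix")
  em <- suppressWarnings(nmds_embed(mat, n_restarts = 5, seed = 1))
  expect_lt(em$stress, 0.01)
  em2 <- suppressWarnings(nmds_embed(mat, n_restarts = 5, seed = 1))
  expect_identical(em$points, em2$points)
})

test_that("NMMDS stress is recomputable from the returned coordinates", {
  withr::with_seed(11, {
    n <- 9
    x <- matrix(rnorm(3 * n), n, 3)
    d <- as.matrix(dist(x))
  })
  ids <- paste0("c", 1:9)
  dimnames(d) <- list(ids, ids)
  mat <- structure(list(cloud_ids = ids, source_kinds = rep("gene", 9),
                        metric = "symmetric", means = d, sds = d * 0,
                        provenance = list()), class = "cloud_dist_matrix")
  em <- nmds_embed(mat, n_restarts = 10, seed = 4)
  obs <- as.vector(as.dist(d))
  emb <- as.vector(dist(em$points))
  o <- order(obs)
  iso <- isoreg(emb[o])
  stress <- sqrt(sum((emb[o] - iso$yf)^2) / sum(emb^2))
  expect_equal(em$stress, stress, tolerance = 1e-6)
  expect_equal(em$r_squared, cor(obs, emb)^2, tolerance = 1e-12)
})

test_that("equidistant outliers embed on a peripheral arc", {
  # 6 tightly clustered clouds plus 4 outliers equidistant from everything
  n <- 10
  ids <- paste0("c", 1:n)
  m <- matrix(8, n, n, dimnames = list(ids, ids))
  m[1:6, 1:6] <- 1
  diag(m) <- 0
  mat <- structure(list(cloud_ids = ids,
                        source_kinds = c(rep("gene", 6), rep("randomized", 4)),
                        metric = "symmetric", means = m, sds = m * 0,
                        provenance = list()), class = "cloud_dist_matrix")
  em <- nmds_embed(mat, n_restarts = 10, seed = 2)
  centroid <- colMeans(em$points[1:6, ])
  r_gene <- sqrt(rowSums(sweep(em$points[1:6, ], 2, centroid)^2))
  r_out <- sqrt(rowSums(sweep(em$points[7:10, ], 2, centroid)^2))
  expect_gt(min(r_out), max(r_gene))
})
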