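# Statistical tests on treecloud space: centrality of the reference cloud,
# the treeishness statistic tau, Welch-t / percentile-overlap incongruence
# screens, and the gamma-based HGT test.

#' Centrality p-value from a rank
#'
#' The rank-based p-value of the centrality test: the rank of the focal
#' cloud's mean distance among the null clouds' means, divided by the size
#' of the null (e.g. rank 1 of 379 gives p = 1/379 ~ 0.0026).
#'
#' @param rank integer rank (1 = smallest mean distance).
#' @param n_null number of clouds in the null.
#' @return p-value in `(0, 1]`.
#' @export
centrality_p_value <- function(rank, n_null) {
  if (rank < 1 || rank > n_null) stopf("rank must be in [1, n_null]")
  rank / n_null
}

#' Rank-based test of the centrality of a treecloud
#'
#' For every cloud, computes its mean distance to all other clouds (by
#' randomly sampling `n_pairs` tree pairs per cloud pair and averaging the
#' per-pair means over the other clouds). The focal cloud's mean is ranked
#' within the null formed by the other clouds' means; `p = rank / n_null`.
#' A focal cloud at the statistical center of treespace ranks first.
#'
#' @param clouds list of `tree_cloud` objects, or a precomputed
#'   `cloud_dist_matrix` (its `means` are then used directly).
#' @param focal `cloud_id` of the focal (reference) cloud.
#' @param metric one of [treecloud_metrics()] (ignored when a matrix is
#'   supplied).
#' @param n_pairs tree pairs sampled per cloud pair.
#' @param seed integer seed.
#' @return object of class `centrality_result`: `focal_cloud`,
#'   `per_cloud_mean_distance` (named), `focal_rank`, `n_clouds_in_null`,
#'   `p_value`.
#' @export
centrality_test <- function(clouds, focal, metric = "symmetric",
                            n_pairs = 1000, seed = 1) {
  if (inherits(clouds, "cloud_dist_matrix")) {
    ids <- clouds$cloud_ids
    m <- clouds$means
  } else {
    if (length(clouds) < 3L) stopf("need at least 3 clouds")
    ids <- vapply(clouds, function(cl) cl$cloud_id, "")
    n <- length(clouds)
    seeds <- matrix(derive_seeds(seed, n * n), n, n)
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      est <- cloud_distance(clouds[[i]], clouds[[j]], metric = metric,
                            mode = "random_pairs", n_pairs = n_pairs,
                            seed = seeds[i, j])
      m[i, j] <- m[j, i] <- est$mean
    }
  }
  if (!focal %in% ids) stopf("focal cloud '%s' not found", focal)
  diag(m) <- NA_real_  # mean distance to *other* clouds only
  per_cloud <- rowMeans(m, na.rm = TRUE)
  focal_mean <- per_cloud[[focal]]
  null_means <- per_cloud[names(per_cloud) != focal]
  # rank of the focal mean on the null; a focal above the whole null sits
  # at the top rank (p = 1)
  rank <- min(1L + sum(null_means < focal_mean), length(null_means))
  structure(list(focal_cloud = focal, per_cloud_mean_distance = per_cloud,
                 focal_rank = rank, n_clouds_in_null = length(null_means),
                 p_value = centrality_p_value(rank, length(null_means))),
            class = "centrality_result")
}

#' @export
print.centrality_result <- function(x, ...) {
  cat(sprintf(
    "centrality of '%s': rank %d of %d null clouds, p = %.4g\n",
    x$focal_cloud, x$focal_rank, x$n_clouds_in_null, x$p_value))
  invisible(x)
}

#' Treeishness from category means
#'
#' `tau = 1 - d(T_G, T_U) / d(T_R, T_U)`: one minus the ratio of the mean
#' gene-to-reference distance over the mean randomized-to-reference
#' distance. 1 when gene treeclouds are identical to the reference cloud,
#' 0 when they are no closer to it than tip-randomized trees.
#'
#' @param mean_gene_ref mean gene-to-reference tree distance.
#' @param mean_ref_random mean randomized-to-reference tree distance
#'   (must be > 0).
#' @return tau.
#' @export
tau_from_means <- function(mean_gene_ref, mean_ref_random) {
  if (mean_ref_random <= 0) stopf("degenerate null: d(T_R, T_U) must be > 0")
  1 - mean_gene_ref / mean_ref_random
}

#' One-tailed normal tail probabilities for tau
#'
#' `P(tau >= 1)` and `P(tau <= 0)` under a normal approximation at the
#' sampled mean and SD of the tau array.
#'
#' @param tau_mean,tau_sd mean and SD of the sampled tau distribution.
#' @return named list with `p_ge_1` and `p_le_0`.
#' @export
tau_tail_probs <- function(tau_mean, tau_sd) {
  list(p_ge_1 = pnorm(1, tau_mean, tau_sd, lower.tail = FALSE),
       p_le_0 = pnorm(0, tau_mean, tau_sd))
}

#' Treeishness of a collection of gene treeclouds
#'
#' Summarizes how similar a population of gene treeclouds is to a central
#' reference treecloud, relative to tip-randomized null treeclouds.
#' Computed both from category means (`tau_from_means`) and as a
#' distribution over sampled triplets (gene tree, reference tree,
#' randomized tree), each triplet yielding
#' `tau_i = 1 - d(gene_i, ref_i) / d(rand_i, ref_i)`; the triplet array
#' gives `tau_mean`, `tau_sd` and the one-tailed normal tail probabilities
#' at 1 and 0.
#'
#' @param gene_clouds list of `tree_cloud` objects.
#' @param reference_cloud the reference `tree_cloud`.
#' @param randomized_clouds non-empty list of tip-randomized `tree_cloud`s.
#' @param metric one of [treecloud_metrics()].
#' @param n_triplets number of sampled triplets.
#' @param seed integer seed.
#' @return object of class `treeishness_result` with `tau_from_means`,
#'   `tau_mean`, `tau_sd`, `p_ge_1`, `p_le_0`, `metric`, and the component
#'   means `mean_gene_ref_distance`, `mean_gene_random_distance`,
#'   `mean_ref_random_distance`.
#' @export
treeishness <- function(gene_clouds, reference_cloud, randomized_clouds,
                        metric = "symmetric", n_triplets = 1000, seed = 1) {
  metric <- match.arg(metric, treecloud_metrics())
  if (length(randomized_clouds) == 0L) stopf("randomized_clouds is empty")
  if (inherits(gene_clouds, "tree_cloud")) gene_clouds <- list(gene_clouds)
  if (inherits(randomized_clouds, "tree_cloud"))
    randomized_clouds <- list(randomized_clouds)
  seeds <- derive_seeds(seed, 4L)
  picks <- withr::with_seed(seeds[1], {
    g_cl <- sample.int(length(gene_clouds), n_triplets, replace = TRUE)
    r_cl <- sample.int(length(randomized_clouds), n_triplets, replace = TRUE)
    g_tr <- vapply(g_cl, function(i)
      sample.int(n_trees(gene_clouds[[i]]), 1L), 0L)
    r_tr <- vapply(r_cl, function(i)
      sample.int(n_trees(randomized_clouds[[i]]), 1L), 0L)
    u_tr <- sample.int(n_trees(reference_cloud), n_triplets, replace = TRUE)
    u_tr2 <- sample.int(n_trees(reference_cloud), n_triplets, replace = TRUE)
    list(g_cl = g_cl, g_tr = g_tr, r_cl = r_cl, r_tr = r_tr,
         u_tr = u_tr, u_tr2 = u_tr2)
  })
  # distances per triplet, batched per contributing cloud
  d_gu <- d_ru <- d_gr <- numeric(n_triplets)
  for (i in seq_along(gene_clouds)) {
    sel <- picks$g_cl == i
    if (!any(sel)) next
    d_gu[sel] <- cloud_pair_distances(gene_clouds[[i]], reference_cloud,
                                      picks$g_tr[sel], picks$u_tr[sel],
                                      metric)
  }
  for (i in seq_along(randomized_clouds)) {
    sel <- picks$r_cl == i
    if (!any(sel)) next
    d_ru[sel] <- cloud_pair_distances(randomized_clouds[[i]], reference_cloud,
                                      picks$r_tr[sel], picks$u_tr2[sel],
                                      metric)
    for (j in seq_along(gene_clouds)) {
      sel2 <- sel & picks$g_cl == j
      if (!any(sel2)) next
      d_gr[sel2] <- cloud_pair_distances(gene_clouds[[j]],
                                         randomized_clouds[[i]],
                                         picks$g_tr[sel2], picks$r_tr[sel2],
                                         metric)
    }
  }
  if (all(d_ru == 0)) stopf("degenerate null: all d(T_R, T_U) are zero")
  ok <- d_ru > 0
  tau_arr <- 1 - d_gu[ok] / d_ru[ok]
  tails <- tau_tail_probs(mean(tau_arr), sd(tau_arr))
  structure(list(
    tau_from_means = tau_from_means(mean(d_gu), mean(d_ru)),
    tau_mean = mean(tau_arr), tau_sd = sd(tau_arr),
    p_ge_1 = tails$p_ge_1, p_le_0 = tails$p_le_0,
    metric = metric, n_triplets = sum(ok), seed = as.integer(seed),
    mean_gene_ref_distance = mean(d_gu),
    mean_gene_random_distance = mean(d_gr),
    mean_ref_random_distance = mean(d_ru)),
    class = "treeishness_result")
}

#' @export
print.treeishness_result <- function(x, ...) {
  cat(sprintf(
    paste0("treeishness (%s): tau = %.2f (from means), %.2f +/- %.2f ",
           "(triplets)\n  P(tau >= 1) = %.3g, P(tau <= 0) = %.3g\n"),
    x$metric, x$tau_from_means, x$tau_mean, x$tau_sd, x$p_ge_1, x$p_le_0))
  invisible(x)
}

#' Welch test of within- versus between-treecloud distances
#'
#' One-tailed Welch (unequal-variance) t-test of whether gene-to-reference
#' ("between") distances exceed within-gene-cloud distances, with a
#' Bonferroni significance flag, plus the percentile-overlap check of
#' [overlap_test()].
#'
#' @param gene_cloud,reference_cloud `tree_cloud` objects (>= 2 trees each).
#' @param metric one of [treecloud_metrics()].
#' @param n_pairs tree pairs sampled for each distance distribution.
#' @param seed integer seed.
#' @param n_tests_for_bonferroni number of tests the 0.05 level is divided
#'   by.
#' @return one-row data frame: `cloud_id`, `within_mean`, `between_mean`,
#'   `welch_t`, `welch_p_one_tailed`, `bonferroni_significant`, `overlap`.
#' @export
within_between_test <- function(gene_cloud, reference_cloud,
                                metric = "symmetric", n_pairs = 1000,
                                seed = 1, n_tests_for_bonferroni = 1) {
  if (n_trees(gene_cloud) < 2L || n_trees(reference_cloud) < 2L)
    stopf("both clouds need at least 2 trees")
  seeds <- derive_seeds(seed, 2L)
  within <- cloud_distance(gene_cloud, metric = metric,
                           mode = "random_pairs", n_pairs = n_pairs,
                           seed = seeds[1])$distances
  between <- cloud_distance(gene_cloud, reference_cloud, metric = metric,
                            mode = "random_pairs", n_pairs = n_pairs,
                            seed = seeds[2])$distances
  wt <- tryCatch(
    t.test(between, within, alternative = "greater", var.equal = FALSE),
    error = function(e) NULL)
  if (is.null(wt) || !is.finite(wt$p.value)) { # both samples constant
    p <- if (mean(between) > mean(within)) 0 else 1
    tstat <- NA_real_
  } else {
    p <- wt$p.value
    tstat <- unname(wt$statistic)
  }
  data.frame(cloud_id = gene_cloud$cloud_id,
             within_mean = mean(within), between_mean = mean(between),
             welch_t = tstat, welch_p_one_tailed = p,
             bonferroni_significant = p < 0.05 / n_tests_for_bonferroni,
             overlap = overlap_test(within, between),
             stringsAsFactors = FALSE)
}

#' Percentile-overlap check of two distance distributions
#'
#' Returns `TRUE` ("overlapping") when the 92nd percentile of the
#' within-cloud distances is at or above the 8th percentile of the
#' between-cloud distances (the 84% confidence-interval overlap rule;
#' boundary inclusive). Percentiles use linear interpolation between order
#' statistics (`quantile` type 7).
#'
#' @param within_sample,between_sample numeric samples of at least 13
#'   values each.
#' @return logical: do the distributions overlap?
#' @export
overlap_test <- function(within_sample, between_sample) {
  if (length(within_sample) < 13L || length(between_sample) < 13L)
    stopf("need at least 13 values per sample for the 92/8 percentile rule")
  unname(quantile(within_sample, 0.92, type = 7) >=
           quantile(between_sample, 0.08, type = 7))
}

#' Gamma-based screen for horizontal gene transfer
#'
#' Builds the null distribution of Ge's gamma on `n_null` random
#' within-gene-cloud tree pairs, computes gamma on `n_between` random
#' gene-versus-reference pairs, counts how many between-cloud gammas are
#' extreme relative to the null at level `alpha`, and compares that count
#' to the binomial expectation (`n_between` trials at rate `alpha`) with an
#' upper-tail binomial p-value.
#'
#' Gamma takes few discrete values when trees differ by small rearrangement
#' counts, so the null typically has large tied atoms and the naive
#' "at or above the `(1 - alpha)` null quantile" rule can count far more
#' (or, read strictly, far fewer) than `alpha` of exchangeable pairs as
#' extreme, invalidating the binomial comparison. The default therefore
#' ranks each between-cloud gamma within the null with uniform random
#' tie-breaking (a randomized PIT: extreme when the tie-broken rank
#' exceeds the `1 - alpha` point), which is exactly calibrated under
#' exchangeability and coincides with the quantile rule when the null has
#' no ties. `ties = "at_or_above"` applies the literal inclusive-quantile
#' rule instead.
#'
#' @param gene_cloud,reference_cloud `tree_cloud` objects (>= 2 trees each).
#' @param n_null within-cloud null pairs.
#' @param n_between between-cloud pairs.
#' @param alpha extremeness level of the screen.
#' @param seed integer seed.
#' @param ties `"randomized"` (default) or `"at_or_above"`; see Details.
#' @return object of class `gamma_hgt_result`: `count_extreme`,
#'   `binomial_p`, `threshold` (the `1 - alpha` null quantile, for
#'   reference), `null_gamma`, `between_gamma`, `n_between`, `alpha`,
#'   `ties`.
#' @export
gamma_hgt_test <- function(gene_cloud, reference_cloud, n_null = 1000,
                           n_between = 1000, alpha = 0.05, seed = 1,
                           ties = c("randomized", "at_or_above")) {
  ties <- match.arg(ties)
  if (n_trees(gene_cloud) < 2L || n_trees(reference_cloud) < 2L)
    stopf("both clouds need at least 2 trees")
  ng <- n_trees(gene_cloud); nu <- n_trees(reference_cloud)
  idx <- withr::with_seed(as.integer(seed), {
    ia <- sample.int(ng, n_null, replace = TRUE)
    ib <- sample.int(ng, n_null, replace = TRUE)
    while (any(same <- ia == ib))
      ib[same] <- sample.int(ng, sum(same), replace = TRUE)
    list(ia = ia, ib = ib,
         ga = sample.int(ng, n_between, replace = TRUE),
         gb = sample.int(nu, n_between, replace = TRUE),
         u = runif(n_between))
  })
  null_gamma <- gamma_pairs(gene_cloud, gene_cloud, idx$ia, idx$ib)$gamma
  between_gamma <- gamma_pairs(gene_cloud, reference_cloud,
                               idx$ga, idx$gb)$gamma
  threshold <- unname(quantile(null_gamma, 1 - alpha, type = 7))
  if (ties == "at_or_above") {
    count <- sum(between_gamma >= threshold)
  } else {
    below <- vapply(between_gamma, function(g) sum(null_gamma < g), 0)
    tied <- vapply(between_gamma, function(g) sum(null_gamma == g), 0)
    u_rank <- (below + idx$u * (tied + 1)) / (n_null + 1)
    count <- sum(u_rank > 1 - alpha)
  }
  p <- pbinom(count - 1L, n_between, alpha, lower.tail = FALSE)
  structure(list(cloud_id = gene_cloud$cloud_id, count_extreme = count,
                 binomial_p = p, threshold = threshold,
                 null_gamma = null_gamma, between_gamma = between_gamma,
                 n_between = n_between, alpha = alpha, ties = ties,
                 seed = as.integer(seed)),
            class = "gamma_hgt_result")
}

#' @export
print.gamma_hgt_result <- function(x, ...) {
  cat(sprintf(
    "gamma HGT screen '%s': %d of %d between-cloud gammas above the %.0f%% null quantile (binomial p = %.3g)\n",
    x$cloud_id, x$count_extreme, x$n_between, 100 * (1 - x$alpha),
    x$binomial_p))
  invisible(x)
}

#' Per-gene incongruence report
#'
#' One row per gene treecloud combining the Welch within/between test, the
#' percentile-overlap check, and the gamma HGT screen against a reference
#' treecloud. Bonferroni correction uses the number of gene clouds.
#'
#' @param gene_clouds list of `tree_cloud` objects.
#' @param reference_cloud the reference `tree_cloud`.
#' @param metric one of [treecloud_metrics()] (for the distance screens).
#' @param n_pairs pairs per distance sample.
#' @param gamma_n_null,gamma_n_between pair counts for [gamma_hgt_test()].
#' @param alpha extremeness level of the gamma screen.
#' @param seed integer seed.
#' @return data frame, one row per gene cloud.
#' @export
incongruence_report <- function(gene_clouds, reference_cloud,
                                metric = "symmetric", n_pairs = 1000,
                                gamma_n_null = 1000, gamma_n_between = 1000,
                                alpha = 0.05, seed = 1) {
  seeds <- matrix(derive_seeds(seed, 2L * length(gene_clouds)), ncol = 2L)
  rows <- lapply(seq_along(gene_clouds), function(i) {
    wb <- within_between_test(gene_clouds[[i]], reference_cloud,
                              metric = metric, n_pairs = n_pairs,
                              seed = seeds[i, 1],
                              n_tests_for_bonferroni = length(gene_clouds))
    g <- gamma_hgt_test(gene_clouds[[i]], reference_cloud,
                        n_null = gamma_n_null, n_between = gamma_n_between,
                        alpha = alpha, seed = seeds[i, 2])
    cbind(wb, data.frame(gamma_count_extreme = g$count_extreme,
                         gamma_binomial_p = g$binomial_p))
  })
  do.call(rbind, rows)
}
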