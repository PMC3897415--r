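---
title: "Quantifying congruence of Bayesian gene-tree posteriors with treecloud distances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying congruence of Bayesian gene-tree posteriors with treecloud distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When hundreds of single-copy gene families are available for a clade, each
family yields its own estimate of the organismal phylogeny, and a Bayesian
analysis yields not one tree per family but a posterior *distribution* of
trees — a **treecloud**. Horizontal gene transfer (HGT), model
misspecification, alignment error, short alignments and incomplete lineage
sorting all push individual gene trees away from the vertical (organismal)
history, raising the practical question: does a reference tree estimated
from a handful of well-conserved concatenated proteins represent the
histories of the rest of the genes, or is treespace so incoherent that no
central tendency exists?

`treecloud` operationalizes this question. Every gene family, the
concatenated reference, and tip-randomized null copies are treated as point
clouds in treespace; pairwise cloud distances are estimated by subsampling
tree pairs; and the resulting all-versus-all matrix supports a visual
analysis (non-metric multidimensional scaling, NMMDS) and a family of
statistics: a rank test for the *centrality* of the reference cloud, a
one-number *treeishness* summary `tau`, Welch-t and percentile-overlap
screens of per-gene incongruence, and Ge's `gamma` statistic as a targeted
HGT screen.

## Distances between trees and between treeclouds

Two tree-to-tree metrics are provided, both on unrooted trees:

* **Symmetric (Robinson–Foulds topology) distance**: the number of
  non-trivial bipartitions present in exactly one of the two trees. It is
  an even integer for binary trees, bounded by $2(n-3)$ for $n$ taxa; two
  independently label-randomized binary trees sit near that ceiling
  (mean $\approx 50$ for $n = 28$).
* **Branch-length RF distance**: over the union of the two trees' splits
  (pendant edges included, matched by leaf), accumulate branch-length
  differences, a split absent from one tree contributing its full length.
  The default accumulates absolute differences; squared differences are
  available via `convention = "squared"`. The absolute convention is the
  package default because it is the scale on which unit-rescaled, fully
  incongruent trees approach the analytic bound
  $d \le L(T_1) + L(T_2) = 2$, the magnitude a practitioner can sanity
  check against; the squared sum for such trees is two orders of magnitude
  smaller and dominated by a few long branches.

Because the branch-length metric otherwise just measures total treelength
differences (slowly evolving genes look "close" regardless of topology),
the `rf_rescaled` metric first rescales every sampled tree to total
treelength 1 (`rescale_to_unit_length()`); naive use of unscaled
branch-length distances is discouraged for cross-gene comparison.

A cloud-to-cloud distance is the mean over sampled tree pairs
(`cloud_distance()`). Two subsampling protocols are exposed, matching the
two ways such means are used: `all_cross_pairs` draws `n_trees` (default
100) trees per cloud without replacement and evaluates all cross pairs
(used when assembling all-pairs matrices), while `random_pairs` draws
`n_pairs` (default 1000) pairs with replacement (used by the statistical
tests; within-cloud sampling never pairs a tree with itself). Both are
deterministic given `seed`.

## MAST, the SPR surrogate and Ge's gamma

The maximum agreement subtree (MAST) of two trees is the largest leaf
subset on which their restrictions are topologically identical.
`mast_size()` computes it exactly: an unrooted MAST containing leaf $s$
corresponds to a rooted agreement subtree of the two trees rooted at $s$'s
neighbor with $s$ removed, so the unrooted value is the maximum over all
$n$ such rootings of a rooted dynamic program over node pairs. At
polytomies the program takes a maximum-weight bipartite matching of child
subtrees (Hungarian algorithm). Agreement is strict isomorphism of the
restricted trees; polytomies are therefore treated as hard. All trees a
posterior sample contains are binary in practice, where the distinction is
moot; for unresolved consensus trees the strict reading is the
conservative one. The surrogate transfer distance is
`spr_surrogate_distance() = n - mast_size()`, the number of leaves that
must be deleted to reconcile the topologies. It is a computable stand-in
for the NP-hard SPR distance, and it is exactly the quantity classical
phylogenetic software reports as "SPR distance" in this context; the two
differ in general (a transfer of a $k$-leaf subtree costs one SPR move but
up to $k$ leaf deletions), which is why the simulator's transfer events
move single leaves (see below).

Ge's statistic combines the two metrics:

$$\gamma = \frac{d_S}{m + n} - \frac{d_M}{x - 3},$$

where $d_S$ is the symmetric distance, $d_M$ the SPR surrogate, $m$ and
$n$ the internal-branch counts of the two trees and $x$ the taxon count.
The normalization is a genuinely open reading of the source material: the
denominators used here are the internal-branch counts for $d_S$ (so a
fully incongruent binary pair has a first term of 1) and the maximal
surrogate distance $x - 3$ for $d_M$ (so the second term is also in
$[0, 1]$). `ge_gamma()` reports every component so any alternative
normalization can be recomputed from the result. High gamma — much
incongruence, removable by few transfers — is the HGT signature.

## The gamma HGT screen and discreteness

`gamma_hgt_test()` follows the screening recipe: a null of gamma over
1000 random within-gene-cloud pairs, gamma over 1000 gene-versus-reference
pairs, a count of between-cloud gammas extreme at level
$\alpha = 0.05$ relative to the null, and an upper-tail binomial p-value
for that count against `Binomial(1000, 0.05)`.

One numerical point deserves emphasis. Gamma is a function of small
integer rearrangement counts, so its null distribution over posterior tree
pairs is concentrated on few values; an atom frequently spans the 95th
percentile. Counting between-cloud gammas "at or above the 95th null
percentile" then classifies the whole atom as extreme — under simulated
exchangeable clouds we measured self-null "extreme" fractions above 0.5
instead of 0.05, which makes the binomial comparison meaningless (a strict
">" reading errs in the opposite direction). The default extremeness rule
is therefore a randomized rank (randomized probability integral
transform): a between-cloud gamma is extreme when its null rank, with ties
broken uniformly at random, exceeds the $1-\alpha$ point. This is exactly
calibrated under exchangeability, coincides with the quantile rule
whenever the null is tie-free (the regime the recipe was designed for),
and retains full power against transfer-perturbed references. The literal
inclusive rule remains available as `ties = "at_or_above"`.

## Centrality, treeishness and the per-gene screens

**Centrality** (`centrality_test()`): for every cloud, the mean distance
to all other clouds is estimated; the focal (reference) cloud's mean is
ranked within the null formed by the other clouds' means, and
$p = \mathrm{rank} / N_\mathrm{null}$. The focal cloud is excluded from
its own null, so with 380 clouds the best attainable p is
$1/379 \approx 0.0026$. Ties rank low (conservative), and a focal above
the entire null is capped at the top rank ($p = 1$). The p-value lives on
the grid $k/N$ and is uniform on it when the focal cloud is exchangeable
with the null clouds.

**Treeishness** (`treeishness()`):

$$\tau = 1 - \frac{d(T_G, T_U)}{d(T_R, T_U)}$$

with $d(T_G, T_U)$ the gene-to-reference and $d(T_R, T_U)$ the
randomized-to-reference distance. $\tau = 1$ when gene clouds coincide
with the reference cloud, $\tau = 0$ when they carry no more signal than
tip-randomized trees. It is computed both from category means and as a
distribution over sampled (gene, reference, randomized) triplets, whose
mean and SD feed one-tailed normal tail probabilities
$P(\tau \ge 1)$ and $P(\tau \le 0)$. Triplets with a zero
randomized-to-reference distance are dropped (they cannot occur for
randomized clouds at realistic taxon counts; an all-degenerate sample is
an error).

**Per-gene screens** (`within_between_test()`, `overlap_test()`): the
within-cloud distance sample is compared to the gene-to-reference sample
with a one-tailed Welch unequal-variance t-test (Bonferroni-corrected
across genes), and with the 84%-confidence-interval overlap heuristic:
the distributions are called *overlapping* when the 92nd percentile of
the within distances reaches at least the 8th percentile of the between
distances (boundary inclusive). Percentiles use linear interpolation
between order statistics (`quantile` type 7), which matters at these
asymmetric percentile levels and is therefore fixed and documented. When
both samples are constant with equal means the Welch p is 1 by
convention. Note the overlap convention: interval intersection is scored
as overlap, which matches the confidence-interval-overlap logic the rule
is built on.

## NMMDS of treecloud space

`nmds_embed()` ordains the between-cloud means (the within-cloud diagonal
is stored in the matrix but excluded from the ordination, as is standard
for dissimilarity input) with Kruskal stress-1 NMMDS under isotonic
regression, ties unconstrained (vegan's `monoMDS`, global model). Every
run starts from a fresh random configuration; the best of `n_restarts`
(default 20) is returned with its stress and the squared Pearson
correlation $r^2$ between observed and embedded distances. Because any
2-D picture of a high-dimensional treespace is an abstraction, the
pipeline produces three independent embeddings per metric from different
seeds; clustering conclusions should be stable across them. A cluster of
congruent gene clouds surrounded by mutually equidistant randomized
clouds cannot be embedded exactly in the plane — the randomized clouds
are displayed on a peripheral arc at roughly equal radius, which is the
qualitative signature to expect, not genuine clustering of the randomized
clouds.

## The simulator

`simulate_dataset()` generates datasets with known congruence structure so
that every statistic can be exercised and calibrated without sequence
data. Its defaults are the study conditions the package is aimed at:
28 taxa, 1000 trees per posterior cloud. A posterior sample is emulated,
not re-estimated: each sampled tree is the cloud's central tree after
$K \sim \mathrm{Poisson}(\text{topo\_jitter\_rate})$ random NNI moves
(default rate 1, giving within-cloud symmetric means of a few units, small
against the randomized level of $\approx 50$, as in real posteriors) with
independent lognormal multiplicative branch-length noise (default sigma
0.3, a typical posterior CV for branch lengths). Branch lengths of the
species tree default to a heavy-tailed mixture — 15% of branches on a long
scale (Exponential with mean 0.5 substitutions/site), the rest short
(mean 0.02) — so that a few branches carry most of the treelength and
rescaled-RF distances between randomized clouds approach the analytic
bound of 2, as observed in real data. An exponential option is provided
for homogeneous lengths.

HGT genes get a central tree perturbed by `apply_hgt()`: each transfer
prunes one uniformly chosen leaf and regrafts it at a uniform position on
another edge. Transfers are modeled at the single-leaf level deliberately
— an HGT event replaces the gene copy of one recipient genome, relocating
one leaf of the gene tree — and this guarantees the invariant
`spr_surrogate_distance(original, perturbed) <= n_spr`, which multi-leaf
SPR moves would break.

What the simulator does *not* emulate: sequence-level estimation error
(alignments and substitution models are bypassed), MCMC autocorrelation,
coalescent incomplete lineage sorting, and rate variation across genes.
Passing calibration tests on simulated clouds therefore shows the
statistics behave as designed under posterior-like spread and controlled
transfer signal; it does not certify behavior under every real-data
pathology (paralogy, alignment error, long-branch attraction).

## Numerical choices and degenerate inputs

* Taxa are capped at 63 so a split is one 64-bit word; splits are
  canonicalized so rooted inputs are handled identically to their
  unrooted forms (the two root-adjacent edges merge, summing lengths).
* Burn-in removal is a fraction of trees in file order (generation
  numbers are not assumed); a cloud keeps the last
  $\lceil (1-f) \, n \rceil$ samples and must be non-empty.
* Trees with all-zero branch lengths cannot be rescaled (error); clouds
  with mixed leaf sets are a hard error naming the offending tree.
* Random pair sampling is with replacement (configurable by protocol
  choice); every sampling function takes an explicit seed, and compound
  analyses derive per-component seeds from one master seed, echoed into
  all outputs together with a config hash.
* All distances are deterministic; no tie-breaking is needed outside the
  gamma screen discussed above.

## Problem sizes used in the test suite

The shipped tests run the full logic at reduced scale, chosen to keep a
complete run comfortable on one CPU: oracle equivalence of the MAST
program against exhaustive subset enumeration on $10^4$ random pairs of
5–8-leaf trees; randomized-cloud geometry over 1000 pairs of 28-leaf
trees; gamma-screen calibration on 200-tree clouds split from one
simulated posterior; transfer-enrichment on 40 genes with 200-tree clouds
at 10% HGT; and NMMDS structure on 15 gene clouds plus 6 randomized
clouds. The same code paths scale to the 380-cloud, 1000-tree setting by
changing configuration values only.

## Known limitations

* The SPR surrogate equals leaf-deletion (MAST) distance, not true SPR
  distance; gamma inherits this choice, which is also how the statistic
  was computed in the classical tooling this package mirrors.
* Soft-polytomy (refinement-based) agreement subtrees are not
  implemented; unresolved consensus trees are compared strictly.
* The treeishness tail probabilities use a normal approximation at the
  sampled mean and SD of the tau array; the tau distribution is mildly
  skewed, so these tails are indicative rather than exact.
* NMMDS is for visualization; distances in the plot are rank-faithful at
  best, and all quantitative conclusions should rest on the distance
  matrix and the rank/t/binomial tests, not on embedded coordinates.
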