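---
title: "Methods: temporal-group analysis of PPI network topology and function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal-group analysis of PPI network topology and function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netphylo)
```

This vignette documents the models, statistics and design choices behind
`netphylo`, in the spirit of a methods section: what each stage assumes,
which knobs matter, how degenerate inputs are handled, and what the
synthetic-data tests do and do not demonstrate about real data.

## The analysis in one paragraph

Genes of an undirected, simple PPI network are stratified into six
temporal groups (TGs) by phylostratigraphy: a gene belongs to the oldest
clade in which it has a sequence-similarity hit at or below an e-value
threshold, and to the youngest group if it has none. Per-group topology
(degree, local clustering, shortest-path distances, interaction density)
quantifies how network structure varies with gene age. Function enters
through binary annotation vectors over the sub-root level of the Gene
Ontology, compared by Mahalanobis distance; group-averaged functional
distances are clustered into a dendrogram whose significance comes from
a gene-label permutation test, and correlated with group age
differences. Finally, hub neighborhoods ("topological units") are tested
for functional coherence against degree-preserving rewired networks,
with controls for directly interacting partner pairs and for duplicated
genes.

## Temporal groups

`assign_temporal_groups()` implements the oldest-clade rule: a hit
qualifies when `evalue <= threshold` (inclusive; the threshold is a
plain float, default `1e-20`), and the gene takes the smallest group
index among clades with a qualifying hit. Genes absent from every clade
form the final group — lineage-specific genes. The default species →
clade scheme (`temporal_group_scheme()`) maps protostomes to TG1, teleost
fish to TG2, amphibians to TG3, chicken to TG4 and non-primate mammals
to TG5, with approximate clade ages 990, 450, 360, 310, 90 and 50 Mya.
Assignment is monotone in the threshold: loosening it can only move a
gene to an *older* group, a property the test suite checks on random hit
tables. No minimum alignment length is enforced — hits are judged by
e-value alone, so pre-filtered hit tables should be supplied if coverage
matters.

Duplication clusters (`build_duplication_clusters()`) are the connected
components of the within-genome similarity graph at a stricter threshold
(default `1e-25`): similarity chains A–B, B–C place A, B, C in one
cluster even if A and C are dissimilar. Multi-gene clusters mark genes
with detectable duplication history.

## Topology statistics

Local clustering is `2T(v) / k(k-1)` and is *undefined* (`NA`), not
zero, for nodes of degree < 2; group means of clustering are taken over
defined nodes only. Shortest-path distances come from breadth-first
search on the unweighted graph; unreachable pairs are excluded from all
averages (the only convention that keeps means finite) and the excluded
fraction is reported per group-pair cell as a coverage attribute.
Group-pair averages count within-group pairs once and never include
self-pairs. The per-group "distance to all others" is the
pair-count-weighted mean over that group's row of the 6 × 6 matrix —
the same weighting used to reconstruct per-group means from published
group-level tables (`per_group_distance_reconstruction()`).

Interaction density normalization follows the row-wise reading: with
`normalize = TRUE` each row m of D is divided by group m's aggregate
density `sum_n I(m,n) / sum_n E(m,n)`, which makes rows comparable as
displayed; dividing by the whole-network density instead is available
via `normalize = "network"`.

Rates of change divide the absolute property difference between
consecutive groups by the age difference in Myr. The final stage
(TG5→TG6) is excluded by default — its 40-Myr span is too short for a
stable estimate — and rates are normalized per property by their sum
across stages (`normalize = "max"` and `"none"` are flags).

The degree-vs-age correlation uses the group index as the age rank (six
tied levels, average-rank ties): Spearman correlations are rank-based,
and six coarse age classes carry no more than their order. The power-law
summary (`degree_histogram_loglog()`) is a descriptive least-squares
slope on log2-binned frequencies, deliberately *not* a maximum-likelihood
exponent estimator.

## Functional distance

`build_annotation_matrix()` propagates each gene's annotations up the
is_a graph and records which *sub-root* terms (direct children of the
namespace root) are reached: using one fixed, shallow level avoids the
redundancy of deeper, nested terms and gives every gene a comparable
vector. GAF rows with a NOT qualifier are excluded; all evidence codes
(including IEA) are retained; terms missing from the ontology and
obsolete terms are dropped with logged counts.

The Mahalanobis distance uses the inverse covariance of the sub-root
terms, estimated over the entire annotation universe (not only network
genes): term dependence is a property of the annotation corpus, and the
larger universe stabilizes the estimate. Binary data with ubiquitous or
absent terms make the covariance singular; a ridge of `1e-6` is then
added to the diagonal, with a Moore–Penrose pseudoinverse as the final
fallback. The pseudoinverse identity `S S⁻ S = S` is asserted to 1e-8 in
the tests. With an identity covariance the distance reduces exactly to
Euclidean, which the suite property-tests on random binary vectors.

The Resnik backend defines term information content as
`IC = -log2 p(term)`, with `p` the fraction of annotated genes whose
propagated annotation set contains the term; gene similarity is the
maximum IC over common ancestors of any annotation pair, and distance is
`(1/2)^sim` — base 2 throughout, so that two identical single-term genes
with `p = 1/4` sit at distance `0.25` and genes sharing only the root at
distance 1. Either backend yields a positive functional-distance/age
correlation on age-graded synthetic data; Mahalanobis is the default
throughout the pipeline.

Pairwise distances for n genes are computed blockwise from the quadratic
form `d²(x,y) = q(x) + q(y) - 2 xᵀ Σ⁻¹ y`, and the
distance-vs-network-distance profile can subsample pairs (seeded) for
very large networks; exact mode is the default at the scales used here.

## The dendrogram permutation test

The 6 × 6 functional distance matrix is clustered by agglomerative
hierarchical clustering with average linkage (UPGMA) by default — the
linkage is not dictated by theory, so single and complete linkage are
available as flags. The test statistic is the *summed merge height* of
the tree: lower means the groups can be joined at shorter functional
distances, i.e. a more structured age-graded space. The null permutes
the gene → group labels (preserving group sizes), rebuilds the group
matrix from the unchanged pairwise distances and reclusters;
`p = (1 + #{null <= observed}) / (reps + 1)`, one-sided by the add-one
rule, so p is always in (0, 1]. One subtlety the test fixtures exposed:
the "lower sum = more structure" direction holds for *graded* structure
(adjacent groups closer than distant ones, as gene age produces); six
mutually equidistant clusters would invert it. Degenerate all-equal
matrices are tie-broken deterministically with a warning.

The functional-distance/age correlation defaults to the group *rank*
scale: Spearman rho between the 21 upper-triangle cells (diagonal
included, age difference 0) and |rank difference|. Absolute Mya
differences are available via `age_scale = "mya"`; note the two scales
order pairs differently because the Mya gaps between groups are uneven
(540, 90, 50, 220, 40 Myr), so the choice is substantive, and the rank
scale is the natural partner of a rank correlation over six coarse age
classes. A flag also excludes the diagonal (15 cells) for sensitivity
analysis.

## Hub coherence against rewired nulls

A hub is a node with degree at least `hub_min_degree`; when not given,
the pipeline uses the 0.98 degree quantile so the definition scales with
network size. The *group distance* of a hub averages functional
distances over unordered partner pairs from different temporal groups —
restricting to cross-group pairs removes the trivial contribution of
same-age functional similarity and makes the test conservative. Null
networks are degree-preserving rewirings (double-edge swaps rejecting
self-loops and multi-edges, 10 attempted swaps per edge, after which
edge overlap with the original drops well below 30% on
duplication-divergence networks). Per-hub values from all rewirings are
pooled (one-mean-per-rewiring is a flag) and compared with the empirical
values by a two-sample Kruskal–Wallis test — equivalent to Mann–Whitney,
df = 1 — reporting H, p and the direction of the difference.

Two bias controls mirror the confounds of this design: partner pairs
that are themselves edges can be dropped (directly interacting proteins
are functionally similar), and all genes in multi-gene duplication
clusters can be removed before hub calling (duplicated partners inherit
function). The distance-two baseline compares hub neighborhoods against
all gene pairs at network distance two — where non-interacting partners
of any node live. Its Z statistic uses *per-hub means* as the empirical
sampling units: partner pairs of one hub share genes and are strongly
correlated, and pooling pairs with an i.i.d. standard error makes the Z
anticonservative (we measured null SDs near 1.7 with pair pooling versus
1.08 with hub-level units in ablation runs).

The "controlled" correlation asks whether a property–age correlation
survives conditioning on function: the global Spearman rho (property vs
group index) is compared with the unweighted mean of within-category
rhos over all sub-root categories with at least 10 usable genes, via a
one-sample t-test of the per-category rhos against the global value
(df = retained categories − 1). This construction is an interpretation —
several "controlled correlation" definitions exist — chosen because it
is transparent, reproduces the df pattern of a per-category analysis
over ~30 sub-root terms, and a size-weighted variant is a flag.
Categories with constant property or constant group are excluded and
counted.

Enrichment uses the hypergeometric upper tail per (group, sub-root term)
with BH correction *within each group's family* (what a per-group
enrichment table tabulates), background defaulting to network genes
since the analysis concerns the network; property z-scores use
`z = (mean_cat - mean_all) / (sd_all / sqrt(n_cat))` with Gaussian
two-sided p and BH across categories.

## The synthetic-data generator

`generator_config()` documents every knob. The network grows by
duplication–divergence from a 5-clique: duplicate a uniform node, keep
each parent edge with probability `p_edge_retain = 0.4`, add
Poisson(`p_new_edge = 0.1` × mean degree) random edges; the largest
component is kept. These defaults were chosen once, from pilot runs,
to give a heavy-tailed degree distribution (top-decile mean ≳ 5× the
median), mean degree near 6 at n = 1000, and a clear birth-order/degree
gradient (Spearman ≈ −0.5) — the qualitative regime of curated human PPI
data at a desk-scale node count, not a fit to any particular network.

Births are cut at quantiles into six groups (equal sextiles by default)
carrying the standard ages. Annotations use a two-level toy ontology
(root + 30 sub-root terms): every gene carries 2 core terms; each
remaining term has a home group and is carried with probability
`0.7 · exp(-0.3 |group - home|)`. The gradient 0.3 was fixed from pilot
runs for a specific reason worth recording: the Mahalanobis metric
whitens by the *pooled* covariance, so if the age gradient is made very
strong it dominates the covariance and is normalized away —
between-group distances then saturate non-monotonically. A moderate
gradient survives whitening and yields group-level age correlations
around 0.5–0.7 at n = 1000, comparable to the published human value.
Each planted hub (top 2% by degree) carries a signature set of 3
non-core terms; partners adopt the full signature with probability
`hub_coherence = 0.8` — a hub neighborhood emulates a functional module
(e.g. a complex), which is why the signature is a term *set* rather than
a single term. Omega is Gamma(shape 2) with mean `0.03 + 0.03 (g - 1)`.
Hit tables are emitted consistently with the planted groups (qualifying
hit in the own clade, above-threshold decoys in older clades), and a
parent–child duplication leaves a detectable self-hit with probability
0.15 — genome-wide single-linkage at stringent thresholds captures only
a minority of duplication history, and full detectability would place
every gene in one pedigree cluster.

Setting `age_gradient = 0` and `hub_coherence = 0` ablates all
functional structure and is used for type-I calibration.

**What the generator does not emulate:** real GO DAG depth (two levels
only), sequence-level evolution (e-values are drawn, not computed),
annotation bias toward well-studied genes, false-positive interactions,
and a reliable clustering-coefficient gradient across ages — DD networks
at this density have noisy per-group clustering means, so the test suite
asserts heterogeneity of clustering across groups but not its
monotonicity. Passing the planted-truth tests therefore demonstrates
correctness of the machinery and adequate power at n = 1000, not that
real human data would show the same effect sizes.

## Problem sizes and numerical choices

The test suite runs the full pipeline at 1000 genes (one seed), the
hub-threshold stability check at 1000 genes, and type-I calibration at
400 genes × 24 ablated seeds with 49-permutation dendrogram tests —
sizes chosen so the whole suite completes in about a minute while the
binomial bound on the calibration count (≤ 4 rejections of 24 at
nominal 0.05; P(X ≥ 5) < 0.01) stays discriminating. The acceptance
script runs one full study at 1000 genes with 199-permutation tests.
Permutation p-values always use the add-one rule. Covariance inversion
prefers `solve()`, guarded by a reciprocal-condition-number check at
1e-10, then ridge + solve, then pseudoinverse. Distances are clamped at
zero before the square root to absorb negative round-off. All stochastic
stages accept a single seed; the generator derives per-stage seeds from
it by fixed offsets so individual artifacts are independently
reproducible.

## Known limitations

- Cross-database gene-identifier mapping is out of scope: identifiers
  are opaque strings, and merging interaction sources is the caller's
  responsibility.
- Omega (Ka/Ks) values are consumed from a table; codon-model estimation
  belongs to dedicated phylogenetics software.
- The 6 × 6 group matrices compress ~45M gene pairs into 21 averages;
  conclusions at the group level do not license gene-level claims.
- The hub Kruskal–Wallis H grows with hub count and rewiring reps;
  compare p-values and directions across datasets, not H magnitudes.
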