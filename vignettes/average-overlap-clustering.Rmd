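---
title: "Comparing and merging single-cell clusters with average overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing and merging single-cell clusters with average overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoclust)
```

## The problem

Unsupervised community detection (Leiden, Louvain) on scRNA-seq data is run
at a single global resolution, while real tissues contain both broad,
well-separated populations and subtle subpopulations. Over-clustering
splits homogeneous populations into several clusters; under-clustering
hides small ones. Deciding which de novo clusters represent the same cell
identity is usually done by eyeballing marker genes.

`aoclust` makes that comparison quantitative. Each cluster is summarized
not by its expression vector but by its *ranking* of differentially
expressed genes, and cluster similarity is the **average overlap (AO)** of
two rankings — a top-weighted rank-similarity statistic. Clusters that
agree on which genes are *most* discriminating are treated as similar even
when their absolute expression profiles are nearly collinear with everyone
else's, which is exactly the regime (closely related T-cell-like subsets)
where correlation-based comparisons become unstable.

## The statistic

For two ranked lists $a, b$ of the same $N$ genes, the overlap at depth
$d$ is

$$ O_d = \frac{|\,\mathrm{top}_d(a) \cap \mathrm{top}_d(b)\,|}{d}, $$

and the average overlap is the unweighted mean over **all** depths,

$$ \mathrm{AO}(a,b) = \frac{1}{N}\sum_{d=1}^{N} O_d . $$

A gene near the head of both lists participates in almost every depth, so
discordance at the top costs more than discordance at the tail: a single
adjacent swap at position $i$ of an otherwise identical list costs exactly
$1/(N i)$ (a property the test suite asserts for all $N \le 10$). AO is 1
iff the lists are element-wise identical and 0 iff they share no content;
$1 - \mathrm{AO}$ is the distance used for clustering. We deliberately use
the plain unweighted mean over depths $1..N$ — no rank-biased geometric
weighting and no truncation parameter — because the lists compared here
are finite and of equal length by construction.

Equal lengths are enforced rather than truncated to the shorter list:
every comparison in the workflow happens on the global marker-gene union,
so unequal lengths can only indicate a caller error.

### The shuffle null and AO z-scores

Over uniformly random permutation pairs of an $N$-element universe, AO has
expectation $(N+1)/(2N)$ (exactly; verified exhaustively for $N \le 5$) —
about 0.5 for long lists — and is approximately normal.
`null_distribution(n, m_shuffles, seed)` estimates the null mean and sd
from `m_shuffles = 1000` seeded permutation pairs (exhaustively for
$N \le 7$), and `ao_zscore()` expresses an observed AO in null standard
deviations. Shuffled same-gene lists score 0 on average; similarly ranked
lists score increasingly positive; anti-similar lists negative.

Two choices the definition leaves open, fixed here: each null draw
permutes *both* lists independently (equivalent in distribution to
permuting one list against a fixed reference, since AO depends only on the
relative ordering); and one null is built per analysis for the single list
length in play — the global-union length — never pooled across lengths.
The null is content-agnostic: it depends on $N$ only. For $N = 1$ the null
sd is undefined and z-scores are refused explicitly.

## From counts to rankings

`rank_genes_vs_rest()` performs the standard one-vs-rest two-sample
Wilcoxon rank-sum test per gene on log-normalized expression (library-size
scaling to the median library, then `log1p`), using the normal
approximation with tie correction and no continuity correction. "Ranked by
significance" needs a total order, so the sort key is: signed enrichment
z (over-expression first) descending, then $|\log_2$ fold change$|$
descending, then gene identifier. Log fold changes use the scanpy-style
convention $\log_2\big((\mathrm{expm1}(\bar x_{in}) + 10^{-9}) /
(\mathrm{expm1}(\bar x_{rest}) + 10^{-9})\big)$. One-sided p-values are
reported with Benjamini–Hochberg adjustment for display only — the ranking
is invariant to any monotone adjustment. Upstream feature selection,
normalization refinements and QC (mitochondrial/ribosomal filters, doublet
removal) are out of scope: callers pass a pre-filtered count matrix.

Each cluster's top-$k$ genes (default $k = 25$) are pooled into the global
marker set, and each cluster re-ranks that union by its own full DE
ordering (`rankings_on_union()`), giving equal-length lists over a shared
universe — the input to `pairwise_ao()`.

## Trees and merging

`linkage_from_ao()` agglomerates clusters on $1-\mathrm{AO}$. The default
linkage is average (UPGMA): no linkage is canonical for
cluster-of-clusters trees, and UPGMA is the common, monotone choice;
complete and single linkage are available. The implementation is an
explicit $O(K^3)$ agglomeration so that its tie rule is fully specified:
among tied minimum distances the pair whose sorted labels are
lexicographically smallest merges first, making trees reproducible across
platforms. (K is the number of clusters — tens, not thousands — so cubic
cost is irrelevant.)

`merge_to_k()` follows the fixed tree's merge order until the target group
count is reached. Because all z-scores share one null, "merge the pair
with the highest AO z-score" and "merge the smallest $1-\mathrm{AO}$
distance" coincide; the merge log reports both. Re-computing markers and
AO after every merge (`merge_with_recompute()`) is available as an opt-in
variant; on well-separated data the two agree (tested), and the fixed-tree
default keeps results a pure function of one marker analysis.

## The evaluation harness

`agreement_metrics()` implements ARI (pair counting, chance-adjusted), AMI
(arithmetic-mean normalization; expected mutual information under the
exact hypergeometric permutation model) and the Fowlkes–Mallows score.
`average_cluster_purity()` is cell-weighted by default — then it equals
the overall fraction of cells whose cluster's majority truth label matches
their own — with an unweighted per-cluster mean behind a flag, since
"average cluster purity" is ambiguous. `centroid_expression_distance()`
standardizes each gene to zero mean/unit variance across cells (dropping
zero-variance genes with a warning), matches each merged cluster to its
majority truth population (ties to the larger population, then
lexicographic) and reports Euclidean centroid distances.

`baseline_distance_matrix()` provides the comparison metrics: Pearson,
Spearman, Kendall and Euclidean distances on cluster-mean marker
expression or on cluster means of the first 50 principal components of
standardized expression, the unranked `direct_overlap` baseline
$1 - |\mathrm{top}_k(a) \cap \mathrm{top}_k(b)|/k$, and AO itself.
Correlations become distances as $1 - r$ (not $1 - |r|$): anticorrelated
clusters should be maximally distant.

`score_marker_set_on_reference()` supports annotation against sorted bulk
reference populations: each reference gene is z-scored across populations
(per gene, not per population; constant rows are dropped with a warning)
and a marker set's z-values are combined per population with Stouffer's
method, $\sum z_i / \sqrt{n}$.

## The synthetic-data generator

`simulate_dataset()` draws baseline gene abundances log-normal, per-cell
library sizes log-normal (mean 5000, CV 0.3 by default), and counts
negative-binomial (dispersion 0.3) — the standard noise model under which
Wilcoxon ranking behaves as the method assumes. Each population carries a
planted marker block whose means are multiplied by
$e^{\mathrm{lfc}}$. Sibling pairs share a fraction of their blocks, with
independent Gaussian jitter on the shared markers' log effects in each
sibling, so sibling rankings overlap without coinciding — similarity is
induced through exactly the quantity the method measures (shared marker
genes with similar rankings), not through cell mixing.
`split_clusters()` randomly halves named populations into pseudo-clusters
to emulate over-clustering.

Two frozen scenarios define the package's test bed:

* the **default scenario** (`simulation_config()`): 5 populations × 200
  cells, 2000 genes, 40 markers each, lfc = 2 (≈7.4-fold), sibling pairs
  (1,2) and (3,4) sharing 80% of markers with jitter sd 0.5, populations
  1 and 3 split. Well-separated; the end-to-end recovery test demands
  merging back to 5 groups with ARI = 1 in at least 18 of 20 seeds.
* the **homogeneous sibling scenario** (`sibling_scenario()`): 5
  populations × 40 cells, 1500 genes, lfc = 0.3 (≈1.35-fold), dispersion
  2, shallow libraries (1200), 90% marker sharing with jitter sd 0.8,
  populations 1 and 3 split. Deliberately hard, emulating closely related
  T-cell-like subsets: here AO-guided merging stays accurate and stable
  while correlation/Euclidean baselines degrade and the unranked direct
  overlap collapses when only 5 markers per cluster are used — the
  qualitative benchmark shape the acceptance tests assert over 20 seeds.

What the generator does **not** emulate: batch effects, doublets, ambient
RNA, cell-cycle structure, zero-inflation beyond the NB, or surface
protein channels. Passing tests therefore show that the statistics and
the workflow behave correctly under the assumed noise model, not that
AO-guided merging is superior on any particular real tissue.

## Numerical choices and degenerate inputs

Overlap counts are integers accumulated exactly and divided once per
depth; deterministic expectations are tested at tolerance $10^{-12}$.
Every stochastic routine takes an explicit seed and restores the caller's
RNG stream. Rankings of length 1 have AO $\in \{0,1\}$ but no z-score
(null sd undefined — an explicit error). Cells with zero total counts are
an error naming the cell; all-zero genes normalize to zero; zero-variance
genes are excluded from standardization with a warning.

Problem sizes throughout the test suite (up to 1000 cells × 2000 genes,
20 seeds per property) were chosen so the whole suite documents the
method at laptop scale; the properties asserted are scale-free.

## Limitations

* AO compares rankings over the *union* of top markers; two clusters with
  genuinely disjoint biology still share the union's tail ordering noise,
  which is why significance is judged through the shuffle null rather
  than raw AO.
* The null is content-agnostic; it does not model correlation between
  marker statistics induced by shared cells (one-vs-rest contrasts of the
  same dataset are not independent). z-scores are calibration aids, not
  exact p-values.
* `merge_to_k` requires the caller to choose the target group count (in
  benchmarks, the number of ground-truth labels); no automatic cut
  selection is provided.
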