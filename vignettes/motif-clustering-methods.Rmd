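---
title: "Clustering binding motifs with a genetic k-medoids algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering binding motifs with a genetic k-medoids algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifclust)
```

## The problem

Transcription-factor binding motifs are summarised as position weight
matrices (PWMs): one probability distribution over A, C, G, T per binding
position. Motif databases are redundant — many factors from one structural
family (bHLH, bZIP, C2H2 zinc fingers, forkhead, ...) bind near-identical
sites — so a recurring task is to group similar PWMs and summarise each
group by a familial binding profile (FBP), an averaged matrix describing
the family's shared specificity.

The classical route is hierarchical: align all motif pairs, build a guide
tree, and cut it. That inherits the *frozen sub-alignment* artifact — an
early bad merge can never be revisited — and needs a separate criterion to
pick the number of clusters. `motifclust` instead treats the problem as a
single combinatorial optimisation: motifs are embedded alignment-free as
k-mer frequency vectors, compared once by cosine distance, and a genetic
algorithm searches over both the number of clusters **K** and the medoid
set simultaneously, scoring candidates with the mean silhouette width.

## The model

**Information-content trimming.** Each PWM column scores
$I = 2 + \sum_j p_j \log_2 p_j$ bits (0 for the uniform column, 2 for a
pure one). Before feature extraction the two motif ends are trimmed: while
the lower-IC end column is below the threshold (default 0.3 bits) and the
motif is longer than the minimum core (default 4 columns), that end column
is removed, ties going to the left end. Trimming is deterministic, never
removes interior columns, and never shortens a motif below
`min(length, min_core)`.

**k-mer frequency vectors.** A trimmed motif of length $\ell$ defines, for
every word $w$ of length $k$ (default $k = 4$, hence a $4^k = 256$-vector)
the expected number of occurrences of $w$ across its $\ell - k + 1$
windows under the per-position independence model:
$\mathrm{KFV}(w) = \sum_i \prod_{j} p_{i+j,\,w_j}$.
Because databases record motifs on an arbitrary strand, the default policy
adds the forward vector of the reverse complement, which makes the
embedding strand-invariant and gives the exact mass identity
$\sum_w \mathrm{KFV}(w) = 2(\ell - k + 1)$ — a cheap, strong internal
check the test-suite exercises. A forward-only policy is exposed for users
whose motifs are consistently oriented.

**Distance.** Motif dissimilarity is the cosine distance
$d(a, b) = 1 - a \cdot b / (\lVert a\rVert\,\lVert b\rVert)$ between
KFVs, in $[0, 1]$ for nonnegative vectors. The $n \times n$ matrix is
computed once and never changes during clustering.

**Genetic k-medoids search.** A candidate solution is a pair
(K, medoid vector), K in $\{2, \dots, n-1\}$. Evaluating a candidate runs
*one* greedy swap pass of k-medoids (each medoid slot in ascending index
order, each non-medoid in ascending index order, a swap committed
immediately whenever it strictly lowers the total distance-to-medoid cost),
then scores the induced assignment with the mean silhouette
$s(i) = (b_i - a_i) / \max(a_i, b_i)$, where $a_i$ is the mean distance to
the motif's own cluster and $b_i$ the smallest mean distance to another
cluster; members of singleton clusters score 0 (the classical convention,
which keeps every candidate scoreable). The single pass buys local-search
quality without the cost of running PAM to convergence.

The population evolves steady-state: per generation, the worst
`ceiling(replace_fraction * pop_size)` individuals (5 of 100 at the
defaults) are replaced by offspring bred by linear-ranking roulette
selection, uniform crossover restricted to parents with equal K (a parent
with a unique K is cloned instead), a K-perturbing mutation (add or drop
one cluster), and duplicate-medoid repair. When the population's diversity
collapses — more than `diversity_threshold` (default 0.8) of individuals
share one K — the mutation rate is temporarily boosted. The best candidate
ever evaluated is returned.

## Parameters

| parameter | default | units / range | role |
|---|---|---|---|
| `ic_threshold` | 0.3 | bits | edge-trimming cutoff |
| `min_core` | 4 | columns | shortest trimmed motif |
| `k` | 4 | letters | KFV word length |
| `strand_policy` | both | both / forward | strand invariance of the embedding |
| `pseudocount` | 0 | counts | count normalisation (published matrices used as-is) |
| `pop_size` | 100 | individuals | GA population |
| `generations` | 300 | iterations | GA length |
| `mutation_rate` | 0.05 | probability | base K-perturbation rate |
| `boosted_mutation_rate` | 0.25 | probability | rate while diversity exceeds the threshold |
| `diversity_threshold` | 0.8 | fraction | converged-population trigger |
| `replace_fraction` | 0.05 | fraction | steady-state replacement |
| `selective_pressure` | 1.5 | (1, 2] | linear-ranking bias |
| `coverage_fraction` | 0.5 | fraction | FBP edge-column retention |

The trimming, word-length, population, generation, mutation, diversity and
replacement defaults are the published protocol values. The boosted
mutation rate (5x base), the selective pressure (the midpoint of the
standard linear-ranking range) and the FBP coverage fraction are engine
choices this package documents and exposes rather than hard-codes; the
published description names these knobs without fixing them.

## Familial binding profiles

Each cluster is summarised by star-aligning every member to the cluster
medoid: ungapped sliding in both orientations, scored by the sum of
per-column Pearson correlations between probability columns (zero-variance
columns contribute 0), requiring at least `min_overlap = 4` shared
columns; ties prefer the smaller absolute offset, then the forward
orientation. TFBS motifs are short and effectively ungapped, so gapped
alignment buys nothing here, and anchoring on the medoid (rather than a
progressive multiple alignment) avoids re-introducing the tree-order
dependence the method is designed to escape. The FBP column is the
arithmetic mean over covering members; edge columns covered by fewer than
`coverage_fraction` of members are dropped (`>=` keeps the boundary case),
interior low-coverage columns are kept but flagged, so the profile stays
contiguous.

Held-out motifs are re-classified by the same KFV/cosine metric against
the trimmed FBP matrices — the metric used for clustering, so
cross-validation tests the pipeline that produced the clusters. In
leave-one-out cross-validation every motif of a non-singleton cluster is
removed in turn and all FBPs are rebuilt from the remaining members; when
the removed motif was the medoid, the fold re-anchors on the remaining
member with the smallest summed within-cluster distance (a recomputed
medoid — the natural choice; the published protocol does not specify one).

## Synthetic data and what the tests show

`planted_families()` generates ground-truth fixtures: per family a seed
motif of sharply peaked random columns (Dirichlet(0.2) draws), members
perturbed around the seed column-wise with a symmetric concentration
parameter (Dirichlet centred on the seed column; higher = tighter;
infinity copies the seed), optional shifts padded with uniform columns,
and rejection sampling until all pairwise seed KFV distances exceed a
separation floor (default 0.5, the midpoint of the cosine range — distinct
TF families in real collections typically sit this far apart). The noise
protocol (`noise_series()`) blends every motif with a random motif sampled
column-wise from the pool of all input columns, at signal fractions 0.9
down to 0.5, ten replicates each by default.

The generator emulates the geometry that matters to the method — tight
within-family KFV neighbourhoods, well-separated family centroids,
degradation under convex noise — but not several features of real
collections: unequal family sizes and motif lengths, inter-family
similarity gradients (e.g. families sharing submotifs), dinucleotide
dependence within sites, and curation noise in class labels. Passing the
recovery tests therefore demonstrates the engine's correctness and its
behaviour under controlled degradation, not its accuracy on any particular
database.

Test and acceptance problem sizes are deliberately desk-scale: 3 families
of 8 members (n = 24) for recovery, LOOCV and the noise curve, and an
unbalanced 3+3+2 toy (n = 8) where *every* (K, medoid-set) partition can
be enumerated and the engine's returned fitness checked against the true
optimum.

## Numerical and degenerate-case choices

- Ties everywhere break to the lowest index (nearest-medoid assignment,
  classification) or to the left/forward (trimming, alignment), making
  every run a pure function of (input, seed).
- Swaps are committed only on *strict* cost decrease, so 1-swap-optimal
  configurations pass through the local search unchanged.
- $0 \log 0 = 0$ in the information content; IC is clipped to $[0, 2]$
  against rounding.
- Cosine distances are clipped to $[0, 1]$ and the matrix symmetrised
  against floating-point asymmetry; a zero KFV (impossible for a valid
  PWM) is an error, not a NaN.
- A single seeded RNG drives initialisation, selection, crossover,
  mutation and repair; derived seeds (master + run index) make
  multi-run studies reproducible.
- `n < 4` is rejected: K must range over $\{2,\dots,n-1\}$ to be
  meaningful.

## Known limitations

- The local search optimises distance-to-medoid cost while the fitness is
  silhouette. On clusterable data the two agree; on unstructured (noise
  only) distance matrices the swap pass can steer candidates away from
  silhouette-optimal but cost-unstable medoid sets, so the returned
  fitness can sit below the unconstrained enumeration optimum. This is a
  property of the one-round design, inherited deliberately; the enumeration
  equality is asserted on clusterable toys.
- Published benchmark figures for this family of methods depend on the
  licensed TRANSFAC and versioned JASPAR collections; this package ships
  only synthetic fixtures, so its acceptance checks are property-based
  (recovery, oracle equality, conservation laws, monotone degradation)
  rather than reproductions of database-specific numbers.
- Runtime scales as $O(n^2)$ per fitness evaluation (silhouette) on top of
  the swap pass; the engine is intended for motif-collection sizes
  (tens to a few hundred), not thousands of objects.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
pf <- planted_families(3, 8, motif_length = 10, concentration = 50)
D <- build_distance_matrix(pf$motifs)
sol <- ga_cluster(D, ga_config(seed = 1))
sol
head(cluster_assignments(sol))
homogeneity_report(sol, pf$labels)$weighted_purity
loocv_stability(pf$motifs, sol, D)$accuracy
```
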