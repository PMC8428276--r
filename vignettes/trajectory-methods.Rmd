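---
title: "Constrained trajectory trees: models, parameters and design choices"
author: "trajtree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained trajectory trees: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajtree)
```

# The problem and the approach

Single-cell profiles sample a developmental process as a static cloud of
cells. Trajectory inference reconstructs the process as a tree: a root
population of progenitors, internal transitions, and terminal fates at the
leaves. Fully unsupervised tree builders (minimum spanning trees or
principal graphs over a reduced space) struggle exactly where biology is
most interesting — rare terminal populations that clustering absorbs into
neighbours, and distinct fates whose end states are transcriptionally
adjacent so that an MST happily connects them. `trajtree` instead asks the
analyst for the two facts they usually know — which cluster is the root and
which clusters are terminal fates — and builds the tree under those
constraints. Everything else (preprocessing, clustering, embedding,
pseudotime, per-branch expression trends) is standard scaffolding around
that constrained construction.

# Preprocessing and dimension reduction

Counts are filtered (cells below a detected-feature floor first, then
features below a cell-support floor; this order is the common single-cell
convention), library-size normalised to a fixed per-cell total
(`scaleFactor`, default 10^4) and log1p-transformed. Variable features are
ranked by a variance-stabilised dispersion: the residual of log-variance
against a lowess fit on log-mean, so that selection is not dominated by the
mean–variance trend. Scaling centres each feature, divides by the sample
standard deviation and clips at ±10 by default (clipping bounds the
influence of outlier cells; zero-variance features map to zero). PCA is
computed on the scaled matrix; the per-component sign is fixed so the
largest-magnitude loading is positive, which makes embeddings and all
downstream trees reproducible across platforms. Accessibility z-score
matrices (`layer = "zscore"`) skip normalisation and scaling and feed PCA
directly.

The number of retained components can be chosen by the elbow of the scree
curve (maximum distance to the first–last chord) or by a cumulative
explained-variance target; both are suggestions the user can override.

# Clustering and the role of k

Cells are joined to their k nearest neighbours in the selected-PC space and
the directed relation is symmetrised by union — union rather than mutual
symmetrisation keeps sparse, rare populations connected to the graph.
Communities are found by Leiden (default; modularity objective, resolution
1) or Louvain on the unweighted topology; the edge weights (Euclidean
distances) are kept for the later distance computations, not for community
detection. Cluster ids are relabelled 1..C by decreasing size.

k is the main dial: `sweepK` re-clusters for k = 4…20 and reports the
cluster counts. Fewer neighbours give more, finer clusters; a rare terminal
type only becomes its own cluster (and hence can be declared a leaf) at
small k. The package deliberately leaves the choice to the user, who should
compare cluster counts with the number of expected cell types.

# Landmark ISOMAP

For visualisation the kNN graph is embedded in 3-D by landmark ISOMAP. The
landmarks are per-cluster *graph hubs* — the cells with the most
within-cluster kNN connections — which anchor every cluster in the
embedding at a well-connected, central cell. Geodesics are computed as one
single-source Dijkstra search per landmark (landmark-first ordering; the
searches are independent, so they parallelise trivially and their results
are identical to serial execution). Classical MDS on the double-centred
squared landmark–landmark distances gives landmark coordinates; the
remaining cells are placed by the standard triangulation formula
(pseudo-inverse projection of their squared-distance vectors against the
landmark column means). Negative eigenvalues arising from non-Euclidean
geodesic matrices are truncated at zero. If the kNN graph is disconnected,
components are first bridged by repeatedly adding the shortest
inter-component Euclidean edge — L-ISOMAP needs finite distances, and a
single shortest bridge distorts geometry least.

The default of one hub per cluster is raised automatically until at least
`max(10, n_clusters)` landmarks exist, which keeps the triangulation
well-posed.

# The constrained spanning tree

Cluster-level distances come in two flavours. The *neighbour distance*
between two clusters is the mean length of the cell-level kNN edges joining
them (NA when no edge joins them); the *graph distance* is the all-pairs
shortest-path closure over the neighbour distances. NA entries are treated
as absent (infinite) edges.

The tree is then built in three steps:

1. **Backbone.** A kNN graph over the non-leaf clusters with the graph
   distance as metric, the neighbour size grown from 3 until the backbone
   is connected (capped at the non-leaf count minus one; reaching the cap
   while disconnected is an error naming the components).
2. **Leaf groups.** Each group's *connector* is the member with the
   smallest graph distance to any non-leaf cluster, and it is linked to
   that nearest non-leaf cluster. Group structures: `parallel` links every
   member independently to the attachment cluster; `linear` chains members
   by increasing graph distance from the attachment (connector first);
   `mst` joins members by their internal minimum spanning tree, attached
   via the connector. Members unreachable in graph distance fall back to
   centroid Euclidean distance with a warning.
3. **Paths.** The tree is the union of shortest paths from the root to
   every leaf cluster, with leaf clusters acting as path sinks so they stay
   terminal. Non-leaf clusters on no path are merged in afterwards, each
   attached to its nearest on-tree non-leaf cluster and flagged with
   provenance `attached_isolated`.

Two numerical choices here deserve explanation, because they were forced by
observed failure modes rather than taste:

* **Tie-breaking in Dijkstra prefers the deepest predecessor.** The graph
  distance matrix is a metric closure: along a chain of clusters, a direct
  edge and the hop-by-hop path cost *exactly* the same. Under a naive
  (e.g. lexicographic) tie-break the shortest-path tree collapses onto
  star-like hubs, skipping intermediate clusters — which both merges
  distinct bifurcations and strands the skipped clusters as isolated
  pendants. Preferring, among equal-cost predecessors, the one furthest
  from the root (then the smallest id, for determinism) reconstructs the
  chains.
* **Isolated clusters never attach to declared leaves.** A declared leaf
  must end with degree 1; the merged-in extras attach to the nearest
  on-tree *non-leaf* cluster. They are also the reason a validation report
  exists: a pendant non-leaf cluster violates the rule that internal
  clusters should have degree at least two, so such nodes are listed there
  rather than silently accepted or forcibly rewired.

`spanningTree(..., attachMode = "path")` offers an alternative attachment
rule in which each leaf joins the routing graph through all of its direct
neighbour edges and the root-side shortest path picks the attachment; the
default `"nearest"` follows the classical nearest-non-leaf rule, which in
our benchmarks resolves junctions slightly better.

An unrooted `exploratoryMST` over the graph distances is available when no
prior knowledge exists.

## Counting bifurcations and branches

A *bifurcation* is a node with at least two children in the rooted tree —
including a root with two children, whose undirected degree is only 2 but
which is plainly a split point of the trajectory. A *branch* is an edge of
the tree after collapsing every non-root chain node (one parent, one
child); the root is never collapsed. By default both counts describe the
full tree as drawn; `trajectoryOnly = TRUE` first removes
`attached_isolated` side nodes, counting only the root-to-leaf system.

# Pseudotime

Each cell is assigned to one of the tree edges incident to its own
cluster: the cell is orthogonally projected onto the segment between the
two endpoint centroids in the same PC space used for clustering, the
offset is clamped to [0, 1], and the candidate with the smallest
perpendicular residual wins. Pseudotime is `depth(parent) + offset ×
length(edge)`; a root-cluster cell projecting at offset 0 has pseudotime
exactly 0. The selection rule (minimal perpendicular residual after
clamping) and the projection space are implementation choices; the
candidate set — edges incident to the cell's own cluster — is the defining
constraint. Exports include a per-branch [0, 1]-normalised column next to
the raw cumulative lengths.

# Principal trend analysis

Expression along a branch is noisy per cell, so cells are first averaged
into contiguous equal-count pseudotime bins (default `min(100, n_cells)`
bins; the remainder is spread over the leading bins). The genes × bins
matrix X is then decomposed by sequentially extracting sparse-smooth
rank-one components `X ≈ d · u vᵀ`:

* `u` (per-gene **scores**) is updated by soft-thresholding `X v` at
  `lambdaSparse` and renormalising — most gene scores are exactly zero, and
  a score's sign is the direction of the gene's contribution to the trend;
* `v` (the per-bin **trend**) is updated by solving
  `(I + lambdaSmooth · D₂ᵀD₂) v = Xᵀ u` with `D₂` the second-difference
  operator, then renormalising — a discrete smoothing spline on the bin
  axis;
* `d = uᵀ X v`; the alternation starts from the leading singular pair and
  stops when the relative change in `d` falls below `tol`.

Ranks are extracted by deflation (`X ← X − d u vᵀ`); three ranks are the
default and usually capture the main patterns. The trend sign is fixed so
the endpoint difference is nonnegative, flipping scores with it. Default
penalties are data-driven: `lambdaSmooth` by generalized cross-validation
on the bin axis, `lambdaSparse` as a Bonferroni-style support threshold
`sigma · qnorm(1 − 0.05 / (2 genes))` with `sigma` the MAD of the rank-one
SVD residual — under Gaussian noise no pure-noise gene enters the support
with probability about 0.95. A `lambdaSparse` large enough to zero all
scores yields a flagged null trend rather than an error. Whether multiple
ranks should be estimated jointly rather than by deflation is not settled;
deflation is simple, monotone in residual norm, and what this package does.

# The lineage simulator

`simulateLineage` generates tree-structured counts with full ground truth.
Branch segments carry per-program activities `W_k(t)` following Gaussian
random walks along pseudotime; each child branch continues from its
parent's endpoint and then diverges independently — divergence between
sibling branches is exactly accumulated walk variance. Gene means are
`base_g · exp(Σ_k H_gk W_k(t))` with sparse nonnegative gene–program
weights (1–3 programs per gene, Gamma weights), renormalised per cell so
that total depth is `library_factor × totalCounts` with
`library_factor ~ LogNormal(0, libsizeSigma)`. Counts are negative
binomial with size `dispersion` (variance `mu + mu²/dispersion`; the
default size 10 makes variance about twice the mean at mean 10; `Inf`
gives Poisson). Cells are placed uniformly along their branch.

Calibration of the defaults, chosen once as a realistic operating point:

* `programWalkSd = 0.11` per step with 40-step branches keeps the
  accumulated log-drift over the deepest seven-segment paths near 2 per
  program, so fold changes stay in a realistic range and no single gene
  captures a cell's whole library (a stronger walk does exactly that once
  `exp()` compounds, collapsing all late branches into a one-gene
  signature). A mean-reverting variant (`programTau < Inf`) is available
  but not the default: reversion bounds the spread for very deep trees at
  the cost of tree-like geometry, since branches then wander around a
  common centre instead of diverging.
* `nPrograms = 20` for the benchmark presets: program space is where
  branches decorrelate, and too few dimensions let unrelated branches
  re-approach by chance.
* `totalCounts = 2000` over 500 genes matches typical droplet-data depth,
  and at k = 12 the resulting Leiden cluster counts sit near the number of
  true branch segments — the property a practitioner checks when choosing
  a clustering.

Two presets fix the evaluation designs: `rare_lineage` — seven types A–G
on a three-bifurcation tree (A the root; E a 15-cell rare leaf, 0.78 % of
1,915 cells; 300 cells each in A–D, 350 in F and G); the cartoon topology
is A→(B, C), B→(D, E), D→(F, G). `six_bifurcations` — a caterpillar of six
successive splits: 13 branch segments, 7 leaves, 100 cells per segment,
1,300 cells × 500 genes, `libsizeSigma = 0.7`.

What the simulator does *not* emulate: dropout beyond NB sampling, doublets,
batch effects, cell-cycle structure, or non-uniform cell density along
branches. Passing the recovery tests therefore demonstrates the pipeline's
correctness on clean tree-structured data, not robustness to every real
artefact.

# What the benchmark recovery does and does not show

On the `six_bifurcations` preset with 10 PCs, k = 12 and the seven terminal
clusters declared as singleton leaf groups, the recovered trees have 5–6
bifurcations (majority 6 over typical seed sets) and 12–15 branches.
The two residual imperfections are instructive:

* Adjacent junctions occasionally merge: when one cluster spans two
  consecutive split regions, two bifurcations appear as a single node with
  three children. This is a resolution effect of clustering, not of the
  tree construction.
* Terminal branches occasionally split into two clusters; the fragment not
  declared as the leaf ends up off every root-to-leaf path and is merged
  in as an `attached_isolated` pendant, inflating the branch count. The
  validation report names these nodes, and `trajectoryOnly = TRUE`
  counting excludes them.

# Problem sizes used in the test suite

Unit tests run on instances small enough for exhaustive oracles: full
Floyd–Warshall on ≤ 30-node graphs, spanning-tree enumeration via Prüfer
sequences on ≤ 7 clusters, all set partitions of 9 nodes for the
modularity check, 60-point curves for the ISOMAP equivalence, and 50 × 20
planted models for trend recovery. The end-to-end recovery checks run the
full pipeline on the 1,300-cell preset across five seeds, about two
seconds per seed.

# Known limitations

* Tree topologies only: loops (cell cycle) and convergent fates that
  genuinely rejoin are out of scope.
* The constrained tree is only as good as the clustering it is given;
  wrongly declared leaves produce a valid but wrong tree.
* Pseudotime is piecewise-linear along centroid segments, coarser than
  principal-curve refinements.
* The trend decomposition assumes an additive sparse-smooth structure per
  branch and does not test differential expression.
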