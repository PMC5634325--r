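---
title: "clustviz: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clustviz: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustviz)
```

## What the engine computes

`clustviz` is the back end of a clustered-heatmap visualization: it takes a
labeled numeric matrix (genes, PTMs, or single cells by samples or markers),
whose row and column labels may carry category tracks, and produces a single
self-contained document with everything a front end needs to render and
re-order a heatmap without recomputation:

* hierarchical clustering of both axes,
* flat group assignments at ten dendrogram slice levels per axis,
* rank orders (initial, alphabetical, sum, variance, cluster),
* pre-computed row-filtered "views" at a ladder of retention fractions,
* row and column similarity matrices, and
* category tracks propagated onto the nodes.

Cluster-category enrichment and K-means downsampling (for single-cell scale
inputs) are computed by the same package.

## Clustering model

Distances between vectors default to cosine distance,
$d(u, v) = 1 - \frac{u \cdot v}{\lVert u \rVert \lVert v \rVert}$,
and trees are built by average linkage (UPGMA): at each step the pair of
clusters $A, B$ minimizing the mean inter-cluster distance
$\frac{1}{|A||B|}\sum_{a \in A, b \in B} d(a,b)$ is merged. Both choices are
configurable (`euclidean`/`correlation`, `single`/`complete`). Correlation
distance is implemented as cosine distance of centered vectors, so both share
one code path and one degenerate-vector policy.

Three numerical conventions make results exactly reproducible:

* **Tie-breaking.** Among cluster pairs at the minimal distance, the pair
  whose smallest original leaf index is lowest wins (then the second index).
  Generic linkage libraries leave this unspecified, which is why the
  agglomeration loop is implemented here rather than delegated; `stats::hclust`
  is used in the test suite as an independent oracle for heights, alongside a
  brute-force agglomerator that recomputes cluster distances from the raw
  distance matrix at every step.
* **Zero-norm vectors** have no direction, so cosine distance to them is
  undefined. The declared policy: distance 1 to any nonzero vector, 0 to
  another zero-norm vector. After row Z-scoring, a constant row becomes a zero
  row, so this keeps constant features clusterable instead of poisoning the
  matrix with NaN.
* **Missing entries** are imputed transiently to the vector mean at
  distance-computation time only (equivalently 0 after Z-scoring); the stored
  matrix keeps its missing values. Rows that survive the missing-value filter
  retain at most a tolerated number of holes, and the vector mean is the
  least-informative fill for an angular metric.

### Leaf order and dendrogram slices

The display order of leaves is fixed by a deterministic rule: at every merge
the subtree containing the smallest original index is placed first. No
optimal-leaf-ordering heuristic is applied — the order is a tie-break, not a
quality claim.

Flat groups are obtained by cutting the tree at thresholds expressed as
fractions of the maximum merge height; the default is ten evenly spaced
slices $0.1, 0.2, \ldots, 1.0$, matching a ten-position slider. A merge is
applied when its height is at or below the cut, so the fraction-1.0 slice is
always a single group. Because UPGMA heights are non-decreasing, the merges
below any cut are a prefix of the merge sequence; group assignments at finer
levels therefore refine coarser levels by construction, and group ids are
numbered by the leaf order of each group's first member (id 1 is the
left-most group on screen). Heights are never re-scaled: fractional
thresholds make documents comparable across datasets of different absolute
scale.

## Normalization and filtering

* **Z-score**: per vector, $(v - \bar v)/s$ over non-missing entries, with
  `ddof = 1` (sample sd) by default, matching the dataframe conventions of
  the surrounding ecosystem. Constant vectors map to all zeros rather than
  NaN so they remain clusterable. Variance filters use the same `ddof`.
* **Quantile normalization** forces all vectors along an axis onto one
  distribution: the per-rank mean of the sorted vectors (ties receive the
  mean of their tied reference values). This is delegated to
  `limma::normalizeQuantiles`, the field-standard implementation; a per-rank
  *median* reference is available as a small local variant. By default the
  function refuses matrices with missing values, since ranks are ambiguous
  there; the PTM workflow — whose stage order requires quantile
  normalization *before* the missing-value filter — opts into
  `allow_missing = TRUE`, which maps each vector's non-missing entries onto
  the reference by interpolated rank (limma's behavior) and leaves the holes
  in place.
* **Top-N filters** (`sum`, `variance`, `abs-sum`) keep exactly
  `min(N, axis length)` vectors, clamping with a warning; fractional
  requests keep `ceiling(f * length)`. Ties break by original position
  (earlier wins) and survivors keep their original relative order, so
  filtering is a stable selection, not a re-sort.
* **Missing-value filter** removes vectors with strictly more than
  `max_missing` holes; the PTM workflow uses the tolerance of 7.
* **Ratio to reference** divides each sample column by its mapped
  per-run reference column and drops the references; division by a zero or
  missing reference entry yields a missing value rather than an infinity.

## K-means downsampling

Single-cell matrices are reduced to `k` centroids before clustering. Two
variants share the assignment code:

* **Lloyd** (default): full-batch iterations; on convergence each centroid
  is exactly the mean of its members.
* **Mini-batch** (recommended above roughly 50,000 rows): per-center
  learning-rate updates on random batches of 1,024, followed by one full
  assignment pass; final centroids are recomputed as member means of that
  assignment so the size and majority tracks are exact.

The cluster count contract is exact: clusters that empty out are re-seeded
from the points currently farthest from their centroid and assignment is
repeated, so the output always has `k` non-empty clusters. Assignment ties
go to the lowest cluster id. All randomness flows from one explicit seed
scoped with `withr::with_seed`, so runs are bit-reproducible and never
disturb the caller's RNG state.

Category propagation: every categorical row track yields a
`Majority-<name>` track holding the modal value per cluster (ties break to
the lexicographically smallest value, for determinism); numeric tracks
propagate as per-cluster means; cluster sizes are attached as the numeric
`number in clust` track, whose entries always sum to the input row count.
`random_subsample` draws a fixed number of rows per group of a categorical
track, without replacement, preserving original order; `transfer_labels`
maps cluster-level annotations back onto observations.

## Category enrichment

For a group of size $n$ at a chosen slice level and a category value with
in-group count $k$ and background proportion $p_0$, the enrichment p-value
is the exact upper binomial tail $P(X \ge k)$, $X \sim \mathrm{Bin}(n, p_0)$,
computed via `stats::pbinom`. The binomial *proportion* test family admits a
normal approximation; the exact tail was chosen because dendrogram clusters
are routinely tiny (a handful of leaves) where the z-test is unreliable; the
z-statistic $\frac{k/n - p_0}{\sqrt{p_0 (1-p_0)/n}}$ is reported alongside
for reference. Conventions: $k = 0$ returns 1 (the whole sample space);
degenerate backgrounds $p_0 \in \{0, 1\}$ short-circuit to 1; the background
is the value's frequency over *all* leaves of the clustered axis, including
the cluster under test — a documented choice that makes expected values
exactly computable in tests. Raw p-values are reported, matching the
per-cluster display the document feeds; Benjamini–Hochberg adjustment is
available behind `adjust = TRUE`.

`looks_like_gene_symbols` is an offline stand-in for symbol autodetection:
the case-insensitive fraction of labels present in a caller-supplied
reference list (a ~1,300-symbol subset of common human gene symbols ships
with the package; it is a convenience fixture, not a complete annotation).

## The document and its views

The serialized document (schema `cm-1`) contains per-node records (name,
initial index, cluster-order index, sum and variance ranks, group id per
slice level, category values), the dense value grid with missing markers,
the slice fractions, provenance (metric, linkage, normalization, seed, tool
version), optional row/column similarity blocks, and the view list. The
default view ladder applies row-sum and row-variance filters at fractions
$1.0, 0.9, \ldots, 0.1$ — one view per slider position per metric — and each
view re-clusters both axes of the filtered matrix. Views never re-normalize:
normalization is applied once, upstream, so views stay comparable. A view
that would retain fewer than two rows is skipped with a warning.

Serialization uses 17-significant-digit numbers, enough for doubles to
round-trip exactly, and a fixed field order, so identical inputs and
configuration produce byte-identical JSON; `validate_document` checks shape
agreement, permutation validity, and group-refinement monotonicity, and
reports violations with JSON-path-style locations. The schema is
content-faithful to what a heatmap front end needs but makes no claim of
wire compatibility with any particular viewer.

## Synthetic generators

The generators produce inputs with the statistical structure each pipeline
assumes, at any scale, from one seed:

* `make_block_matrix`: rows and columns partitioned into blocks; row block
  $b$ is elevated by `effect` $\times$ `noise_sd` on the columns of block
  $b$. The block-diagonal design guarantees angular separation between row
  blocks, so at `effect = 10` clustering recovers the planted partition
  exactly, while `effect = 0` carries no signal — both ends are asserted in
  the tests.
* `make_cytof_like`: a Gaussian mixture of cell types in surface-marker
  space (18 surface + 10 phospho markers by default, mirroring a
  28-marker mass-cytometry panel), each type elevated by 8 sd on its own
  dedicated surface markers; exact treatment-arm counts
  (`Plasma`/`PMA`); and a planted responder — type 1 under PMA shifts on
  the first four phospho markers, echoing a phospho-activation signature as
  a detectable effect only, not a signaling model.
* `make_ptm_like`: positive lognormal PTM levels with one reference column
  per multiplex run (default 1,730 PTMs, 37 cell lines, 8 runs),
  missingness planted completely at random at rate 0.1, and an expression
  block whose planted high-variance subset (sd ratio 10) is exactly what a
  top-variance filter recovers.
* `make_ccle_like`: expression across tissues, two histology subtypes per
  tissue with subtype signatures on random gene subsets, plus
  tissue/histology/sub-histology/gender tracks.

What the generators do *not* emulate: heavy-tailed count noise, batch
effects, spillover or debarcoding artifacts, informative missingness,
correlated marker panels. Passing tests therefore demonstrate that the
pipeline mechanics (stage order, counts, determinism, recovery under clean
separation) are correct — not that the methods are robust on real
instrument data.

## Problem sizes and runtime choices

The test suite exercises the printed pipeline parameters at their native
scales where they are the point (a 220,000 x 28 downsampling run to 2,000
clusters, mini-batch; 2,000-per-arm subsampling; the 1,000-to-250 and
5,000-to-1,000 variance filters) and reduced scales elsewhere (workflow
logic at a few hundred rows), keeping the whole suite under about two
minutes. Mini-batch K-means is the documented variant at the full single-cell
scale; Lloyd at that scale would cost hundreds of full-matrix assignment
passes for no contract difference. The agglomeration loop maintains cached
row minima (rescanning only rows whose cached nearest neighbour was
invalidated), which keeps clustering of a few thousand leaves interactive in
pure R.

## Known limitations

* No optimal leaf ordering; the display order is a deterministic tie-break.
* No model-based imputation or batch correction; the distance-time mean
  imputation is deliberately minimal.
* Mini-batch centroids depend on the seed and batch schedule; only the
  cluster *count* and track arithmetic are contract-exact.
* The enrichment background includes the tested cluster; very large
  clusters are therefore conservatively scored.
* The TSV category encodings (inline `label|Name: value` segments and
  block `Name: value` header rows/columns) are this package's declared
  dialect.
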