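# clustviz

Back-end engine for interactive clustered heatmaps of omics matrices.

Heatmap viewers for transcriptomics, phospho-proteomics, and mass cytometry
need far more than a matrix render: dendrograms the user can slice into flat
clusters, rank orders to re-sort by, pre-computed filtered views behind a
slider, similarity matrices, category annotations, and enrichment statistics
for any cluster the user clicks. `clustviz` computes all of that up front
and serializes it into one self-contained visualization JSON document, so a
front end never has to recompute anything. It is written for computational
biologists who need to prepare matrices — bulk expression panels,
PTM/phospho ratios, or hundreds of thousands of single cells — for
interactive exploration.

## What it computes

For a labeled matrix $X \in \mathbb{R}^{m \times n}$ with per-axis category
tracks:

* **Clustering.** Pairwise cosine distances
  $d(u,v) = 1 - \frac{u \cdot v}{\lVert u\rVert\,\lVert v\rVert}$ and
  average linkage (UPGMA) on both axes — the defaults; euclidean/correlation
  and single/complete are available. The agglomeration uses a fully
  deterministic tie-break so identical inputs give byte-identical output.
* **Dendrogram slices.** Flat group assignments at ten cut heights
  ($0.1, \ldots, 1.0$ of the maximum merge height), refinement-monotone by
  construction.
* **Rank orders** by sum, variance, label, and cluster order.
* **Views.** Row-filtered variants (sum and variance, fractions
  $1.0 \ldots 0.1$), each re-clustered.
* **Similarity matrices** ($1 - d$) for rows and columns.
* **K-means downsampling** (Lloyd or mini-batch) of single-cell matrices to
  exactly `k` centroids carrying a `number in clust` size track and
  `Majority-*` modal category tracks; seeded random subsampling per
  treatment group; label transfer back to cells.
* **Enrichment.** For each cluster and category value, the exact upper
  binomial tail $P(X \ge k)$, $X \sim \mathrm{Bin}(n, p_0)$, with the
  background proportion $p_0$ taken over all leaves.

Three case-study pipelines compose these primitives: a PTM+expression
workflow (ratio to per-run reference, quantile normalization,
missing-value filter at 7, row Z-score, top-1,000-variance expression
block, column-intersection join), a CyTOF workflow (column Z-score, K-means
downsampling to 2,000 clusters in surface-marker space, 2,000-cell
per-treatment subsampling in phospho space), and a CCLE workflow
(per-tissue top-250-variance filter, row Z-score). Seeded synthetic
generators emulate each input shape so everything runs without downloads.

## Worked example

Downsample a synthetic 20,000-cell CyTOF-like matrix to 200 clusters in
surface-marker space, build the document, and test cluster enrichment:

```r
library(clustviz)

cells  <- make_cytof_like(n_cells = 20000, n_types = 4, seed = 7)
marker <- get_track(cells, "columns", "Marker-Type")
surface <- subset_axis(zscore(cells, "columns"),
                       which(marker$entries == "surface"), "columns")
ds  <- kmeans_downsample(surface, 200, seed = 7, algorithm = "minibatch")
doc <- build_visualization(ds$centroids, view_specs = NULL)
doc
#> <viz_document cm-1> 200 x 18, 1 view(s), 10 group level(s)
table(get_track(ds$centroids, "rows", "Majority-Treatment")$entries)
#> Plasma    PMA
#>    105     95
```

Each of the 200 centroid rows carries its cluster size and modal treatment;
sizes sum to 20,000. At slice level 5 the dendrogram falls into exactly the
four planted cell types, and every group is maximally enriched for its type:

```r
gcols  <- grep("^group_", names(doc$row_nodes), value = TRUE)
groups <- structure(list(fractions = doc$group_levels,
                         cut_heights = doc$group_levels,
                         assignments = matrix(unlist(doc$row_nodes[gcols]),
                                              ncol = length(gcols))),
                    class = "group_levels")
tracks <- list(category_track("Majority-Cell-Type",
                              doc$row_nodes[["cat_Majority-Cell-Type"]]))
cluster_enrichment(groups, 5, tracks)
#>   group      category_name category_value  n  k    p0    z  p_value
#> 1     1 Majority-Cell-Type         type-4 39 39 0.195 12.7 2.05e-28
#> 2     2 Majority-Cell-Type         type-3 54 54 0.270 12.1 1.97e-31
#> 3     3 Majority-Cell-Type         type-1 49 49 0.245 12.3 1.17e-30
#> 4     4 Majority-Cell-Type         type-2 58 58 0.290 11.9 6.59e-32
```

Here `n` is the cluster size, `k` the members carrying the value, `p0` the
value's global frequency, and `p_value` the exact upper binomial tail — a
cluster made entirely of one type whose global share is ~20–30 % is
astronomically unlikely under the background, which is the point of the
statistic.

Serialize with `write_viz_json(doc, "doc.json")`; `validate_document()`
checks shape, permutation, and refinement invariants. A command-line
wrapper over the same functions ships at `inst/cli/cm.R`
(`Rscript cm.R build|downsample|enrich|validate|synth|workflow ...`).

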