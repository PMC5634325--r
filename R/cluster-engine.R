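#' Pairwise distances between rows or columns
#'
#' Computes the full symmetric distance matrix between the vectors along one
#' axis. Cosine distance is `1 - (u . v) / (|u||v|)`; correlation distance is
#' the cosine distance of the centered vectors. Missing entries are imputed
#' transiently to the vector mean (never written back). Zero-norm vectors
#' have cosine distance 1 to any nonzero vector and 0 to another zero-norm
#' vector.
#'
#' @param m a [labeled_matrix()].
#' @param axis `"rows"` or `"columns"`: which vectors to compare.
#' @param metric `"cosine"` (default), `"euclidean"`, or `"correlation"`.
#' @return A symmetric numeric matrix with zero diagonal, labeled by the
#'   axis labels.
#' @export
pairwise_distance <- function(m, axis = c("rows", "columns"),
                              metric = c("cosine", "euclidean",
                                         "correlation")) {
  axis <- match_axis(axis)
  metric <- match.arg(metric)
  v <- impute_for_distance(m$values, axis)
  x <- if (axis == "rows") v else t(v)   # vectors as rows
  if (nrow(x) < 2) cv_abort("need at least 2 vectors on the ", axis, " axis")
  d <- switch(metric,
    "euclidean" = as.matrix(stats::dist(x, method = "euclidean")),
    "cosine" = cosine_dist(x),
    "correlation" = cosine_dist(x - rowMeans(x)))
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

cosine_dist <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  xn <- x / ifelse(zero, 1, nrm)
  s <- tcrossprod(xn)
  s <- pmin(pmax(s, -1), 1)
  d <- 1 - s
  # zero-norm policy: distance 1 to anything nonzero, 0 to another zero vector
  if (any(zero)) {
    d[zero, ] <- 1
    d[, zero] <- 1
    d[zero, zero] <- 0
  }
  d
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Classic bottom-up agglomeration under average (UPGMA), single, or complete
#' linkage via Lance-Williams updates. Among cluster pairs at the minimal
#' distance, the pair whose smallest original leaf index is lowest (then the
#' second index) is merged, so results are exactly reproducible.
#'
#' @param d a symmetric non-negative distance matrix (or `dist` object).
#' @param method `"average"` (default), `"single"`, or `"complete"`.
#' @return A `linkage_tree`: list with `merges` (an (n-1) x 2 integer matrix
#'   in `hclust` convention, negative entries are leaves), `heights`
#'   (non-decreasing), `n_leaves`, `labels`, and `leaf_order` (see
#'   [leaf_ordering()]).
#' @export
linkage <- function(d, method = c("average", "single", "complete")) {
  method <- match.arg(method)
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(d < 0)) cv_abort("distance matrix has negative entries")
  if (max(abs(d - t(d))) > 1e-12) cv_abort("distance matrix not symmetric")
  n <- nrow(d)
  labels <- rownames(d)
  if (n == 1) {
    tree <- structure(list(merges = matrix(integer(), 0, 2),
                           heights = numeric(0), n_leaves = 1L,
                           labels = labels, leaf_order = 1L,
                           method = method),
                      class = "linkage_tree")
    return(tree)
  }
  D <- d
  diag(D) <- Inf
  size <- rep(1L, n)
  minleaf <- seq_len(n)        # smallest original leaf index per slot
  id <- -seq_len(n)            # hclust-style cluster id occupying each slot
  merges <- matrix(0L, n - 1, 2)
  heights <- numeric(n - 1)
  # maintained row minima avoid a full matrix scan at every merge
  rmin <- apply(D, 1, min)
  nnidx <- max.col(-D, ties.method = "first")
  for (s in seq_len(n - 1)) {
    mval <- min(rmin)
    rows_tied <- which(rmin == mval)
    ci <- integer(0); cj <- integer(0)
    for (r in rows_tied) {
      cols <- which(D[r, ] == mval)
      ci <- c(ci, rep.int(r, length(cols)))
      cj <- c(cj, cols)
    }
    keep <- ci < cj
    ci <- ci[keep]; cj <- cj[keep]
    # deterministic tie-break: lowest smallest original member index, then
    # lowest second index
    k1 <- pmin(minleaf[ci], minleaf[cj])
    k2 <- pmax(minleaf[ci], minleaf[cj])
    pick <- order(k1, k2)[1]
    i <- ci[pick]; j <- cj[pick]
    heights[s] <- mval
    first_i <- minleaf[i] <= minleaf[j]
    merges[s, ] <- if (first_i) c(id[i], id[j]) else c(id[j], id[i])
    di <- D[, i]; dj <- D[, j]
    new <- switch(method,
      "average" = (size[i] * di + size[j] * dj) / (size[i] + size[j]),
      "single" = pmin(di, dj),
      "complete" = pmax(di, dj))
    new[i] <- Inf
    new[j] <- Inf
    D[, i] <- new
    D[i, ] <- new
    D[, j] <- Inf
    D[j, ] <- Inf
    size[i] <- size[i] + size[j]
    minleaf[i] <- min(minleaf[i], minleaf[j])
    id[i] <- s
    # update the cached minima: improvements first, then rows whose cached
    # nearest neighbour was i or j and must be rescanned
    improved <- which(new < rmin)
    rmin[improved] <- new[improved]
    nnidx[improved] <- i
    stale <- which((nnidx == i | nnidx == j))
    stale <- setdiff(stale, improved)
    for (k in stale) {
      rmin[k] <- min(D[k, ])
      nnidx[k] <- which.min(D[k, ])
    }
    rmin[i] <- min(new)
    nnidx[i] <- which.min(new)
    rmin[j] <- Inf
    nnidx[j] <- i
  }
  tree <- structure(list(merges = merges, heights = heights,
                         n_leaves = as.integer(n), labels = labels,
                         leaf_order = integer(0), method = method),
                    class = "linkage_tree")
  tree$leaf_order <- leaf_ordering(tree)
  tree
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> %d leaves, %s linkage, max height %.4g\n",
              x$n_leaves, x$method,
              if (length(x$heights)) max(x$heights) else 0))
  invisible(x)
}

#' Deterministic display order of the leaves
#'
#' Depth-first traversal in which, at every merge, the subtree containing the
#' smallest original leaf index comes first. This fixes the heatmap display
#' order without any optimal-ordering heuristics.
#'
#' @param t a `linkage_tree`.
#' @return An integer permutation of `1:n_leaves`.
#' @export
leaf_ordering <- function(t) {
  n <- t$n_leaves
  if (n == 1) return(1L)
  # iterative in-order walk; merges rows already place the smaller-index
  # subtree on the left
  out <- integer(n)
  pos <- 0L
  stack <- integer(2 * n)
  top <- 1L
  stack[1] <- n - 1L          # root merge step
  while (top > 0L) {
    node <- stack[top]
    top <- top - 1L
    if (node < 0L) {
      pos <- pos + 1L
      out[pos] <- -node
    } else {
      # push right first so the left child is processed first
      top <- top + 1L; stack[top] <- t$merges[node, 2]
      top <- top + 1L; stack[top] <- t$merges[node, 1]
    }
  }
  out
}

#' Convert a linkage tree to an hclust object
#'
#' @param t a `linkage_tree`.
#' @return A `stats::hclust` object (for plotting or interop).
#' @export
as_hclust <- function(t) {
  structure(list(merge = t$merges, height = t$heights,
                 order = t$leaf_order,
                 labels = t$labels, method = t$method,
                 call = match.call(), dist.method = NULL),
            class = "hclust")
}

#' Flat partitions from dendrogram slices
#'
#' Cuts the tree at each threshold, expressed as a fraction of the maximum
#' merge height: merges whose height is at or below the cut are applied and
#' each resulting connected subtree is one group. Group ids are numbered by
#' the leaf order of each group's first member, so id 1 is always the
#' left-most group in the display.
#'
#' @param t a `linkage_tree`.
#' @param fractions increasing cut fractions in (0, 1]. Default ten evenly
#'   spaced slices `0.1, 0.2, ..., 1.0`.
#' @return A `group_levels` object: list with `fractions`, `cut_heights`, and
#'   `assignments`, an `n_leaves x length(fractions)` integer matrix.
#' @export
slice_groups <- function(t, fractions = seq(0.1, 1, by = 0.1)) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions, strictly = TRUE))
  n <- t$n_leaves
  if (n == 0) cv_abort("empty tree")
  hmax <- if (length(t$heights)) max(t$heights) else 0
  cuts <- fractions * hmax
  # heights are non-decreasing, so the merges at or below each cut are a
  # prefix of the merge sequence: one pass with snapshots per level
  n_below <- vapply(cuts, function(h) sum(t$heights <= h), 0L)
  assignments <- matrix(0L, n, length(fractions),
                        dimnames = list(t$labels, NULL))
  comp <- seq_len(n)                    # leaf -> component root (leaf index)
  cluster_of <- vector("list", max(nrow(t$merges), 1))
  members <- as.list(seq_len(n))
  get_members <- function(node) {
    if (node < 0) members[[-node]] else cluster_of[[node]]
  }
  snapshot <- function(comp) {
    # renumber components by leaf_order of first appearance
    ids <- integer(n)
    next_id <- 0L
    seen <- integer(0)
    for (leaf in t$leaf_order) {
      hit <- match(comp[leaf], seen)
      if (is.na(hit)) {
        next_id <- next_id + 1L
        seen[next_id] <- comp[leaf]
        ids[leaf] <- next_id
      } else {
        ids[leaf] <- hit
      }
    }
    ids
  }
  for (li in which(n_below == 0)) assignments[, li] <- snapshot(comp)
  for (s in seq_len(nrow(t$merges))) {
    mem <- c(get_members(t$merges[s, 1]), get_members(t$merges[s, 2]))
    cluster_of[[s]] <- mem
    comp[mem] <- min(mem)
    for (li in which(n_below == s)) assignments[, li] <- snapshot(comp)
  }
  structure(list(fractions = fractions, cut_heights = cuts,
                 assignments = assignments),
            class = "group_levels")
}

#' Standard rank orders for both axes
#'
#' Precomputes the permutations a heatmap front end needs to reorder rows and
#' columns: the initial (input) order, case-insensitive alphabetical order,
#' descending sum and variance orders (stable in the original order on ties),
#' and the dendrogram leaf order.
#'
#' @param m a [labeled_matrix()].
#' @param t_rows,t_cols `linkage_tree`s for the rows and columns of `m`.
#' @return A list with elements `rows` and `cols`, each a named list of
#'   integer permutations: `initial`, `alphabetical`, `sum`, `variance`,
#'   `cluster`.
#' @export
rank_orders <- function(m, t_rows, t_cols) {
  stopifnot(t_rows$n_leaves == nrow(m$values),
            t_cols$n_leaves == ncol(m$values))
  one_axis <- function(axis, tree) {
    labs <- axis_labels(m, axis)
    list(initial = seq_along(labs),
         alphabetical = order(tolower(labs), seq_along(labs)),
         sum = order_desc_stable(axis_metric(m$values, axis, "sum")),
         variance = order_desc_stable(axis_metric(m$values, axis,
                                                  "variance")),
         cluster = tree$leaf_order)
  }
  list(rows = one_axis("rows", t_rows),
       cols = one_axis("columns", t_cols))
}

#' Similarity matrix of rows or columns
#'
#' `1 - distance` for every pair of vectors along the axis, packaged as a
#' square labeled matrix whose rows and columns both carry the axis labels
#' and category tracks (so the similarity heatmap keeps its annotations).
#'
#' @inheritParams pairwise_distance
#' @return A square [labeled_matrix()] with unit diagonal.
#' @export
similarity_matrix <- function(m, axis = c("rows", "columns"),
                              metric = c("cosine", "euclidean",
                                         "correlation")) {
  axis <- match_axis(axis)
  d <- pairwise_distance(m, axis, metric)
  s <- 1 - d
  diag(s) <- 1
  tracks <- axis_tracks(m, axis)
  labeled_matrix(s, row_categories = tracks, col_categories = tracks)
}
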