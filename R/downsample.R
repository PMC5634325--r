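#' K-means downsampling with category propagation
#'
#' Replaces the `n` rows of a matrix by exactly `k` cluster centroids, as
#' used to reduce hundreds of thousands of single cells to a clusterable
#' overview. Every categorical row track yields a per-cluster majority track
#' (modal value; ties broken by the lexicographically smallest value),
#' numeric tracks propagate as per-cluster means, and a numeric
#' `"number in clust"` track records cluster sizes. Clusters that empty out
#' during iteration are re-seeded from the points farthest from their
#' centroid, so the output always has exactly `k` rows.
#'
#' @param m a [labeled_matrix()] with no missing entries.
#' @param k cluster budget (1 <= k <= rows).
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @param algorithm `"lloyd"` (batch, centroids are exact member means) or
#'   `"minibatch"` (stochastic updates, recommended beyond ~50,000 rows;
#'   final centroids are recomputed as member means of the final
#'   assignment).
#' @param max_iter iteration cap (Lloyd sweeps or mini-batches).
#' @param batch_size mini-batch size (minibatch only).
#' @return A `downsample_result`: list with `centroids` (a `labeled_matrix`
#'   of `k` rows carrying the propagated tracks), `membership` (integer
#'   cluster id per input row, named by row label), and `sizes`.
#' @export
kmeans_downsample <- function(m, k, seed = 1L,
                              algorithm = c("lloyd", "minibatch"),
                              max_iter = if (algorithm[1] == "lloyd")
                                50L else 200L,
                              batch_size = 1024L) {
  algorithm <- match.arg(algorithm)
  x <- m$values
  if (anyNA(x)) cv_abort("matrix has missing entries; filter or impute first")
  n <- nrow(x)
  if (k > n) cv_abort("k = ", k, " exceeds number of rows ", n)
  fit <- withr::with_seed(as.integer(seed), {
    if (algorithm == "lloyd") lloyd_kmeans(x, k, max_iter)
    else minibatch_kmeans(x, k, max_iter, batch_size)
  })
  centers <- fit$centers
  member <- fit$cluster
  sizes <- tabulate(member, nbins = k)
  clab <- sprintf("clust-%d", seq_len(k))
  rownames(centers) <- clab
  colnames(centers) <- colnames(x)
  tracks <- list(category_track("number in clust", as.numeric(sizes),
                                "numeric"))
  for (tr in m$row_categories) {
    tracks <- c(tracks, list(propagate_track(tr, member, k)))
  }
  centroids <- labeled_matrix(centers,
                              row_categories = tracks,
                              col_categories = m$col_categories)
  structure(list(centroids = centroids,
                 membership = stats::setNames(member, rownames(x)),
                 sizes = sizes,
                 algorithm = algorithm, seed = as.integer(seed)),
            class = "downsample_result")
}

propagate_track <- function(tr, member, k) {
  if (tr$kind == "numeric") {
    means <- vapply(seq_len(k), function(j)
      mean(tr$entries[member == j]), 0)
    category_track(tr$name, means, "numeric")
  } else {
    modal <- vapply(seq_len(k), function(j) {
      tab <- table(tr$entries[member == j])
      # majority value; ties -> lexicographically smallest modal value
      sort(names(tab)[tab == max(tab)])[1]
    }, "")
    category_track(paste0("Majority-", tr$name), modal, "categorical")
  }
}

# nearest-centroid assignment in row chunks; ties take the lowest center id
assign_nearest <- function(x, centers, chunk = 8192L) {
  n <- nrow(x)
  cl <- integer(n)
  d2min <- numeric(n)
  c2 <- rowSums(centers^2)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    cross <- x[idx, , drop = FALSE] %*% t(centers)
    d2 <- outer(rowSums(x[idx, , drop = FALSE]^2), c2, "+") - 2 * cross
    pick <- max.col(-d2, ties.method = "first")
    cl[idx] <- pick
    d2min[idx] <- d2[cbind(seq_along(idx), pick)]
  }
  list(cluster = cl, d2 = pmax(d2min, 0))
}

# re-seed empty clusters from the points currently farthest from their
# centroid, then re-assign; guarantees k non-empty clusters
fill_empty <- function(x, centers, asg, k, max_rounds = 25L) {
  for (round in seq_len(max_rounds)) {
    sizes <- tabulate(asg$cluster, nbins = k)
    empty <- which(sizes == 0)
    if (!length(empty)) break
    far <- order(-asg$d2)[seq_along(empty)]
    centers[empty, ] <- x[far, , drop = FALSE]
    asg <- assign_nearest(x, centers)
  }
  list(centers = centers, asg = asg)
}

recompute_means <- function(x, cl, k, centers) {
  for (j in seq_len(k)) {
    mem <- which(cl == j)
    if (length(mem)) centers[j, ] <- colMeans(x[mem, , drop = FALSE])
  }
  centers
}

lloyd_kmeans <- function(x, k, max_iter) {
  centers <- x[sample.int(nrow(x), k), , drop = FALSE]
  cl_prev <- NULL
  for (it in seq_len(max_iter)) {
    asg <- assign_nearest(x, centers)
    res <- fill_empty(x, centers, asg, k)
    centers <- res$centers; asg <- res$asg
    centers <- recompute_means(x, asg$cluster, k, centers)
    if (identical(asg$cluster, cl_prev)) break
    cl_prev <- asg$cluster
  }
  asg <- assign_nearest(x, centers)
  res <- fill_empty(x, centers, asg, k)
  centers <- recompute_means(x, res$asg$cluster, k, res$centers)
  list(centers = centers, cluster = res$asg$cluster)
}

minibatch_kmeans <- function(x, k, max_iter, batch_size) {
  n <- nrow(x)
  centers <- x[sample.int(n, k), , drop = FALSE]
  counts <- rep(0, k)
  for (it in seq_len(max_iter)) {
    idx <- sample.int(n, min(batch_size, n))
    xb <- x[idx, , drop = FALSE]
    cl <- assign_nearest(xb, centers)$cluster
    for (j in unique(cl)) {
      mem <- which(cl == j)
      counts[j] <- counts[j] + length(mem)
      eta <- length(mem) / counts[j]
      centers[j, ] <- (1 - eta) * centers[j, ] +
        eta * colMeans(xb[mem, , drop = FALSE])
    }
  }
  asg <- assign_nearest(x, centers)
  res <- fill_empty(x, centers, asg, k)
  centers <- recompute_means(x, res$asg$cluster, k, res$centers)
  list(centers = centers, cluster = res$asg$cluster)
}

#' @export
print.downsample_result <- function(x, ...) {
  cat(sprintf("<downsample_result> %d clusters from %d observations (%s)\n",
              nrow(x$centroids$values), length(x$membership), x$algorithm))
  invisible(x)
}

#' Seeded random subsampling of rows
#'
#' Draws `n_per_group` rows uniformly without replacement from each level of
#' a categorical row track (or from all rows when no track is given), e.g.
#' an equal number of cells from each treatment arm. Groups smaller than
#' `n_per_group` are kept whole. The original row order is preserved within
#' the sample and the draw is bit-reproducible given the seed.
#'
#' @param m a [labeled_matrix()].
#' @param n_per_group rows to draw per group.
#' @param group_track name of a categorical row track, or `NULL`.
#' @param seed integer seed.
#' @return A `labeled_matrix` with the sampled rows.
#' @export
random_subsample <- function(m, n_per_group, group_track = NULL, seed = 1L) {
  groups <- if (is.null(group_track)) {
    rep("all", nrow(m$values))
  } else {
    tr <- get_track(m, "rows", group_track)
    if (tr$kind != "categorical")
      cv_abort("group track '", group_track, "' is numeric; need categorical")
    tr$entries
  }
  idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(sort(unique(groups)), function(g) {
      pool <- which(groups == g)
      if (length(pool) <= n_per_group) pool
      else sample(pool, n_per_group)
    }), use.names = FALSE)
  })
  subset_axis(m, sort(idx), "rows")
}

#' Transfer cluster-level labels back to observations
#'
#' After annotating downsampled clusters (e.g. naming cell types from
#' surface-marker expression), assigns each original observation the label of
#' its cluster.
#'
#' @param membership integer cluster id per observation, as returned in
#'   `downsample_result$membership`.
#' @param cluster_labels character vector of labels indexed by cluster id
#'   (or named by cluster id).
#' @return A character vector of per-observation labels, preserving the
#'   names of `membership`.
#' @export
transfer_labels <- function(membership, cluster_labels) {
  ids <- sort(unique(membership))
  if (!is.null(names(cluster_labels))) {
    lab <- cluster_labels[as.character(ids)]
    missing <- ids[is.na(lab)]
  } else {
    missing <- ids[ids > length(cluster_labels)]
    lab <- cluster_labels
  }
  if (length(missing))
    cv_abort("unlabeled cluster id(s): ", paste(missing, collapse = ", "))
  out <- if (!is.null(names(cluster_labels))) {
    unname(cluster_labels[as.character(membership)])
  } else {
    cluster_labels[membership]
  }
  stats::setNames(out, names(membership))
}
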