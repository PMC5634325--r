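# independent oracles used across test files; these recompute results from
# first principles and never call the code paths they check

# brute-force agglomeration: cluster distances recomputed from the original
# distance matrix at every step (no Lance-Williams shortcut)
brute_force_agglomerate <- function(d, method = "average") {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  cluster_dist <- function(a, b) {
    vals <- d[a, b, drop = FALSE]
    switch(method,
           average = mean(vals),
           single = min(vals),
           complete = max(vals))
  }
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        dd <- cluster_dist(clusters[[i]], clusters[[j]])
        key <- c(dd,
                 min(clusters[[i]][1], clusters[[j]][1]),
                 max(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) ||
            dd < best$key[1] - 1e-12 ||
            (abs(dd - best$key[1]) <= 1e-12 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    heights <- c(heights, best$key[1])
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# canonical form of a partition (list of member sets) for set comparison
canon_partition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, `[`, 0, 1))]
}

# partitions implied by a linkage_tree after each merge
tree_partitions <- function(t) {
  n <- t$n_leaves
  members <- as.list(seq_len(n))
  merged <- vector("list", nrow(t$merges))
  out <- list()
  for (s in seq_len(nrow(t$merges))) {
    get <- function(node) if (node < 0) members[[-node]] else merged[[node]]
    merged[[s]] <- sort(c(get(t$merges[s, 1]), get(t$merges[s, 2])))
    comp <- seq_len(n)
    for (q in seq_len(s)) comp[merged[[q]]] <- min(merged[[q]])
    out[[s]] <- canon_partition(unname(split(seq_len(n), comp)))
  }
  out
}

# exact upper binomial tail by direct coefficient summation
naive_binom_tail <- function(k, n, p0) {
  if (k == 0) return(1)
  sum(vapply(k:n, function(i) choose(n, i) * p0^i * (1 - p0)^(n - i), 0))
}

random_distance_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    x <- matrix(stats::runif(n * n), n)
    d <- (x + t(x)) / 2
    diag(d) <- 0
    d
  })
}

tiny_matrix <- function(values, ...) {
  labeled_matrix(values, ...)
}
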