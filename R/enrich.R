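#' Category composition of a leaf set
#'
#' Counts how often each value of a categorical track occurs among the given
#' leaves (the "breakdown" shown for a dendrogram cluster).
#'
#' @param leaves integer indices of the leaves in the cluster.
#' @param track a categorical [category_track()] covering the axis.
#' @return A named integer vector of counts; the counts sum to
#'   `length(leaves)`.
#' @export
category_breakdown <- function(leaves, track) {
  if (!length(leaves)) cv_abort("empty leaf set")
  if (any(leaves < 1 | leaves > length(track$entries)))
    cv_abort("leaf index outside track '", track$name, "'")
  tab <- table(track$entries[leaves])
  stats::setNames(as.integer(tab), names(tab))
}

#' Exact upper-tail binomial enrichment probability
#'
#' The binomial proportion test used for cluster-category enrichment:
#' the probability of observing at least `k` carriers in a cluster of size
#' `n` when each member independently carries the category with the
#' background proportion `p0`, i.e. `P(X >= k)` for
#' `X ~ Binomial(n, p0)`. `k = 0` spans the whole sample space and returns 1;
#' degenerate backgrounds (`p0` of 0 or 1) short-circuit to 1.
#'
#' @param k in-cluster carrier count, `0 <= k <= n`.
#' @param n cluster size.
#' @param p0 background carrier proportion in `[0, 1]`.
#' @return The upper-tail probability in `(0, 1]`.
#' @examples
#' binom_enrichment(10, 10, 0.5)   # 0.5^10
#' @export
binom_enrichment <- function(k, n, p0) {
  stopifnot(n >= 0, p0 >= 0, p0 <= 1)
  if (k > n) cv_abort("k = ", k, " exceeds n = ", n)
  if (k < 0) cv_abort("k must be >= 0")
  if (k == 0 || p0 <= 0 || p0 >= 1) return(1)
  stats::pbinom(k - 1, size = n, prob = p0, lower.tail = FALSE)
}

# normal-approximation z statistic of the same proportion test, reported for
# reference alongside the exact tail
binom_zstat <- function(k, n, p0) {
  if (p0 <= 0 || p0 >= 1) return(NA_real_)
  (k / n - p0) / sqrt(p0 * (1 - p0) / n)
}

#' Category enrichment of every group at one dendrogram slice level
#'
#' For each group at the chosen slice level and each value of each
#' categorical track present in the group: `n` is the group size, `k` the
#' in-group carrier count, `p0` the value's frequency across all leaves
#' (including the group itself), and the p-value the exact upper binomial
#' tail [binom_enrichment()]. Numeric tracks are skipped with a notice.
#' Raw p-values are reported; Benjamini-Hochberg adjustment is opt-in.
#'
#' @param groups a `group_levels` object from [slice_groups()].
#' @param level index into the slice levels.
#' @param tracks list of [category_track()]s on the clustered axis.
#' @param adjust if `TRUE`, add a `p_adjusted` column (Benjamini-Hochberg
#'   across all results of the level).
#' @return A data frame with columns `group`, `category_name`,
#'   `category_value`, `n`, `k`, `p0`, `z`, `p_value` (and optionally
#'   `p_adjusted`), sorted by group then ascending p-value.
#' @export
cluster_enrichment <- function(groups, level, tracks, adjust = FALSE) {
  stopifnot(inherits(groups, "group_levels"),
            level >= 1, level <= length(groups$fractions))
  asg <- groups$assignments[, level]
  n_total <- length(asg)
  rows <- list()
  cat_tracks <- Filter(function(tr) tr$kind == "categorical", tracks)
  skipped <- setdiff(vapply(tracks, `[[`, "", "name"),
                     vapply(cat_tracks, `[[`, "", "name"))
  if (length(skipped))
    cv_log("skipping numeric track(s): ", paste(skipped, collapse = ", "))
  for (tr in cat_tracks) {
    if (length(tr$entries) != n_total)
      cv_abort("track '", tr$name, "' does not cover the clustered axis")
    global <- table(tr$entries) / n_total
    for (g in sort(unique(asg))) {
      members <- which(asg == g)
      counts <- category_breakdown(members, tr)
      for (val in names(counts)) {
        k <- counts[[val]]
        n <- length(members)
        p0 <- as.numeric(global[[val]])
        rows[[length(rows) + 1]] <- data.frame(
          group = g, category_name = tr$name, category_value = val,
          n = n, k = k, p0 = p0,
          z = binom_zstat(k, n, p0),
          p_value = binom_enrichment(k, n, p0),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(group = integer(), category_name = character(),
               category_value = character(), n = integer(), k = integer(),
               p0 = numeric(), z = numeric(), p_value = numeric(),
               stringsAsFactors = FALSE)
  }
  out <- out[order(out$group, out$p_value, out$category_value), ]
  rownames(out) <- NULL
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Fraction of labels matching a gene-symbol reference
#'
#' Offline stand-in for symbol autodetection: the case-insensitive fraction
#' of labels found in a caller-supplied reference symbol list. A small
#' reference of common human gene symbols ships with the package (see
#' [gene_symbol_reference()]).
#'
#' @param labels non-empty character vector of row labels.
#' @param reference character vector of official symbols.
#' @return Matched fraction in `[0, 1]`.
#' @export
looks_like_gene_symbols <- function(labels,
                                    reference = gene_symbol_reference()) {
  if (!length(labels)) cv_abort("empty label list")
  mean(tolower(labels) %in% tolower(reference))
}

#' Packaged reference list of common human gene symbols
#'
#' A plain-text, one-symbol-per-line subset of official human gene symbols
#' sufficient for coarse autodetection; not a complete genome annotation.
#'
#' @return A character vector of symbols.
#' @export
gene_symbol_reference <- function() {
  path <- system.file("extdata", "gene_symbols_subset.txt",
                      package = "clustviz", mustWork = TRUE)
  readLines(path)
}
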