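#' Z-score normalization along one axis
#'
#' Each vector along the axis is centered and scaled to mean 0, sd 1 over its
#' non-missing entries. Constant vectors (sd = 0) map to all zeros so they
#' remain clusterable; the missingness pattern is preserved.
#'
#' @param m a [labeled_matrix()].
#' @param axis `"rows"` or `"columns"`.
#' @param ddof delta degrees of freedom of the standard deviation
#'   (default 1, the sample sd).
#' @return A `labeled_matrix` of the same shape.
#' @examples
#' m <- labeled_matrix(matrix(c(1, 2, 3), 1, 3))
#' zscore(m, "rows")$values   # -1 0 1
#' @export
zscore <- function(m, axis = c("rows", "columns"), ddof = 1) {
  axis <- match_axis(axis)
  v <- m$values
  n_axis <- if (axis == "rows") ncol(v) else nrow(v)
  if (n_axis <= ddof)
    cv_abort("axis length ", n_axis, " <= ddof ", ddof)
  norm_vec <- function(x) {
    mu <- mean(x, na.rm = TRUE)
    s <- sqrt(vec_var(x, ddof))
    if (is.na(s) || s == 0) {
      x[!is.na(x)] <- 0
      x
    } else {
      (x - mu) / s
    }
  }
  out <- if (axis == "rows") {
    t(apply(v, 1, norm_vec))
  } else {
    apply(v, 2, norm_vec)
  }
  dimnames(out) <- dimnames(v)
  m$values <- out
  m
}

#' Quantile normalization along one axis
#'
#' Forces every vector along the axis to share an identical distribution:
#' each vector's entries are replaced by the reference value at their rank,
#' where the reference is the per-rank mean (or median) of the sorted
#' vectors; ties receive the mean of their tied reference values. Delegates
#' to `limma::normalizeQuantiles` for the mean reference.
#'
#' @param m a [labeled_matrix()] without missing entries along the axis
#'   (filter or impute first), unless `allow_missing` is set.
#' @param axis `"rows"` or `"columns"`. The normalized vectors run along this
#'   axis: `"columns"` makes all columns share one distribution.
#' @param reference `"mean"` (default) or `"median"` per-rank summary.
#' @param allow_missing if `TRUE` (mean reference only), missing entries stay
#'   missing and each vector's non-missing entries are mapped onto the
#'   reference distribution by interpolated rank, as `limma` does; the
#'   default is to refuse incomplete input.
#' @return A `labeled_matrix`.
#' @export
quantile_normalize <- function(m, axis = c("columns", "rows"),
                               reference = c("mean", "median"),
                               allow_missing = FALSE) {
  axis <- match.arg(axis)
  reference <- match.arg(reference)
  v <- m$values
  if (anyNA(v) && !allow_missing)
    cv_abort("quantile normalization requires a complete matrix; ",
             "run filter_missing() or impute first")
  if (anyNA(v) && reference == "median")
    cv_abort("allow_missing supports only the mean reference")
  flip <- axis == "rows"
  x <- if (flip) t(v) else v
  out <- if (reference == "mean") {
    limma::normalizeQuantiles(x, ties = TRUE)
  } else {
    qn_median(x)
  }
  if (flip) out <- t(out)
  dimnames(out) <- dimnames(v)
  m$values <- out
  m
}

# per-rank median reference with tie averaging, same contract as the mean path
qn_median <- function(x) {
  ref <- apply(apply(x, 2, sort), 1, stats::median)
  apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_along(ref), ref, xout = r, rule = 2)$y
  })
}

#' Keep the top vectors along one axis by a summary metric
#'
#' Retains the `keep` rows (or columns) with the largest sum, variance, or
#' absolute sum, computed over non-missing entries. Ties are broken by
#' original position (earlier wins) and survivors keep their original
#' relative order. Category tracks are subset accordingly.
#'
#' @param m a [labeled_matrix()].
#' @param metric `"sum"`, `"variance"`, or `"abs-sum"`.
#' @param n count of vectors to keep (integer >= 1, clamped to the axis
#'   length with a warning). Exactly one of `n` and `fraction` must be given.
#' @param fraction fraction in (0, 1] of the axis length to keep (ceiling).
#' @param axis `"rows"` or `"columns"`.
#' @param ddof degrees-of-freedom correction for the variance metric.
#' @return A `labeled_matrix`.
#' @export
filter_top <- function(m, metric = c("variance", "sum", "abs-sum"),
                       n = NULL, fraction = NULL,
                       axis = c("rows", "columns"), ddof = 1) {
  metric <- match.arg(metric)
  axis <- match_axis(axis)
  len <- if (axis == "rows") nrow(m$values) else ncol(m$values)
  if (len == 0) cv_abort("empty matrix")
  if (is.null(n) == is.null(fraction))
    cv_abort("give exactly one of n and fraction")
  n_keep <- if (!is.null(fraction)) {
    stopifnot(fraction > 0, fraction <= 1)
    as.integer(ceiling(fraction * len))
  } else {
    stopifnot(n >= 1)
    if (n > len)
      warning("n = ", n, " clamped to axis length ", len, call. = FALSE)
    as.integer(min(n, len))
  }
  score <- axis_metric(m$values, axis, metric, ddof)
  idx <- sort(order_desc_stable(score)[seq_len(n_keep)])
  subset_axis(m, idx, axis)
}

axis_metric <- function(v, axis, metric, ddof = 1) {
  mar <- if (axis == "rows") 1 else 2
  switch(metric,
         "sum" = apply(v, mar, function(x) sum(x, na.rm = TRUE)),
         "abs-sum" = apply(v, mar, function(x) sum(abs(x), na.rm = TRUE)),
         "variance" = apply(v, mar, vec_var, ddof = ddof))
}

#' Drop vectors with too many missing entries
#'
#' Removes rows (or columns) whose missing count is strictly greater than
#' `max_missing`; order is preserved. With `max_missing = 7` this is the
#' missing-value rule used by the PTM workflow.
#'
#' @param m a [labeled_matrix()].
#' @param max_missing maximum tolerated number of missing entries (>= 0).
#' @param axis `"rows"` or `"columns"`.
#' @return A `labeled_matrix`.
#' @export
filter_missing <- function(m, max_missing, axis = c("rows", "columns")) {
  axis <- match_axis(axis)
  stopifnot(is.numeric(max_missing), max_missing >= 0)
  mar <- if (axis == "rows") 1 else 2
  n_miss <- apply(m$values, mar, function(x) sum(is.na(x)))
  subset_axis(m, which(n_miss <= max_missing), axis)
}

#' Divide sample columns by per-run reference columns
#'
#' Each sample column is divided elementwise by its mapped reference column
#' (e.g. the non-cancerous tissue channel of its multiplex run); reference
#' columns are dropped from the output. Division by a missing or zero
#' reference entry yields a missing value.
#'
#' @param m a [labeled_matrix()].
#' @param reference either a single reference column label applied to every
#'   sample, or a named character vector mapping each sample column label to
#'   its reference column label.
#' @return A `labeled_matrix` containing only the sample columns.
#' @export
ratio_to_reference <- function(m, reference) {
  v <- m$values
  cols <- colnames(v)
  if (is.null(names(reference))) {
    stopifnot(length(reference) == 1)
    if (!reference %in% cols) cv_abort("reference column '", reference,
                                       "' not found")
    samples <- setdiff(cols, reference)
    reference <- stats::setNames(rep(reference, length(samples)), samples)
  }
  ref_cols <- unique(unname(reference))
  samples <- setdiff(cols, ref_cols)
  unmapped <- setdiff(samples, names(reference))
  if (length(unmapped))
    cv_abort("sample column(s) without a reference mapping: ",
             paste(utils::head(unmapped, 5), collapse = ", "))
  missing_ref <- setdiff(unname(reference), cols)
  if (length(missing_ref))
    cv_abort("mapped reference column(s) not in matrix: ",
             paste(missing_ref, collapse = ", "))
  out <- sapply(samples, function(s) {
    r <- v[, reference[[s]]]
    denom_bad <- is.na(r) | r == 0
    res <- v[, s] / r
    res[denom_bad] <- NA_real_
    res
  })
  keep_idx <- match(samples, cols)
  m2 <- subset_axis(m, keep_idx, "columns")
  m2$values[] <- out
  m2
}

# transient distance-time imputation: missing entries replaced by the vector
# mean (all-missing vectors by 0); never written back to the matrix
impute_for_distance <- function(v, axis) {
  if (!anyNA(v)) return(v)
  fill <- function(x) {
    mu <- mean(x, na.rm = TRUE)
    x[is.na(x)] <- if (is.nan(mu)) 0 else mu
    x
  }
  out <- if (axis == "rows") t(apply(v, 1, fill)) else apply(v, 2, fill)
  dimnames(out) <- dimnames(v)
  out
}
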