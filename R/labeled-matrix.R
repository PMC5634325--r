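#' Labeled matrix with per-axis category tracks
#'
#' The central container of the package: a numeric matrix whose rows and
#' columns carry unique labels plus any number of category tracks. A track
#' annotates every label on one axis with either a string (categorical, e.g.
#' histology) or a finite number (numeric "value-based" category, e.g.
#' cluster size).
#'
#' @param values numeric matrix; `NA` marks missing entries.
#' @param row_labels,col_labels character vectors of axis labels. Default to
#'   the dimnames of `values`. Duplicates are disambiguated by appending a
#'   numeric suffix, with a warning.
#' @param row_categories,col_categories lists of [category_track()] objects,
#'   each with one entry per label on the axis.
#' @return An object of class `labeled_matrix`.
#' @examples
#' m <- labeled_matrix(matrix(1:4, 2, dimnames = list(c("G1", "G2"),
#'                                                    c("S1", "S2"))))
#' dim(m$values)
#' @export
labeled_matrix <- function(values, row_labels = rownames(values),
                           col_labels = colnames(values),
                           row_categories = list(),
                           col_categories = list()) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(row_labels))
    row_labels <- sprintf("row-%d", seq_len(nrow(values)))
  if (is.null(col_labels))
    col_labels <- sprintf("col-%d", seq_len(ncol(values)))
  row_labels <- disambiguate_labels(as.character(row_labels), "row")
  col_labels <- disambiguate_labels(as.character(col_labels), "column")
  dimnames(values) <- list(row_labels, col_labels)
  m <- structure(
    list(values = values,
         row_categories = row_categories,
         col_categories = col_categories),
    class = "labeled_matrix")
  validate_labeled_matrix(m)
  m
}

#' Category track for one matrix axis
#'
#' @param name track name (e.g. `"Majority-Treatment"`, `"number in clust"`).
#' @param entries one value per axis label, in axis order. A numeric vector
#'   (all finite) yields a numeric track; anything else is coerced to
#'   character and yields a categorical track.
#' @param kind optional override, `"categorical"` or `"numeric"`.
#' @return An object of class `category_track` with fields `name`, `kind`,
#'   `entries`.
#' @export
category_track <- function(name, entries, kind = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (is.null(kind)) {
    kind <- if (is.numeric(entries)) "numeric" else "categorical"
  }
  kind <- match.arg(kind, c("categorical", "numeric"))
  if (kind == "numeric") {
    entries <- as.numeric(entries)
    if (any(!is.finite(entries)))
      cv_abort("numeric category track '", name, "' contains non-finite entries")
  } else {
    entries <- as.character(entries)
    if (length(unique(entries)) < 1)
      cv_abort("categorical track '", name, "' is empty")
  }
  structure(list(name = name, kind = kind, entries = entries),
            class = "category_track")
}

disambiguate_labels <- function(labels, what) {
  if (any(!nzchar(labels)))
    cv_abort("empty ", what, " label(s) at position(s) ",
             paste(which(!nzchar(labels)), collapse = ", "))
  if (any(grepl("\t", labels, fixed = TRUE)))
    cv_abort(what, " labels must not contain tab characters")
  if (anyDuplicated(labels)) {
    dups <- unique(labels[duplicated(labels)])
    warning("duplicate ", what, " labels disambiguated with numeric suffixes: ",
            paste(utils::head(dups, 5), collapse = ", "),
            if (length(dups) > 5) ", ..." else "", call. = FALSE)
    labels <- make.unique(labels, sep = "-")
  }
  labels
}

#' Validate a labeled matrix
#'
#' Checks the container invariants: value/label shape agreement, track
#' lengths, finite numeric tracks. Errors on the first violation.
#'
#' @param m a `labeled_matrix`.
#' @return `m`, invisibly.
#' @export
validate_labeled_matrix <- function(m) {
  stopifnot(inherits(m, "labeled_matrix"))
  v <- m$values
  if (length(rownames(v)) != nrow(v) || length(colnames(v)) != ncol(v))
    cv_abort("values shape does not match label lengths")
  check_tracks <- function(tracks, n, axis) {
    for (tr in tracks) {
      if (!inherits(tr, "category_track"))
        cv_abort("non-track object in ", axis, " categories")
      if (length(tr$entries) != n)
        cv_abort("track '", tr$name, "' has ", length(tr$entries),
                 " entries for ", n, " ", axis)
    }
  }
  check_tracks(m$row_categories, nrow(v), "rows")
  check_tracks(m$col_categories, ncol(v), "columns")
  invisible(m)
}

#' @export
print.labeled_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<labeled_matrix> %d x %d (%d missing)\n",
              nrow(v), ncol(v), sum(is.na(v))))
  fmt_tracks <- function(tr) {
    if (!length(tr)) return("none")
    paste(vapply(tr, function(t) sprintf("%s[%s]", t$name, t$kind), ""),
          collapse = ", ")
  }
  cat("  row tracks: ", fmt_tracks(x$row_categories), "\n", sep = "")
  cat("  col tracks: ", fmt_tracks(x$col_categories), "\n", sep = "")
  invisible(x)
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

#' Subset a labeled matrix along one axis
#'
#' Keeps the given row or column indices (in the given order), subsetting
#' every category track on that axis accordingly.
#'
#' @param m a `labeled_matrix`.
#' @param idx integer indices into the axis.
#' @param axis `"rows"` or `"columns"`.
#' @return A `labeled_matrix`.
#' @export
subset_axis <- function(m, idx, axis = c("rows", "columns")) {
  axis <- match_axis(axis)
  sub_tracks <- function(tracks) {
    lapply(tracks, function(tr)
      category_track(tr$name, tr$entries[idx], tr$kind))
  }
  if (axis == "rows") {
    labeled_matrix(m$values[idx, , drop = FALSE],
                   row_categories = sub_tracks(m$row_categories),
                   col_categories = m$col_categories)
  } else {
    labeled_matrix(m$values[, idx, drop = FALSE],
                   row_categories = m$row_categories,
                   col_categories = sub_tracks(m$col_categories))
  }
}

#' Look up a category track by name
#'
#' @param m a `labeled_matrix`.
#' @param axis `"rows"` or `"columns"`.
#' @param name track name.
#' @return The `category_track`, or an error listing available tracks.
#' @export
get_track <- function(m, axis, name) {
  axis <- match_axis(axis)
  tracks <- if (axis == "rows") m$row_categories else m$col_categories
  for (tr in tracks) if (tr$name == name) return(tr)
  cv_abort("no ", axis, " track named '", name, "'; available: ",
           paste(vapply(tracks, `[[`, "", "name"), collapse = ", "))
}

axis_labels <- function(m, axis) {
  if (axis == "rows") rownames(m$values) else colnames(m$values)
}

axis_tracks <- function(m, axis) {
  if (axis == "rows") m$row_categories else m$col_categories
}
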