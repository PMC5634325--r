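#' Row-filtered view specification
#'
#' A view is a pre-computed variant of the document after keeping a fraction
#' of the rows by a metric and re-clustering. The unfiltered view
#' (`metric "none"`, fraction 1) is always present and listed first.
#'
#' @param filter_metric `"none"`, `"sum"`, or `"variance"`.
#' @param keep_fraction fraction of rows kept, in (0, 1].
#' @return A `view_spec` object.
#' @export
view_spec <- function(filter_metric = c("none", "sum", "variance"),
                      keep_fraction = 1) {
  filter_metric <- match.arg(filter_metric)
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  structure(list(filter_metric = filter_metric,
                 keep_fraction = keep_fraction, axis = "rows"),
            class = "view_spec")
}

#' Default ladder of view specifications
#'
#' The unfiltered view followed by row-sum and row-variance filters at
#' fractions 1.0, 0.9, ..., 0.1 — one view per position of a 10-step
#' row-filter slider per metric.
#'
#' @return List of [view_spec()]s.
#' @export
default_view_specs <- function() {
  fr <- seq(1, 0.1, by = -0.1)
  c(list(view_spec("none", 1)),
    lapply(fr, function(f) view_spec("sum", f)),
    lapply(fr, function(f) view_spec("variance", f)))
}

cluster_config <- function(metric = "cosine", linkage_method = "average",
                           group_fractions = seq(0.1, 1, by = 0.1)) {
  list(metric = metric, linkage_method = linkage_method,
       group_fractions = group_fractions)
}

# cluster both axes of a matrix and derive groups + ranks
cluster_axes <- function(m, config) {
  t_rows <- linkage(pairwise_distance(m, "rows", config$metric),
                    config$linkage_method)
  t_cols <- linkage(pairwise_distance(m, "columns", config$metric),
                    config$linkage_method)
  list(t_rows = t_rows, t_cols = t_cols,
       g_rows = slice_groups(t_rows, config$group_fractions),
       g_cols = slice_groups(t_cols, config$group_fractions),
       ranks = rank_orders(m, t_rows, t_cols))
}

# one axis's node table: name, indices under each order, group ids, categories
make_nodes <- function(m, axis, tree, groups, ranks) {
  labs <- axis_labels(m, axis)
  inv <- function(perm) {
    pos <- integer(length(perm))
    pos[perm] <- seq_along(perm)
    pos
  }
  df <- data.frame(name = labs,
                   ini = seq_along(labs),
                   clust = inv(ranks$cluster),
                   rank_sum = inv(ranks$sum),
                   rank_var = inv(ranks$variance),
                   stringsAsFactors = FALSE)
  for (li in seq_along(groups$fractions)) {
    df[[sprintf("group_%d", li)]] <- groups$assignments[, li]
  }
  for (tr in axis_tracks(m, axis)) {
    df[[paste0("cat_", tr$name)]] <- tr$entries
  }
  df
}

#' Pre-computed row-filtered views
#'
#' For each specification: filter rows with [filter_top()] at the given
#' fraction, re-cluster both axes of the filtered matrix, and emit node
#' tables plus the value grid. Fractions leaving fewer than 2 rows are
#' skipped with a warning.
#'
#' @param m the (already normalized) base [labeled_matrix()].
#' @param specs list of [view_spec()]s; see [default_view_specs()].
#' @param config clustering configuration (metric, linkage, group fractions).
#' @return A named list (`view-1`, `view-2`, ...) of views, each holding
#'   `spec`, `row_nodes`, `col_nodes`, `mat`.
#' @export
build_views <- function(m, specs = default_view_specs(),
                        config = cluster_config()) {
  views <- list()
  for (sp in specs) {
    mv <- if (sp$filter_metric == "none") m
          else filter_top(m, sp$filter_metric, fraction = sp$keep_fraction,
                          axis = "rows")
    if (nrow(mv$values) < 2) {
      warning("view ", sp$filter_metric, "/", sp$keep_fraction,
              " leaves < 2 rows; skipped", call. = FALSE)
      next
    }
    cl <- cluster_axes(mv, config)
    views[[sprintf("view-%d", length(views) + 1)]] <- list(
      spec = list(filter_metric = sp$filter_metric,
                  keep_fraction = sp$keep_fraction, axis = "rows"),
      row_nodes = make_nodes(mv, "rows", cl$t_rows, cl$g_rows,
                             cl$ranks$rows),
      col_nodes = make_nodes(mv, "columns", cl$t_cols, cl$g_cols,
                             cl$ranks$cols),
      mat = unname(mv$values))
  }
  views
}

#' Assemble the visualization document
#'
#' Combines clustering components derived from one matrix into the
#' serializable document consumed by a heatmap front end: node tables with
#' initial/cluster/rank indices, per-level dendrogram group ids and category
#' values; the dense value grid; pre-computed filtered views; and optional
#' row/column similarity blocks.
#'
#' @param m the base [labeled_matrix()].
#' @param axes result of clustering both axes (trees, groups, ranks).
#' @param views named list from [build_views()].
#' @param similarities optional list with `rows` and/or `cols` similarity
#'   [labeled_matrix()]s.
#' @param provenance named list recording metric, linkage, normalization and
#'   seeds.
#' @return A `viz_document`.
#' @keywords internal
assemble_document <- function(m, axes, views, similarities = NULL,
                              provenance = list()) {
  row_nodes <- make_nodes(m, "rows", axes$t_rows, axes$g_rows,
                          axes$ranks$rows)
  col_nodes <- make_nodes(m, "columns", axes$t_cols, axes$g_cols,
                          axes$ranks$cols)
  if (nrow(row_nodes) != nrow(m$values))
    cv_abort("assembly: row_nodes do not match matrix rows")
  if (nrow(col_nodes) != ncol(m$values))
    cv_abort("assembly: col_nodes do not match matrix columns")
  sim_block <- function(s) {
    if (is.null(s)) NULL
    else list(labels = rownames(s$values), mat = unname(s$values))
  }
  doc <- list(schema_version = "cm-1",
              group_levels = axes$g_rows$fractions,
              provenance = provenance,
              row_nodes = row_nodes,
              col_nodes = col_nodes,
              mat = unname(m$values),
              views = views,
              row_similarity = sim_block(similarities$rows),
              col_similarity = sim_block(similarities$cols))
  doc <- doc[!vapply(doc, is.null, TRUE)]
  structure(doc, class = "viz_document")
}

#' Build the full visualization document from a labeled matrix
#'
#' The main entry point of the engine: optional normalization, clustering of
#' both axes with the default cosine distance and average linkage, ten
#' dendrogram slice levels per axis, rank orders, the row-filter view
#' ladder, and row/column similarity matrices.
#'
#' @param m a [labeled_matrix()].
#' @param metric distance metric (default `"cosine"`).
#' @param linkage_method linkage rule (default `"average"`).
#' @param normalize one of `"none"`, `"zscore-rows"`, `"zscore-cols"`,
#'   `"quantile-cols"`; applied once, before clustering (views re-cluster
#'   but never re-normalize).
#' @param group_fractions dendrogram slice thresholds as fractions of the
#'   maximum merge height.
#' @param view_specs list of [view_spec()]s, or `NULL` for just the
#'   unfiltered view.
#' @param similarity include row/column similarity blocks?
#' @param seed integer recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return A `viz_document`.
#' @examples
#' m <- labeled_matrix(matrix(rnorm(24), 6, 4))
#' doc <- build_visualization(m, view_specs = NULL)
#' names(doc)
#' @export
build_visualization <- function(m, metric = "cosine",
                                linkage_method = "average",
                                normalize = c("none", "zscore-rows",
                                              "zscore-cols",
                                              "quantile-cols"),
                                group_fractions = seq(0.1, 1, by = 0.1),
                                view_specs = default_view_specs(),
                                similarity = TRUE, seed = 1L) {
  normalize <- match.arg(normalize)
  m <- switch(normalize,
              "none" = m,
              "zscore-rows" = zscore(m, "rows"),
              "zscore-cols" = zscore(m, "columns"),
              "quantile-cols" = quantile_normalize(m, "columns"))
  config <- cluster_config(metric, linkage_method, group_fractions)
  axes <- cluster_axes(m, config)
  if (is.null(view_specs)) view_specs <- list(view_spec("none", 1))
  views <- build_views(m, view_specs, config)
  sims <- if (similarity) {
    list(rows = similarity_matrix(m, "rows", metric),
         cols = similarity_matrix(m, "columns", metric))
  } else NULL
  assemble_document(
    m, axes, views, sims,
    provenance = list(metric = metric, linkage = linkage_method,
                      normalization = normalize, seed = as.integer(seed),
                      tool = "clustviz",
                      version = as.character(
                        utils::packageVersion("clustviz"))))
}

#' Serialize a visualization document to JSON
#'
#' Deterministic formatting (fixed precision, no locale) so that identical
#' documents serialize to identical bytes.
#'
#' @param doc a `viz_document`.
#' @param path optional file path; when given, the JSON is written there.
#' @return The JSON as a single string (invisibly when `path` is given).
#' @export
write_viz_json <- function(doc, path = NULL) {
  txt <- jsonlite::toJSON(unclass(doc), dataframe = "columns",
                          matrix = "rowmajor", digits = I(17),
                          auto_unbox = TRUE, na = "null", null = "null",
                          pretty = FALSE)
  txt <- as.character(txt)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(txt), con)
    return(invisible(txt))
  }
  txt
}

#' Read a visualization document from JSON
#'
#' @param source a JSON string or a file path.
#' @return A `viz_document`.
#' @export
read_viz_json <- function(source) {
  txt <- if (!grepl("^\\s*\\{", source) && file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else source
  raw <- jsonlite::fromJSON(txt, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE,
                            simplifyMatrix = TRUE)
  fix_nodes <- function(df) {
    df <- as.data.frame(df, stringsAsFactors = FALSE, check.names = FALSE)
    for (col in c("ini", "clust", "rank_sum", "rank_var",
                  grep("^group_", names(df), value = TRUE))) {
      df[[col]] <- as.integer(df[[col]])
    }
    df
  }
  fix_mat <- function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    dimnames(x) <- NULL
    x
  }
  raw$row_nodes <- fix_nodes(raw$row_nodes)
  raw$col_nodes <- fix_nodes(raw$col_nodes)
  raw$mat <- fix_mat(raw$mat)
  raw$group_levels <- as.numeric(raw$group_levels)
  raw$views <- lapply(raw$views, function(v) {
    list(spec = v$spec,
         row_nodes = fix_nodes(v$row_nodes),
         col_nodes = fix_nodes(v$col_nodes),
         mat = fix_mat(v$mat))
  })
  for (blk in c("row_similarity", "col_similarity")) {
    if (!is.null(raw[[blk]])) {
      raw[[blk]] <- list(labels = as.character(raw[[blk]]$labels),
                         mat = fix_mat(raw[[blk]]$mat))
    }
  }
  structure(raw, class = "viz_document")
}

#' Validate a visualization document
#'
#' Checks the document invariants and reports every violation with a
#' JSON-path-like location: schema version; node/matrix shape agreement in
#' the base document and every view; valid permutations in the index
#' columns; refinement monotonicity of the group ids across slice levels.
#'
#' @param doc a `viz_document`, a JSON string, or a path to a JSON file.
#' @return A list with `valid` (logical) and `violations` (character vector
#'   of `"path: message"` entries).
#' @export
validate_document <- function(doc) {
  if (is.character(doc)) {
    doc <- tryCatch(read_viz_json(doc), error = function(e) e)
    if (inherits(doc, "error"))
      return(list(valid = FALSE,
                  violations = paste0("$: malformed JSON (",
                                      conditionMessage(doc), ")")))
  }
  v <- character()
  if (!identical(doc$schema_version, "cm-1"))
    v <- c(v, "$.schema_version: expected \"cm-1\"")
  check_block <- function(rn, cn, mat, where) {
    out <- character()
    if (nrow(rn) != nrow(mat))
      out <- c(out, sprintf("%s: %d row_nodes for %d matrix rows",
                            where, nrow(rn), nrow(mat)))
    if (nrow(cn) != ncol(mat))
      out <- c(out, sprintf("%s: %d col_nodes for %d matrix columns",
                            where, nrow(cn), ncol(mat)))
    for (nm in c("ini", "clust", "rank_sum", "rank_var")) {
      perm <- rn[[nm]]
      if (!is.null(perm) && !identical(sort(perm), seq_len(nrow(rn))))
        out <- c(out, sprintf("%s.row_nodes.%s: not a permutation",
                              where, nm))
    }
    gcols <- grep("^group_", names(rn), value = TRUE)
    if (length(gcols) > 1) {
      for (li in seq_len(length(gcols) - 1)) {
        fine <- rn[[gcols[li]]]
        coarse <- rn[[gcols[li + 1]]]
        ok <- all(tapply(coarse, fine,
                         function(x) length(unique(x)) == 1))
        if (!ok)
          out <- c(out, sprintf(
            "%s.row_nodes.%s: level %d does not refine level %d",
            where, gcols[li], li, li + 1))
      }
    }
    out
  }
  v <- c(v, check_block(doc$row_nodes, doc$col_nodes, doc$mat, "$"))
  for (vn in names(doc$views)) {
    vw <- doc$views[[vn]]
    v <- c(v, check_block(vw$row_nodes, vw$col_nodes, vw$mat,
                          paste0("$.views.", vn)))
  }
  for (blk in c("row_similarity", "col_similarity")) {
    s <- doc[[blk]]
    if (!is.null(s)) {
      if (length(s$labels) != nrow(s$mat) ||
          nrow(s$mat) != ncol(s$mat))
        v <- c(v, sprintf("$.%s: labels/matrix shape mismatch", blk))
    }
  }
  list(valid = length(v) == 0, violations = v)
}

#' @export
print.viz_document <- function(x, ...) {
  cat(sprintf("<viz_document cm-1> %d x %d, %d view(s), %d group level(s)\n",
              nrow(x$mat), ncol(x$mat), length(x$views),
              length(x$group_levels)))
  invisible(x)
}
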