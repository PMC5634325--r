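# The three case-study pipelines, composed from the preprocessing,
# clustering, and downsampling primitives. Each returns the visualization
# document(s) plus a stage-by-stage report of dimensions and parameters.

new_report <- function(workflow, seed) {
  structure(list(workflow = workflow, seed = seed, stages = list()),
            class = "workflow_report")
}

add_stage <- function(report, name, dim_in, dim_out, params = list()) {
  n <- length(report$stages)
  if (n > 0) {
    prev <- report$stages[[n]]$dim_out
    if (!is.null(prev) && !is.null(dim_in) && !identical(prev, dim_in))
      cv_abort("stage '", name, "' input dims (",
               paste(dim_in, collapse = "x"),
               ") do not chain from previous output (",
               paste(prev, collapse = "x"), ")")
  }
  report$stages[[name]] <- list(name = name, dim_in = dim_in,
                                dim_out = dim_out, params = params)
  report
}

#' @export
print.workflow_report <- function(x, ...) {
  cat(sprintf("<workflow_report> %s (seed %d)\n", x$workflow, x$seed))
  for (st in x$stages) {
    cat(sprintf("  %-28s %s -> %s\n", st$name,
                paste(st$dim_in, collapse = "x"),
                paste(st$dim_out, collapse = "x")))
  }
  invisible(x)
}

#' Format a workflow report as plain text
#'
#' @param report a `workflow_report`.
#' @return A character vector of lines.
#' @export
format_report <- function(report) {
  c(sprintf("workflow: %s", report$workflow),
    sprintf("seed: %d", report$seed),
    vapply(report$stages, function(st) {
      sprintf("%s\t%s\t%s\t%s", st$name,
              paste(st$dim_in, collapse = "x"),
              paste(st$dim_out, collapse = "x"),
              paste(sprintf("%s=%s", names(st$params),
                            vapply(st$params, function(p)
                              paste(format(p), collapse = ","), "")),
                    collapse = " "))
    }, ""))
}

#' Lung-cancer PTM plus expression workflow
#'
#' Reproduces the preprocessing pipeline for a multiplexed PTM panel
#' combined with expression data. PTM block: divide each cell-line column by
#' its run's reference column, quantile normalize the columns, drop PTM rows
#' with more than `max_missing` missing values, then Z-score the rows.
#' Expression block: keep the `n_top_var` most variable genes, Z-score the
#' rows. The two blocks are joined on the intersection of their cell-line
#' columns, tagged by a `Data-Type` row track, clustered with the default
#' cosine/average configuration, and assembled into a document.
#'
#' @param ptm a [labeled_matrix()] of positive PTM levels, columns = cell
#'   lines plus reference columns.
#' @param expr a [labeled_matrix()] of expression, columns = cell lines.
#' @param reference_map named character vector mapping each cell-line column
#'   of `ptm` to its reference column.
#' @param max_missing missing-value tolerance per PTM row (default 7).
#' @param n_top_var expression rows kept by the variance filter
#'   (default 1000).
#' @param view_specs views for the final document (default: only the
#'   unfiltered view, to keep the document compact).
#' @param seed integer recorded in the provenance.
#' @return A list with `document` (a `viz_document`) and `report`.
#' @export
run_ptm_workflow <- function(ptm, expr, reference_map, max_missing = 7,
                             n_top_var = 1000, view_specs = NULL,
                             seed = 1L) {
  report <- new_report("ptm", as.integer(seed))
  d0 <- dim(ptm$values)
  ratios <- ratio_to_reference(ptm, reference_map)
  report <- add_stage(report, "ratio_to_reference", d0, dim(ratios$values),
                      list(n_references = length(unique(reference_map))))
  qn <- quantile_normalize(ratios, "columns", allow_missing = TRUE)
  report <- add_stage(report, "quantile_normalize", dim(ratios$values),
                      dim(qn$values), list(reference = "mean"))
  kept <- filter_missing(qn, max_missing, "rows")
  report <- add_stage(report, "filter_missing", dim(qn$values),
                      dim(kept$values), list(max_missing = max_missing))
  ptm_z <- zscore(kept, "rows")
  report <- add_stage(report, "zscore_ptm_rows", dim(kept$values),
                      dim(ptm_z$values))

  e0 <- dim(expr$values)
  expr_top <- filter_top(expr, "variance", n = n_top_var, axis = "rows")
  expr_z <- zscore(expr_top, "rows")

  shared <- intersect(colnames(ptm_z$values), colnames(expr_z$values))
  if (!length(shared)) cv_abort("no shared cell-line columns between ",
                                "the PTM and expression blocks")
  ptm_z <- subset_axis(ptm_z, match(shared, colnames(ptm_z$values)),
                       "columns")
  expr_z <- subset_axis(expr_z, match(shared, colnames(expr_z$values)),
                        "columns")
  combined <- labeled_matrix(
    rbind(ptm_z$values, expr_z$values),
    row_categories = list(category_track(
      "Data-Type", c(rep("PTM", nrow(ptm_z$values)),
                     rep("expression", nrow(expr_z$values))))),
    col_categories = ptm_z$col_categories)
  report$stages[["filter_top_expr"]] <-
    list(name = "filter_top_expr", dim_in = e0, dim_out = dim(expr_z$values),
         params = list(metric = "variance", n = n_top_var))
  report <- within_chain(report, "combine_blocks", dim(combined$values))

  doc <- build_visualization(combined, view_specs = view_specs, seed = seed)
  report <- within_chain(report, "cluster_and_assemble",
                         dim(combined$values))
  list(document = doc, report = report)
}

# append a stage that starts a new chain segment (block combination etc.)
within_chain <- function(report, name, dim_out) {
  report$stages[[name]] <- list(name = name, dim_in = NULL,
                                dim_out = dim_out, params = list())
  report
}

#' CyTOF single-cell workflow
#'
#' Z-scores the marker columns, then produces two documents: (a) the
#' surface-marker space overview, K-means downsampling the cells to
#' `k_clusters` centroids that carry a `Majority-Treatment` flag and the
#' `number in clust` size track, hierarchically clustered with the default
#' configuration; (b) the phospho-marker space view, either randomly
#' subsampling `n_subsample` cells per treatment arm or (via
#' `phospho_method = "kmeans"`) downsampling as in (a). Cluster labels can
#' afterwards be transferred back to single cells with [transfer_labels()].
#'
#' @param cells a [labeled_matrix()] of cells x markers with a categorical
#'   `Treatment` row track and a `Marker-Type` column track tagging each
#'   column `surface` or `phospho`.
#' @param k_clusters K-means cluster budget for downsampling (default 2000).
#' @param n_subsample cells drawn per treatment arm for the phospho view
#'   (default 2000).
#' @param algorithm K-means variant, `"minibatch"` (default, suited to
#'   hundreds of thousands of cells) or `"lloyd"`.
#' @param phospho_method `"subsample"` (default) or `"kmeans"` for the
#'   phospho-space document.
#' @param treatment_track,marker_track track names.
#' @param view_specs views for the documents (default: unfiltered only).
#' @param seed integer seed driving the downsampling and subsampling.
#' @return A list with `surface_document`, `phospho_document`,
#'   `downsample` (the `downsample_result`), and `report`.
#' @export
run_cytof_workflow <- function(cells, k_clusters = 2000,
                               n_subsample = 2000,
                               algorithm = c("minibatch", "lloyd"),
                               phospho_method = c("subsample", "kmeans"),
                               treatment_track = "Treatment",
                               marker_track = "Marker-Type",
                               view_specs = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  phospho_method <- match.arg(phospho_method)
  report <- new_report("cytof", as.integer(seed))
  marker <- get_track(cells, "columns", marker_track)
  get_track(cells, "rows", treatment_track)   # must exist
  z <- zscore(cells, "columns")
  report <- add_stage(report, "zscore_columns", dim(cells$values),
                      dim(z$values))

  surface <- subset_axis(z, which(marker$entries == "surface"), "columns")
  ds <- kmeans_downsample(surface, k_clusters, seed = seed,
                          algorithm = algorithm)
  report$stages[["kmeans_downsample_surface"]] <-
    list(name = "kmeans_downsample_surface", dim_in = dim(surface$values),
         dim_out = dim(ds$centroids$values),
         params = list(k = k_clusters, algorithm = algorithm))
  surface_doc <- build_visualization(ds$centroids, view_specs = view_specs,
                                     seed = seed)

  phospho <- subset_axis(z, which(marker$entries == "phospho"), "columns")
  phospho_input <- if (phospho_method == "subsample") {
    sub <- random_subsample(phospho, n_subsample,
                            group_track = treatment_track, seed = seed)
    report$stages[["random_subsample_phospho"]] <-
      list(name = "random_subsample_phospho",
           dim_in = dim(phospho$values), dim_out = dim(sub$values),
           params = list(n_per_group = n_subsample))
    sub
  } else {
    ds_p <- kmeans_downsample(phospho, k_clusters, seed = seed,
                              algorithm = algorithm)
    report$stages[["kmeans_downsample_phospho"]] <-
      list(name = "kmeans_downsample_phospho",
           dim_in = dim(phospho$values),
           dim_out = dim(ds_p$centroids$values),
           params = list(k = k_clusters, algorithm = algorithm))
    ds_p$centroids
  }
  phospho_doc <- build_visualization(phospho_input, view_specs = view_specs,
                                     seed = seed)
  list(surface_document = surface_doc, phospho_document = phospho_doc,
       downsample = ds, report = report)
}

#' CCLE per-tissue expression workflow
#'
#' Subsets the cell-line columns to one tissue of origin, keeps the
#' `n_top_var` most variable genes within the tissue, Z-scores the gene
#' rows, clusters with the default configuration, and assembles a document
#' in which the histology/sub-histology/gender tracks survive into the
#' column nodes.
#'
#' @param expr a [labeled_matrix()] with a categorical `tissue` column
#'   track.
#' @param tissue tissue name to select.
#' @param n_top_var genes kept by the variance filter (default 250).
#' @param tissue_track name of the tissue column track.
#' @param view_specs views for the document (default: unfiltered only).
#' @param seed integer recorded in the provenance.
#' @return A list with `document` and `report`.
#' @export
run_ccle_workflow <- function(expr, tissue, n_top_var = 250,
                              tissue_track = "tissue", view_specs = NULL,
                              seed = 1L) {
  report <- new_report("ccle", as.integer(seed))
  tr <- get_track(expr, "columns", tissue_track)
  if (!tissue %in% tr$entries)
    cv_abort("unknown tissue '", tissue, "'; available: ",
             paste(sort(unique(tr$entries)), collapse = ", "))
  sub <- subset_axis(expr, which(tr$entries == tissue), "columns")
  report <- add_stage(report, "select_tissue", dim(expr$values),
                      dim(sub$values), list(tissue = tissue))
  top <- filter_top(sub, "variance", n = n_top_var, axis = "rows")
  report <- add_stage(report, "filter_top_variance", dim(sub$values),
                      dim(top$values), list(n = n_top_var))
  z <- zscore(top, "rows")
  report <- add_stage(report, "zscore_rows", dim(top$values),
                      dim(z$values))
  doc <- build_visualization(z, view_specs = view_specs, seed = seed)
  report <- within_chain(report, "cluster_and_assemble", dim(z$values))
  list(document = doc, report = report)
}
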