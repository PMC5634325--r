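#' Block-structured random matrix with planted clusters
#'
#' Rows and columns are partitioned into `n_blocks` groups; row block `b` has
#' its mean raised by `effect * noise_sd` on the columns of block `b` and
#' Gaussian noise with sd `noise_sd` is added everywhere, so the planted row
#' partition is recoverable by clustering whenever `effect` clearly exceeds
#' the noise. Block ids are attached as categorical tracks on both axes.
#'
#' @param n_rows,n_cols matrix shape.
#' @param n_blocks planted cluster count (<= min(n_rows, n_cols)).
#' @param effect between-block mean shift in units of `noise_sd`.
#' @param noise_sd within-block standard deviation.
#' @param missing_rate fraction of entries set to missing.
#' @param seed integer seed; generation is bit-reproducible.
#' @return A [labeled_matrix()] with `row-block` / `col-block` tracks.
#' @export
make_block_matrix <- function(n_rows = 40, n_cols = 20, n_blocks = 2,
                              effect = 10, noise_sd = 1,
                              missing_rate = 0, seed = 1L) {
  stopifnot(n_blocks >= 1, n_blocks <= min(n_rows, n_cols),
            missing_rate >= 0, missing_rate <= 1)
  withr::with_seed(as.integer(seed), {
    row_block <- rep_len(seq_len(n_blocks), n_rows)
    col_block <- rep_len(seq_len(n_blocks), n_cols)
    mu <- matrix(0, n_rows, n_cols)
    for (b in seq_len(n_blocks)) {
      mu[row_block == b, col_block == b] <- effect * noise_sd
    }
    v <- mu + matrix(stats::rnorm(n_rows * n_cols, sd = noise_sd),
                     n_rows, n_cols)
    if (missing_rate > 0) {
      v[stats::runif(length(v)) < missing_rate] <- NA_real_
    }
    labeled_matrix(
      v,
      row_labels = sprintf("row-%d", seq_len(n_rows)),
      col_labels = sprintf("col-%d", seq_len(n_cols)),
      row_categories = list(category_track("row-block",
                                           sprintf("B%d", row_block))),
      col_categories = list(category_track("col-block",
                                           sprintf("B%d", col_block))))
  })
}

cytof_surface_markers <- c(
  "CD45", "CD3", "CD4", "CD8", "CD14", "CD16", "CD19", "CD20", "CD25",
  "CD27", "CD33", "CD34", "CD38", "CD56", "CD123", "CD127", "CD11b",
  "HLADR")

cytof_phospho_markers <- c(
  "pCREB", "pMAPKAP2", "pp38", "pERK1/2", "pSTAT1", "pSTAT3", "pSTAT5",
  "pNFkB", "pS6", "pPLCg2")

#' Synthetic CyTOF-like single-cell matrix
#'
#' Emulates a mass-cytometry experiment: cells (rows) by markers (columns,
#' 18 surface + 10 phospho by default), a Gaussian mixture of cell types in
#' surface-marker space (each type elevated on its own dedicated surface
#' markers by `effect` standard deviations), a `Treatment` track splitting
#' the cells into untreated (`Plasma`) and `PMA` arms, and a planted
#' responder: under PMA, cells of type 1 shift upward on the first four
#' phospho markers. A `Marker-Type` column track tags each column as
#' `surface` or `phospho`.
#'
#' @param n_cells number of cells (rows).
#' @param n_surface,n_phospho marker counts per class.
#' @param n_types number of Gaussian-mixture cell types.
#' @param treatment_fraction fraction of cells in the PMA arm; counts are
#'   exact (`round(treatment_fraction * n_cells)` PMA cells).
#' @param effect type separation and responder shift, in noise sd units.
#' @param seed integer seed.
#' @return A [labeled_matrix()] with `Treatment` and `Cell-Type` row tracks.
#' @export
make_cytof_like <- function(n_cells = 220000L, n_surface = 18L,
                            n_phospho = 10L, n_types = 5L,
                            treatment_fraction = 0.5, effect = 8,
                            seed = 1L) {
  stopifnot(n_types >= 1, n_cells >= n_types)
  withr::with_seed(as.integer(seed), {
    n_mark <- n_surface + n_phospho
    surf_names <- rep_len(cytof_surface_markers, n_surface)
    phos_names <- rep_len(cytof_phospho_markers, n_phospho)
    if (n_surface > length(cytof_surface_markers))
      surf_names <- sprintf("surf-%d", seq_len(n_surface))
    if (n_phospho > length(cytof_phospho_markers))
      phos_names <- sprintf("phos-%d", seq_len(n_phospho))
    type <- sample.int(n_types, n_cells, replace = TRUE)
    n_pma <- round(treatment_fraction * n_cells)
    treatment <- rep("Plasma", n_cells)
    treatment[sample.int(n_cells, n_pma)] <- "PMA"
    # each type owns an equal slice of the surface markers
    per_type <- max(1L, n_surface %/% n_types)
    v <- matrix(stats::rnorm(n_cells * n_mark), n_cells, n_mark)
    for (tt in seq_len(n_types)) {
      own <- (((tt - 1) * per_type) %% n_surface) + seq_len(per_type)
      own <- ((own - 1) %% n_surface) + 1
      v[type == tt, own] <- v[type == tt, own] + effect
    }
    # planted responder: type 1 under PMA shifts on the first 4 phospho cols
    resp <- type == 1 & treatment == "PMA"
    shift_cols <- n_surface + seq_len(min(4L, n_phospho))
    v[resp, shift_cols] <- v[resp, shift_cols] + effect
    labeled_matrix(
      v,
      row_labels = sprintf("cell_%d", seq_len(n_cells)),
      col_labels = c(surf_names, phos_names),
      row_categories = list(
        category_track("Treatment", treatment),
        category_track("Cell-Type", sprintf("type-%d", type))),
      col_categories = list(
        category_track("Marker-Type",
                       c(rep("surface", n_surface),
                         rep("phospho", n_phospho)))))
  })
}

#' Synthetic PTM and expression matrices with per-run references
#'
#' Emulates a multiplexed TMT phospho-proteomics panel: positive PTM levels
#' for `n_lines` cancer cell lines plus one non-cancerous reference column
#' per multiplex run, with missingness planted completely at random, and an
#' expression block in which a designated subset of `n_planted` genes
#' carries `effect`-fold higher variance (so a top-variance filter of that
#' size recovers exactly the planted subset).
#'
#' @param n_ptm number of PTM rows.
#' @param n_expr number of expression rows.
#' @param n_lines number of cell-line columns (shared by both blocks).
#' @param n_runs number of multiplex runs; cell lines are dealt into runs in
#'   order, remainders allowed.
#' @param n_planted size of the high-variance expression subset.
#' @param missing_rate fraction of missing PTM entries.
#' @param effect sd ratio of planted high-variance genes to background.
#' @param seed integer seed.
#' @return A list: `ptm` (a [labeled_matrix()] whose columns are the cell
#'   lines followed by `ref-run-<r>` reference columns, with a `run` column
#'   track), `expr` (genes x cell lines), `reference_map` (named vector
#'   mapping each cell-line column to its run's reference column), and
#'   `planted_high_var` (labels of the planted subset).
#' @export
make_ptm_like <- function(n_ptm = 1730L, n_expr = 5000L, n_lines = 37L,
                          n_runs = 8L, n_planted = 1000L,
                          missing_rate = 0.1, effect = 10, seed = 1L) {
  stopifnot(n_runs >= 1, n_lines >= n_runs, n_planted <= n_expr)
  if (n_lines %% n_runs != 0)
    cv_log("runs are uneven: ", n_lines, " lines in ", n_runs, " runs")
  withr::with_seed(as.integer(seed), {
    run_of <- rep_len(seq_len(n_runs), n_lines)
    line_labels <- sprintf("line-%d", seq_len(n_lines))
    ref_labels <- sprintf("ref-run-%d", seq_len(n_runs))
    base <- stats::rlnorm(n_ptm, meanlog = 0, sdlog = 0.5)
    sample_block <- base * matrix(stats::rlnorm(n_ptm * n_lines,
                                                sdlog = 0.4),
                                  n_ptm, n_lines)
    ref_block <- base * matrix(stats::rlnorm(n_ptm * n_runs, sdlog = 0.2),
                               n_ptm, n_runs)
    if (missing_rate > 0) {
      sample_block[stats::runif(length(sample_block)) < missing_rate] <-
        NA_real_
    }
    ptm <- labeled_matrix(
      cbind(sample_block, ref_block),
      row_labels = sprintf("ptm-%d", seq_len(n_ptm)),
      col_labels = c(line_labels, ref_labels),
      col_categories = list(
        category_track("run",
                       sprintf("run-%d", c(run_of, seq_len(n_runs))))))
    sds <- rep(1, n_expr)
    planted <- sample.int(n_expr, n_planted)
    sds[planted] <- effect
    expr <- labeled_matrix(
      matrix(stats::rnorm(n_expr * n_lines, sd = rep(sds, n_lines)),
             n_expr, n_lines),
      row_labels = sprintf("gene-%d", seq_len(n_expr)),
      col_labels = line_labels)
    list(ptm = ptm, expr = expr,
         reference_map = stats::setNames(ref_labels[run_of], line_labels),
         planted_high_var = sprintf("gene-%d", sort(planted)))
  })
}

#' Synthetic CCLE-like expression matrix grouped by tissue
#'
#' Expression of `n_genes` genes across cell lines drawn from several
#' tissues, each tissue with two histology subtypes whose lines share a
#' subtype-specific signature; `tissue`, `histology`, `sub-histology`, and
#' `gender` categorical column tracks are attached.
#'
#' @param n_genes number of gene rows.
#' @param lines_per_tissue cell lines per tissue.
#' @param tissues character vector of tissue names.
#' @param effect subtype signature strength in noise sd units.
#' @param seed integer seed.
#' @return A [labeled_matrix()].
#' @export
make_ccle_like <- function(n_genes = 1000L, lines_per_tissue = 20L,
                           tissues = c("lung", "breast",
                                       "haematopoietic_and_lymphoid_tissue"),
                           effect = 4, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    n_lines <- lines_per_tissue * length(tissues)
    tissue <- rep(tissues, each = lines_per_tissue)
    subtype <- paste0(tissue, "-sub",
                      rep_len(1:2, n_lines))
    v <- matrix(stats::rnorm(n_genes * n_lines), n_genes, n_lines)
    # each subtype raises a distinct random tenth of the genes
    for (st in unique(subtype)) {
      sig <- sample.int(n_genes, max(1L, n_genes %/% 10))
      v[sig, subtype == st] <- v[sig, subtype == st] + effect
    }
    labeled_matrix(
      v,
      row_labels = sprintf("gene-%d", seq_len(n_genes)),
      col_labels = sprintf("ccle-line-%d", seq_len(n_lines)),
      col_categories = list(
        category_track("tissue", tissue),
        category_track("histology", paste0(tissue, "-carcinoma")),
        category_track("sub-histology", subtype),
        category_track("gender",
                       sample(c("F", "M"), n_lines, replace = TRUE))))
  })
}
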