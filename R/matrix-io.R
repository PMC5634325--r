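#' Tab-separated matrix dialect
#'
#' Settings for reading and writing labeled matrices as TSV. Categories may
#' ride on labels as delimited segments (`"c7|number in clust: 12"`) or as
#' extra header rows/columns before the value block (`"Histology: SCLC"`
#' cells); both encodings are auto-detected on read.
#'
#' @param category_sep delimiter between a label and its inline category
#'   segments (default `"|"`).
#' @param name_value_sep separator between a category name and its value
#'   inside a segment (default `": "`).
#' @param na strings treated as missing in the value block, case-insensitive.
#' @return A `tsv_dialect` object.
#' @export
tsv_dialect <- function(category_sep = "|", name_value_sep = ": ",
                        na = c("", "NA")) {
  structure(list(category_sep = category_sep,
                 name_value_sep = name_value_sep,
                 na = tolower(na)),
            class = "tsv_dialect")
}

#' Parse a label cell into base label and categories
#'
#' Splits `raw` on the dialect's category separator; the first segment is the
#' base label, each further segment is a `Name: value` pair. A value that
#' parses as a finite real is additionally reported in the `numeric` column.
#'
#' @param raw a single non-empty label string.
#' @param dialect a [tsv_dialect()].
#' @return A list with `base_label` (string) and `categories`, a data frame
#'   with columns `name`, `value` (string) and `numeric` (parsed real or NA).
#' @examples
#' parse_category_label("c7|number in clust: 12|Majority-Treatment: Plasma")
#' @export
parse_category_label <- function(raw, dialect = tsv_dialect()) {
  stopifnot(is.character(raw), length(raw) == 1)
  parts <- strsplit(raw, dialect$category_sep, fixed = TRUE)[[1]]
  if (length(parts) == 0 || !nzchar(trimws(parts[1])))
    cv_abort("empty base label in '", raw, "'")
  cats <- if (length(parts) > 1) {
    do.call(rbind, lapply(parts[-1], function(seg) {
      nv <- split_name_value(seg, dialect)
      data.frame(name = nv[1], value = nv[2],
                 numeric = parse_real(nv[2]),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(name = character(), value = character(),
               numeric = numeric(), stringsAsFactors = FALSE)
  }
  list(base_label = trimws(parts[1]), categories = cats)
}

split_name_value <- function(seg, dialect) {
  pos <- regexpr(dialect$name_value_sep, seg, fixed = TRUE)
  if (pos < 0)
    cv_abort("category segment '", seg, "' lacks the '",
             dialect$name_value_sep, "' name/value separator")
  name <- trimws(substr(seg, 1, pos - 1))
  value <- substr(seg, pos + nchar(dialect$name_value_sep), nchar(seg))
  if (!nzchar(name)) cv_abort("empty category name in segment '", seg, "'")
  c(name, trimws(value))
}

parse_real <- function(s) {
  x <- suppressWarnings(as.numeric(s))
  ifelse(is.finite(x), x, NA_real_)
}

#' Read a labeled matrix from TSV
#'
#' The first row holds column labels and the first column row labels.
#' Category tracks are accepted in two encodings, auto-detected: inline label
#' segments (`"cell_001|Majority-Treatment: PMA"`) and block headers (extra
#' leading rows/columns whose cells are all `"Name: value"` with a shared
#' name). Empty or `NA` cells in the value block become missing entries.
#'
#' @param path path to a UTF-8 tab-separated file.
#' @param dialect a [tsv_dialect()].
#' @return A [labeled_matrix()].
#' @export
read_matrix_tsv <- function(path, dialect = tsv_dialect()) {
  if (!file.exists(path)) cv_abort("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0))]
  if (length(lines) < 2) cv_abort("file has no data rows: ", path)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(cells[[1]])
  widths <- lengths(cells)
  # strsplit drops one trailing empty cell, so width-1 is a legal line
  bad <- widths > width | widths < width - 1
  if (any(bad))
    cv_abort("ragged row: line ", which(bad)[1], " has ",
             widths[which(bad)[1]], " cells, header has ", width)
  cells <- lapply(cells, function(r) c(r, rep("", width - length(r))))

  is_nv <- function(x) {
    grepl(dialect$name_value_sep, x, fixed = TRUE)
  }
  # block column-category rows: rows 2.. with an empty corner cell whose
  # non-empty body cells all carry the name/value separator
  n_hdr_rows <- 1
  for (r in 2:length(cells)) {
    body <- cells[[r]][-1]
    body <- body[nzchar(body)]
    if (!nzchar(cells[[r]][1]) && length(body) && all(is_nv(body)))
      n_hdr_rows <- r
    else break
  }
  # block row-category columns: columns 2.. with the same property below the
  # header rows
  n_hdr_cols <- 1
  data_rows <- seq(n_hdr_rows + 1, length(cells))
  for (cc in 2:width) {
    body <- vapply(cells[data_rows], `[[`, "", cc)
    body <- body[nzchar(body)]
    if (!nzchar(cells[[1]][cc]) && length(body) && all(is_nv(body)))
      n_hdr_cols <- cc
    else break
  }
  data_cols <- seq(n_hdr_cols + 1, width)
  if (!length(data_rows) || !length(data_cols))
    cv_abort("no value block found in ", path)

  col_raw <- cells[[1]][data_cols]
  row_raw <- vapply(cells[data_rows], `[[`, "", 1)
  col_parsed <- lapply(col_raw, parse_category_label, dialect = dialect)
  row_parsed <- lapply(row_raw, parse_category_label, dialect = dialect)

  values <- matrix(NA_real_, length(data_rows), length(data_cols))
  for (i in seq_along(data_rows)) {
    raw <- cells[[data_rows[i]]][data_cols]
    miss <- tolower(trimws(raw)) %in% dialect$na
    num <- suppressWarnings(as.numeric(raw))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      j <- which(bad)[1]
      cv_abort("non-numeric value cell '", raw[j], "' at row ", i,
               ", col ", j, " of the value block")
    }
    values[i, !miss] <- num[!miss]
  }

  block_col_tracks <- lapply(seq_len(n_hdr_rows - 1) + 1, function(r) {
    block_track(cells[[r]][data_cols], dialect, sprintf("header row %d", r))
  })
  block_row_tracks <- lapply(seq_len(n_hdr_cols - 1) + 1, function(cc) {
    block_track(vapply(cells[data_rows], `[[`, "", cc), dialect,
                sprintf("header column %d", cc))
  })

  labeled_matrix(
    values,
    row_labels = vapply(row_parsed, `[[`, "", "base_label"),
    col_labels = vapply(col_parsed, `[[`, "", "base_label"),
    row_categories = c(inline_tracks(row_parsed, "row"), block_row_tracks),
    col_categories = c(inline_tracks(col_parsed, "column"), block_col_tracks))
}

block_track <- function(raw, dialect, where) {
  nv <- lapply(raw, split_name_value, dialect = dialect)
  names_seen <- unique(vapply(nv, `[[`, "", 1))
  if (length(names_seen) != 1)
    cv_abort(where, " mixes category names: ",
             paste(names_seen, collapse = ", "))
  make_track(names_seen, vapply(nv, `[[`, "", 2))
}

inline_tracks <- function(parsed, what) {
  all_names <- unique(unlist(lapply(parsed, function(p) p$categories$name)))
  lapply(all_names, function(nm) {
    vals <- vapply(parsed, function(p) {
      hit <- p$categories$value[p$categories$name == nm]
      if (length(hit) != 1)
        cv_abort(what, " label '", p$base_label, "' has ", length(hit),
                 " entries for category '", nm, "' (expected 1)")
      hit
    }, "")
    make_track(nm, vals)
  })
}

# a track is numeric only when every entry parses as a finite real
make_track <- function(name, values) {
  nums <- parse_real(values)
  if (!anyNA(nums)) category_track(name, nums, "numeric")
  else category_track(name, values, "categorical")
}

#' Write a labeled matrix as TSV
#'
#' Inverse of [read_matrix_tsv()]: category tracks are written as block
#' header rows/columns (`"Name: value"` cells), numbers with enough digits to
#' round-trip exactly, missing entries as empty cells.
#'
#' @param m a [labeled_matrix()].
#' @param path output file path.
#' @param dialect a [tsv_dialect()].
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, dialect = tsv_dialect()) {
  validate_labeled_matrix(m)
  v <- m$values
  n_rt <- length(m$row_categories)   # extra header columns
  n_ct <- length(m$col_categories)   # extra header rows
  fmt_cat <- function(tr) {
    vals <- if (tr$kind == "numeric") fmt_num(tr$entries) else tr$entries
    paste0(tr$name, dialect$name_value_sep, vals)
  }
  corner <- rep("", 1 + n_rt)
  header <- c(corner[1], rep("", n_rt), colnames(v))
  cat_rows <- lapply(m$col_categories, function(tr)
    c(corner, fmt_cat(tr)))
  body_vals <- matrix(fmt_num(v), nrow(v), ncol(v))
  row_cat_cols <- vapply(m$row_categories, fmt_cat,
                         character(nrow(v)))
  if (nrow(v) == 1 && n_rt > 0) row_cat_cols <- matrix(row_cat_cols, 1)
  body <- cbind(rownames(v),
                if (n_rt) row_cat_cols else NULL,
                body_vals)
  all_rows <- c(list(header), cat_rows,
                lapply(seq_len(nrow(v)), function(i) body[i, ]))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(all_rows, paste, "", collapse = "\t"), con)
  invisible(path)
}

# shortest decimal form that parses back to the identical double
fmt_num <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- ""
  ok <- !is.na(x)
  s <- sprintf("%.15g", x[ok])
  redo <- as.numeric(s) != x[ok]
  s[redo] <- sprintf("%.17g", x[ok][redo])
  out[ok] <- s
  out
}
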