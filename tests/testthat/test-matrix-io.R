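test_that("a minimal TSV parses into the right matrix", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tS1\tS2", "G1\t1\t2", "G2\t3\t4"), path)
  m <- read_matrix_tsv(path)
  expect_equal(dim(m$values), c(2L, 2L))
  expect_equal(rownames(m$values), c("G1", "G2"))
  expect_equal(colnames(m$values), c("S1", "S2"))
  expect_equal(unname(m$values), matrix(c(1, 3, 2, 4), 2))
  expect_length(m$row_categories, 0)
  expect_length(m$col_categories, 0)
})

test_that("label parsing splits categories and detects numeric values", {
  p <- parse_category_label("AML-1")
  expect_equal(p$base_label, "AML-1")
  expect_equal(nrow(p$categories), 0)

  p <- parse_category_label("cell_001|Majority-Treatment: PMA")
  expect_equal(p$base_label, "cell_001")
  expect_equal(p$categories$name, "Majority-Treatment")
  expect_equal(p$categories$value, "PMA")
  expect_true(is.na(p$categories$numeric))

  p <- parse_category_label("c7|number in clust: 12|Majority-Treatment: Plasma")
  expect_equal(p$categories$name, c("number in clust", "Majority-Treatment"))
  expect_equal(p$categories$numeric, c(12, NA))

  expect_error(parse_category_label("|number in clust: 3"), "empty base")
})

test_that("inline numeric category labels yield a numeric track", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tS1\tS2",
               "c1|number in clust: 37\t1\t2",
               "c2|number in clust: 5\t3\t4"), path)
  m <- read_matrix_tsv(path)
  tr <- get_track(m, "rows", "number in clust")
  expect_equal(tr$kind, "numeric")
  expect_equal(tr$entries, c(37, 5))
})

test_that("a track is categorical unless every entry parses as a real", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tS1\tS2",
               "c1|score: 37\t1\t2",
               "c2|score: high\t3\t4"), path)
  tr <- get_track(read_matrix_tsv(path), "rows", "score")
  expect_equal(tr$kind, "categorical")
  expect_equal(tr$entries, c("37", "high"))
})

test_that("malformed input errors carry coordinates and line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tS1\tS2\tS3", "G1\t1\t2\t3", "G2\t4\t5\tabc"), path)
  expect_error(read_matrix_tsv(path), "row 2, col 3")

  writeLines(c("\tS1\tS2", "G1\t1\t2\t3\t4"), path)
  expect_error(read_matrix_tsv(path), "line 2")
})

test_that("duplicate labels are disambiguated with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tS1\tS2", "G1\t1\t2", "G1\t3\t4"), path)
  expect_warning(m <- read_matrix_tsv(path), "duplicate")
  expect_equal(anyDuplicated(rownames(m$values)), 0L)
})

test_that("empty and NA cells in the value block become missing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tS1\tS2\tS3", "G1\t1\t\t3", "G2\tna\t5\tNA"), path)
  m <- read_matrix_tsv(path)
  expect_equal(sum(is.na(m$values)), 3L)
  expect_equal(m$values["G2", "S2"], 5)
})

test_that("TSV round-trip is the identity on randomized labeled matrices", {
  for (seed in 1:20) {
    m <- withr::with_seed(seed, {
      nr <- sample(2:12, 1)
      nc <- sample(2:8, 1)
      v <- matrix(rnorm(nr * nc), nr, nc)
      v[runif(length(v)) < 0.15] <- NA
      labeled_matrix(
        v,
        row_labels = sprintf("r%d", seq_len(nr)),
        col_labels = sprintf("c%d", seq_len(nc)),
        row_categories = list(
          category_track("grp", sample(letters[1:3], nr, TRUE)),
          category_track("score", round(rnorm(nr), 3))),
        col_categories = list(
          category_track("cond", sample(c("x", "y"), nc, TRUE))))
    })
    path <- withr::local_tempfile(fileext = ".tsv")
    write_matrix_tsv(m, path)
    m2 <- read_matrix_tsv(path)
    expect_identical(m2$values, m$values)
    expect_identical(m2$row_categories, m$row_categories)
    expect_identical(m2$col_categories, m$col_categories)
  }
})

test_that("parsing preserves the full header width", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("\tS1\tS2\tS3\tS4", "G1\t1\t2\t3\t"), path)
  m <- read_matrix_tsv(path)
  expect_equal(ncol(m$values), 4L)
  expect_true(is.na(m$values[1, 4]))
})

test_that("block-dialect category headers round-trip both kinds of track", {
  m <- labeled_matrix(
    matrix(1:6, 2, 3),
    row_labels = c("p1", "p2"), col_labels = c("a", "b", "c"),
    row_categories = list(category_track("type", c("K", "L"))),
    col_categories = list(
      category_track("run", c("r1", "r1", "r2")),
      category_track("number in clust", c(3, 7, 2))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, path)
  m2 <- read_matrix_tsv(path)
  expect_identical(m2$col_categories, m$col_categories)
  expect_equal(get_track(m2, "columns", "number in clust")$kind, "numeric")
})
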