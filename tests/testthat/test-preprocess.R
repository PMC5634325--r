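test_that("zscore centers and scales rows, with the sd=0 convention", {
  m <- labeled_matrix(rbind(c(1, 2, 3), c(5, 5, 5)))
  z <- zscore(m, "rows")
  expect_equal(unname(z$values[1, ]), c(-1, 0, 1))
  expect_equal(unname(z$values[2, ]), c(0, 0, 0))
})

test_that("zscore normalizes every row to mean 0 sd 1 and is idempotent", {
  m <- labeled_matrix(withr::with_seed(4, matrix(rnorm(200, 5, 3), 20, 10)))
  z <- zscore(m, "rows")
  expect_equal(unname(rowMeans(z$values)), rep(0, 20), tolerance = 1e-9)
  expect_equal(unname(apply(z$values, 1, sd)), rep(1, 20), tolerance = 1e-9)
  z2 <- zscore(z, "rows")
  expect_equal(z2$values, z$values, tolerance = 1e-9)
})

test_that("zscore preserves the missingness pattern", {
  v <- withr::with_seed(9, matrix(rnorm(60), 6, 10))
  v[c(2, 17, 40)] <- NA
  z <- zscore(labeled_matrix(v), "columns")
  expect_identical(unname(is.na(z$values)), is.na(v))
})

test_that("quantile normalization maps columns onto the per-rank mean", {
  m <- labeled_matrix(cbind(c(1, 3, 5), c(2, 4, 8)))
  q <- quantile_normalize(m, "columns")
  expect_equal(unname(q$values), cbind(c(1.5, 3.5, 6.5), c(1.5, 3.5, 6.5)))

  ident <- labeled_matrix(cbind(c(2, 1, 7), c(2, 1, 7)))
  expect_equal(quantile_normalize(ident, "columns")$values, ident$values)
})

test_that("quantile-normalized columns share sorted values and rank order", {
  m <- labeled_matrix(withr::with_seed(11, matrix(rexp(120), 30, 4)))
  q <- quantile_normalize(m, "columns")
  sorted <- apply(q$values, 2, sort)
  for (j in 2:4) expect_equal(sorted[, j], sorted[, 1])
  for (j in 1:4) {
    expect_equal(order(q$values[, j]), order(m$values[, j]))
  }
  expect_error(quantile_normalize(
    labeled_matrix(cbind(c(1, NA), c(2, 3)))), "missing")
})

test_that("median-reference quantile normalization uses per-rank medians", {
  m <- labeled_matrix(cbind(c(1, 3, 5), c(2, 4, 8), c(0, 30, 60)))
  q <- quantile_normalize(m, "columns", reference = "median")
  expect_equal(unname(q$values[, 1]), c(1, 4, 8))
  sorted <- apply(q$values, 2, sort)
  for (j in 2:3) expect_equal(sorted[, j], sorted[, 1])
})

test_that("filter_top keeps exactly n vectors, stably on ties", {
  m <- labeled_matrix(withr::with_seed(2, matrix(rnorm(1000 * 5), 1000, 5)))
  expect_equal(nrow(filter_top(m, "variance", n = 250)$values), 250L)
  expect_warning(big <- filter_top(m, "variance", n = 2000), "clamped")
  expect_equal(dim(big$values), dim(m$values))

  ties <- labeled_matrix(matrix(rep(c(1, 2, 3), 6), 6, 3, byrow = TRUE),
                         row_labels = sprintf("t%d", 1:6))
  kept <- filter_top(ties, "variance", n = 3)
  expect_equal(rownames(kept$values), c("t1", "t2", "t3"))
})

test_that("filter_top retains vectors whose metric dominates the dropped", {
  for (seed in 1:10) {
    m <- labeled_matrix(withr::with_seed(seed, matrix(rnorm(240), 24, 10)))
    kept <- filter_top(m, "sum", n = 7)
    vals <- rowSums(m$values)
    kept_vals <- vals[rownames(kept$values)]
    dropped <- vals[setdiff(names(vals), rownames(kept$values))]
    expect_true(min(kept_vals) >= max(dropped))
    expect_equal(nrow(filter_top(m, "sum", fraction = 0.3)$values),
                 ceiling(0.3 * 24))
  }
})

test_that("filter_missing drops rows strictly above the tolerance", {
  v <- matrix(rnorm(11 * 10), 11, 10)
  for (i in 1:11) v[i, seq_len(i - 1)] <- NA    # rows with 0..10 missing
  m <- labeled_matrix(v)
  kept <- filter_missing(m, 7, "rows")
  expect_equal(nrow(kept$values), 8L)
  expect_equal(max(rowSums(is.na(kept$values))), 7)
  expect_equal(dim(filter_missing(m, 10, "rows")$values), dim(v))
  expect_equal(nrow(filter_missing(m, 0, "rows")$values), 1L)
})

test_that("filter_missing never removes a row within tolerance", {
  for (seed in 1:10) {
    v <- withr::with_seed(seed, {
      x <- matrix(rnorm(15 * 8), 15, 8)
      x[runif(length(x)) < 0.3] <- NA
      x
    })
    m <- labeled_matrix(v)
    tol <- seed %% 5
    kept <- filter_missing(m, tol, "rows")
    expect_setequal(as.character(rownames(kept$values)),
                    rownames(m$values)[rowSums(is.na(v)) <= tol])
  }
})

test_that("ratio_to_reference divides by the mapped run reference", {
  m <- labeled_matrix(cbind(s1 = c(2, 4), ref = c(1, 2)),
                      row_labels = c("p1", "p2"))
  r <- ratio_to_reference(m, c(s1 = "ref"))
  expect_equal(unname(r$values[, "s1"]), c(2, 2))
  expect_equal(colnames(r$values), "s1")

  zero <- labeled_matrix(cbind(s1 = c(2, 4), ref = c(0, 2)))
  rz <- ratio_to_reference(zero, c(s1 = "ref"))
  expect_true(is.na(rz$values[1, 1]))
  expect_equal(rz$values[2, 1], 2)
})

test_that("per-run reference mapping routes each sample to its own run", {
  v <- withr::with_seed(5, matrix(rlnorm(7 * 9), 7, 9))
  cols <- c("a1", "a2", "b1", "b2", "c1", "c2", "refA", "refB", "refC")
  m <- labeled_matrix(v, col_labels = cols)
  mapping <- c(a1 = "refA", a2 = "refA", b1 = "refB", b2 = "refB",
               c1 = "refC", c2 = "refC")
  r <- ratio_to_reference(m, mapping)
  for (s in names(mapping)) {
    expect_equal(r$values[, s],
                 m$values[, s] / m$values[, mapping[[s]]],
                 ignore_attr = TRUE)
  }
  expect_error(ratio_to_reference(m, mapping[-1]), "without a reference")
})
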