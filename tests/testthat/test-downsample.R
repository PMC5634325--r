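make_blobs <- function(n_per = 200, sep = 20, seed = 5) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * 2), n_per),
               matrix(rnorm(n_per * 2) + sep, n_per))
    labeled_matrix(x, row_categories = list(
      category_track("blob", rep(c("alpha", "beta"), each = n_per))))
  })
}

test_that("k = n gives singleton clusters equal to the observations", {
  m <- labeled_matrix(withr::with_seed(3, matrix(rnorm(20), 10, 2)))
  ds <- kmeans_downsample(m, 10, seed = 1)
  expect_equal(sort(ds$sizes), rep(1L, 10))
  expect_equal(sort(unname(ds$centroids$values[, 1])),
               sort(unname(m$values[, 1])))
})

test_that("cluster sizes always sum to the number of observations", {
  for (seed in 1:5) {
    m <- labeled_matrix(withr::with_seed(seed, matrix(rnorm(300), 100, 3)))
    k <- c(2, 5, 17, 50, 100)[seed]
    ds <- kmeans_downsample(m, k, seed = seed)
    expect_equal(sum(ds$sizes), 100L)
    expect_equal(
      sum(get_track(ds$centroids, "rows", "number in clust")$entries), 100)
    expect_equal(nrow(ds$centroids$values), k)
    expect_true(all(ds$sizes > 0))
  }
})

test_that("well-separated blobs recover planted labels in majority tracks", {
  m <- make_blobs()
  ds <- kmeans_downsample(m, 2, seed = 11)
  maj <- get_track(ds$centroids, "rows", "Majority-blob")$entries
  expect_setequal(maj, c("alpha", "beta"))
  # each cluster is pure, so majorities equal every member's planted label
  for (j in 1:2) {
    expect_equal(length(unique(
      get_track(m, "rows", "blob")$entries[ds$membership == j])), 1L)
  }
  # independent check: stats::kmeans finds the same two pure clusters
  km <- withr::with_seed(11, stats::kmeans(m$values, 2))
  conf <- table(km$cluster, ds$membership)
  expect_equal(sort(as.vector(conf)), c(0L, 0L, 200L, 200L))
})

test_that("Lloyd centroids equal their members' means", {
  m <- labeled_matrix(withr::with_seed(6, matrix(rnorm(400), 100, 4)))
  ds <- kmeans_downsample(m, 8, seed = 2, algorithm = "lloyd")
  for (j in 1:8) {
    mem <- which(ds$membership == j)
    expect_equal(unname(ds$centroids$values[j, ]),
                 unname(colMeans(m$values[mem, , drop = FALSE])),
                 tolerance = 1e-7)
  }
})

test_that("downsampling is bit-reproducible given the seed", {
  m <- labeled_matrix(withr::with_seed(7, matrix(rnorm(600), 200, 3)))
  a <- kmeans_downsample(m, 12, seed = 42, algorithm = "minibatch")
  b <- kmeans_downsample(m, 12, seed = 42, algorithm = "minibatch")
  expect_identical(a$centroids$values, b$centroids$values)
  expect_identical(a$membership, b$membership)
  c_ <- kmeans_downsample(m, 12, seed = 43, algorithm = "minibatch")
  expect_false(identical(a$centroids$values, c_$centroids$values))
})

test_that("numeric tracks propagate as per-cluster means", {
  m <- make_blobs(n_per = 50)
  m$row_categories <- c(m$row_categories,
                        list(category_track("depth",
                                            rep(c(1, 3), each = 50))))
  ds <- kmeans_downsample(m, 2, seed = 3)
  dep <- get_track(ds$centroids, "rows", "depth")$entries
  expect_setequal(dep, c(1, 3))   # pure clusters -> exact planted means
})

test_that("majority ties break to the lexicographically smallest value", {
  m <- labeled_matrix(matrix(c(0, 0, 0, 0), 4, 1),
                      row_categories = list(
                        category_track("flag", c("z", "a", "z", "a"))))
  ds <- kmeans_downsample(m, 1, seed = 1)
  expect_equal(get_track(ds$centroids, "rows", "Majority-flag")$entries, "a")
})

test_that("k exceeding the row count errors", {
  m <- labeled_matrix(matrix(rnorm(10), 5, 2))
  expect_error(kmeans_downsample(m, 6), "exceeds")
})

test_that("random_subsample draws per group, preserving order", {
  m <- make_blobs(n_per = 500)
  s <- random_subsample(m, 40, "blob", seed = 9)
  expect_equal(unname(table(get_track(s, "rows", "blob")$entries)),
               c(40L, 40L), ignore_attr = TRUE)
  # original relative order preserved
  idx <- match(rownames(s$values), rownames(m$values))
  expect_false(is.unsorted(idx))
  # determinism
  expect_identical(random_subsample(m, 40, "blob", seed = 9)$values,
                   s$values)
  expect_false(identical(random_subsample(m, 40, "blob", seed = 10)$values,
                         s$values))
  # n_per_group beyond group sizes keeps everything
  expect_equal(dim(random_subsample(m, 10000, "blob", seed = 1)$values),
               dim(m$values))
  expect_error(random_subsample(m, 5, "nope", seed = 1), "no rows track")
})

test_that("transfer_labels conserves per-label counts", {
  membership <- stats::setNames(c(1L, 1L, 1L, 2L, 2L),
                                sprintf("cell%d", 1:5))
  out <- transfer_labels(membership, c("T-cell", "Monocyte"))
  expect_equal(unname(out), c("T-cell", "T-cell", "T-cell",
                              "Monocyte", "Monocyte"))
  expect_equal(names(out), names(membership))

  withr::with_seed(13, {
    mem <- stats::setNames(sample.int(5, 50, TRUE), sprintf("c%d", 1:50))
    labs <- sprintf("type-%d", 1:5)
    res <- transfer_labels(mem, labs)
    tally <- table(res)
    for (j in 1:5) {
      expect_equal(unname(tally[labs[j]]), sum(mem == j),
                   ignore_attr = TRUE)
    }
  })
  expect_error(transfer_labels(c(a = 1L, b = 3L), c("x", "y")),
               "unlabeled cluster")
})
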