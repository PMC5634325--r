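test_that("cosine distances match closed forms", {
  m <- labeled_matrix(rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1),
                            d = c(2, 0)))
  d <- pairwise_distance(m, "rows", "cosine")
  expect_equal(d["a", "b"], 1)
  expect_equal(d["a", "c"], 1 - 1 / sqrt(2))
  expect_equal(d["a", "d"], 0)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("zero-norm vectors follow the declared cosine policy", {
  m <- labeled_matrix(rbind(z1 = c(0, 0), z2 = c(0, 0), x = c(1, 2)))
  d <- pairwise_distance(m, "rows", "cosine")
  expect_equal(d["z1", "z2"], 0)
  expect_equal(d["z1", "x"], 1)
})

test_that("cosine distance is bounded, [0,1] for non-negative data", {
  for (seed in 1:20) {
    m <- labeled_matrix(withr::with_seed(seed, matrix(rnorm(48), 8, 6)))
    d <- pairwise_distance(m, "rows", "cosine")
    expect_true(all(d >= 0 - 1e-12) && all(d <= 2 + 1e-12))
    mp <- labeled_matrix(abs(m$values))
    dp <- pairwise_distance(mp, "rows", "cosine")
    expect_true(all(dp <= 1 + 1e-12))
  }
})

test_that("the worked 3-point UPGMA example merges at 1 then 4.5", {
  d <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t <- linkage(d, "average")
  expect_equal(t$heights, c(1, 4.5))
  expect_equal(t$merges[1, ], c(-1L, -2L))
  expect_equal(t$leaf_order, c(1L, 2L, 3L))

  g <- slice_groups(t, c(0.5, 1))
  expect_equal(unname(g$assignments[, 1]), c(1L, 1L, 2L))
  expect_equal(unname(g$assignments[, 2]), c(1L, 1L, 1L))
})

test_that("a single leaf yields an empty merge list", {
  t <- linkage(matrix(0, 1, 1))
  expect_equal(nrow(t$merges), 0L)
  expect_equal(t$leaf_order, 1L)
})

test_that("linkage matches the brute-force agglomeration oracle", {
  for (seed in 1:40) {
    n <- withr::with_seed(seed, sample(3:8, 1))
    d <- random_distance_matrix(n, seed)
    for (method in c("average", "single", "complete")) {
      t <- linkage(d, method)
      oracle <- brute_force_agglomerate(d, method)
      expect_equal(t$heights, oracle$heights, tolerance = 1e-12)
      got <- tree_partitions(t)
      for (s in seq_along(got)) {
        expect_identical(got[[s]],
                         canon_partition(oracle$partitions[[s]]))
      }
    }
  }
})

test_that("average-linkage heights agree with stats::hclust", {
  for (seed in 41:55) {
    d <- random_distance_matrix(withr::with_seed(seed, sample(5:20, 1)),
                                seed)
    t <- linkage(d, "average")
    h <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(t$heights, h$height, tolerance = 1e-10)
  }
})

test_that("linkage rejects invalid distance input", {
  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(linkage(bad), "not symmetric")
  expect_error(linkage(matrix(c(0, -1, -1, 0), 2)), "negative")
})

test_that("leaf ordering puts the smallest-index subtree first", {
  # heights force ((C,D),(A,B)) structure; C (index 3) vs A (index 1):
  # the A-B subtree must come first
  d <- matrix(1, 4, 4)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.2
  d[3, 4] <- d[4, 3] <- 0.1
  t <- linkage(d, "average")
  expect_equal(t$leaf_order, c(1L, 2L, 3L, 4L))
})

test_that("slice fractions below the first merge give singletons", {
  d <- random_distance_matrix(6, 7)
  t <- linkage(d)
  eps <- t$heights[1] / max(t$heights) * 0.5
  g <- slice_groups(t, c(eps, 1))
  expect_equal(length(unique(g$assignments[, 1])), 6L)
  expect_equal(length(unique(g$assignments[, 2])), 1L)
})

test_that("group ids are numbered by leaf order of first member", {
  for (seed in 1:10) {
    d <- random_distance_matrix(8, 100 + seed)
    t <- linkage(d)
    g <- slice_groups(t, c(0.4, 0.8))
    for (li in 1:2) {
      ids_in_leaf_order <- g$assignments[t$leaf_order, li]
      expect_equal(unique(ids_in_leaf_order),
                   seq_len(max(ids_in_leaf_order)))
    }
  }
})

test_that("group refinement is monotone across fractions", {
  for (seed in 1:60) {
    n <- withr::with_seed(seed, sample(4:16, 1))
    t <- linkage(random_distance_matrix(n, 200 + seed))
    g <- slice_groups(t, seq(0.1, 1, by = 0.1))
    for (li in 1:9) {
      fine <- g$assignments[, li]
      coarse <- g$assignments[, li + 1]
      expect_true(all(tapply(coarse, fine,
                             function(x) length(unique(x)) == 1)))
    }
    expect_equal(length(unique(g$assignments[, 10])), 1L)
  }
})

test_that("group count at a cut equals leaves minus merges below it", {
  for (seed in 1:15) {
    n <- withr::with_seed(seed, sample(5:12, 1))
    t <- linkage(random_distance_matrix(n, 300 + seed))
    hmax <- max(t$heights)
    mids <- (t$heights[-1] + t$heights[-length(t$heights)]) / 2
    fracs <- unique(pmin(pmax(mids / hmax, 1e-9), 1))
    fracs <- fracs[!fracs %in% (t$heights / hmax)]
    if (!length(fracs)) next
    fracs <- sort(fracs)
    g <- slice_groups(t, fracs)
    for (li in seq_along(fracs)) {
      below <- sum(t$heights <= fracs[li] * hmax)
      expect_equal(length(unique(g$assignments[, li])), n - below)
    }
  }
})

test_that("rank orders sort by metric descending with stable ties", {
  m <- labeled_matrix(rbind(r1 = c(1, 1, 1), r2 = c(5, 2, 3),
                            r3 = c(3, 2, 2)),
                      col_labels = c("b", "A", "c"))
  t_r <- linkage(pairwise_distance(m, "rows"))
  t_c <- linkage(pairwise_distance(m, "columns"))
  ro <- rank_orders(m, t_r, t_c)
  expect_equal(ro$rows$sum, c(2L, 3L, 1L))        # sums 3, 10, 7
  expect_equal(ro$cols$alphabetical, c(2L, 1L, 3L))
  expect_equal(ro$rows$cluster, t_r$leaf_order)

  ties <- labeled_matrix(rbind(a = c(1, 2), b = c(2, 1), c = c(0, 3)))
  tt <- linkage(pairwise_distance(ties, "rows"))
  tc <- linkage(pairwise_distance(ties, "columns"))
  ro2 <- rank_orders(ties, tt, tc)
  expect_equal(ro2$rows$sum, c(1L, 2L, 3L))       # equal sums keep order
})

test_that("similarity matrices are 1 - distance with unit diagonal", {
  m <- labeled_matrix(rbind(a = c(1, 0), b = c(1, 1)))
  s <- similarity_matrix(m, "rows")
  expect_equal(s$values["a", "b"], 1 / sqrt(2))
  expect_equal(unname(diag(s$values)), c(1, 1))

  m2 <- labeled_matrix(withr::with_seed(8, matrix(rnorm(60), 10, 6)),
                       row_categories = list(
                         category_track("g", rep(c("x", "y"), 5))))
  s2 <- similarity_matrix(m2, "rows")
  d2 <- pairwise_distance(m2, "rows")
  expect_equal(unname(s2$values), unname(1 - d2))
  expect_length(s2$col_categories, 1)   # axis tracks copied to both axes
})
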