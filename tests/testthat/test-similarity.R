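test_that("Jaccard-Needham measures follow the match-count definition", {
  s <- match_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unname(s), c(1L, 1L, 1L, 1L))
  j <- jaccard_needham(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(j$similarity, 1 / 3)
  expect_equal(j$dissimilarity, 2 / 3)

  j <- jaccard_needham(c(1, 0, 1), c(1, 0, 1))
  expect_equal(j$similarity, 1)
  expect_equal(j$dissimilarity, 0)

  j <- jaccard_needham(c(1, 0), c(0, 1))
  expect_equal(j$similarity, 0)
  expect_equal(j$dissimilarity, 1)

  # degenerate all-zero pair is treated as identical
  j <- jaccard_needham(c(0, 0), c(0, 0))
  expect_equal(j$similarity, 1)
  expect_equal(j$dissimilarity, 0)
})

test_that("similarity and dissimilarity sum to one", {
  set.seed(11)
  for (rep in 1:200) {
    z1 <- sample(0:1, 12, replace = TRUE)
    z2 <- sample(0:1, 12, replace = TRUE)
    j <- jaccard_needham(z1, z2)
    expect_equal(j$similarity + j$dissimilarity, 1)
    s <- match_counts(z1, z2)
    expect_equal(sum(s), 12L)
  }
})

test_that("the distance matrix equals brute-force recomputation", {
  set.seed(5)
  m <- matrix(sample(0:1, 15 * 8, replace = TRUE), 15, 8)
  m[3, ] <- m[1, ]  # a duplicated pair
  d <- pairwise_distances(m)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 15))
  expect_equal(d[1, 3], 0)
  for (i in 1:15) for (j in 1:15) {
    expect_equal(d[i, j], jaccard_needham(m[i, ], m[j, ])$dissimilarity)
  }
  # Jaccard distance is a metric: triangle inequality on all triples
  for (i in 1:15) for (j in 1:15) for (k in 1:15) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("density-based clustering recovers planted partitions", {
  # noiseless duplicates: even the smallest min_cluster_size separates them
  pc0 <- planted_clusters(2, 10, 30, 0, seed = 3)
  lab0 <- cluster_attractors(pairwise_distances(pc0$vectors), 2)
  expect_true(same_partition(pc0$labels, lab0))

  # with bit flips, the cluster size prior matches the planted design
  for (p in c(0.02, 0.05)) {
    pc <- planted_clusters(3, 10, 40, p, seed = 7)
    lab <- cluster_attractors(pairwise_distances(pc$vectors), 8)
    expect_true(all(lab > 0))
    expect_true(same_partition(pc$labels, lab))
  }

  m <- matrix(1L, 6, 8)
  expect_equal(unique(cluster_attractors(pairwise_distances(m), 2)), 1L)
  expect_error(cluster_attractors(pairwise_distances(m), 1), "min_cluster_size")
})

test_that("clustering is deterministic and labels noise distinctly", {
  d <- pairwise_distances(bundled_table)
  l1 <- cluster_attractors(d, 2)
  l2 <- cluster_attractors(d, 2)
  expect_identical(l1, l2)
  expect_true(all(l1 >= 0))
  # the bundled model yields a small number of clusters plus noise
  expect_gt(length(unique(l1[l1 > 0])), 1)
  expect_lt(length(unique(l1[l1 > 0])), nrow(bundled_table$profiles) / 2)
})

test_that("category-cluster correlations behave like Pearson r", {
  cm <- rbind(a = c(0.2, 0.8, 0.4, 0.9), b = c(0.9, 0.1, 0.8, 0.3))
  colnames(cm) <- paste0("n", 1:4)
  r <- category_cluster_correlation(cm, cm)
  expect_equal(unname(diag(r)), c(1, 1))
  comp <- 1 - cm
  r2 <- category_cluster_correlation(cm, comp)
  expect_equal(unname(diag(r2)), c(-1, -1))
  expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
  flat <- rbind(z = rep(0.5, 4))
  colnames(flat) <- paste0("n", 1:4)
  expect_warning(category_cluster_correlation(flat, cm), "zero-variance")
})
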