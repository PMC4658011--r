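test_that("z-scoring uses the sample convention and drops degenerate columns", {
  df <- data.frame("parenchyma PE mean" = c(1, 2, 3),
                   "parenchyma PE std" = c(5, 5, 5),
                   label = c(0, 1, 1), check.names = FALSE)
  tab <- suppressMessages(feature_table(df, drop_constant = FALSE))
  Z <- suppressWarnings(zscore_normalize(tab, "bpe"))
  expect_equal(as.vector(Z[, "parenchyma PE mean"]), c(-1, 0, 1))
  expect_false("parenchyma PE std" %in% colnames(Z))
  # all-degenerate scope is an error
  df2 <- data.frame("parenchyma PE std" = rep(1, 4), label = c(0, 0, 1, 1),
                    check.names = FALSE)
  tab2 <- feature_table(df2, drop_constant = FALSE)
  expect_error(suppressWarnings(zscore_normalize(tab2, "bpe")), "zero variance")
  # output columns are standardized to machine precision
  tab3 <- tiny_table(seed = 5)
  Z3 <- zscore_normalize(tab3, "bpe")
  expect_equal(unname(colMeans(Z3)), rep(0, ncol(Z3)), tolerance = 1e-12)
  expect_equal(unname(apply(Z3, 2, sd)), rep(1, ncol(Z3)), tolerance = 1e-12)
})

test_that("well-separated blobs are recovered exactly in every seed", {
  for (s in 1:20) {
    set.seed(s)
    n <- 88
    g <- rep(c(1, 2), c(44, 44))
    X <- matrix(rnorm(n * 4), n, 4) + 5 * (g == 2)
    res <- kmeans_partition(X, k = 2, restarts = 10, seed = s)
    expect_equal(length(unique(paste(res$assignment, g))), 2)
  }
})

test_that("two cases and two partitions give singleton clusters, zero inertia", {
  X <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  res <- kmeans_partition(X, k = 2, restarts = 5, seed = 1)
  expect_identical(sort(as.integer(table(res$assignment))), c(1L, 1L))
  expect_equal(res$inertia, 0)
})

test_that("clustering is deterministic given the seed and label-swap invariant", {
  tab <- tiny_table(seed = 10)
  a <- cluster_bpe(tab, restarts = 10, seed = 3)
  b <- cluster_bpe(tab, restarts = 10, seed = 3)
  expect_identical(a$result$assignment, b$result$assignment)
  # composition reporting does not depend on which index is which
  comp <- a$composition
  flipped <- a$result
  flipped$assignment <- 3L - flipped$assignment
  comp2 <- partition_composition(flipped, tab$label)
  expect_identical(comp$tn_in_enriched, comp2$tn_in_enriched)
  expect_equal(comp$fisher_p, comp2$fisher_p)
})

test_that("k-means on z-scores is invariant to affine column rescaling", {
  tab <- tiny_table(seed = 12)
  df <- as.data.frame(tab)
  cols <- feature_scope(tab, "bpe")
  df[cols[1]] <- df[[cols[1]]] * 40 + 7
  df[cols[2]] <- df[[cols[2]]] * -3
  tab2 <- feature_table(df)
  a <- cluster_bpe(tab, restarts = 10, seed = 5)$result$assignment
  b <- cluster_bpe(tab2, restarts = 10, seed = 5)$result$assignment
  expect_true(all(table(a, b) %in% c(0, as.vector(table(a)))))
})

test_that("partition composition flags extreme and null enrichment", {
  assign_all <- structure(list(assignment = rep(c(1L, 2L), c(11, 77)),
                               inertia = 0, centers = matrix(0, 2, 1),
                               restarts_used = 1L, X = matrix(0, 88, 1)),
                          class = "cluster_result")
  labels <- rep(c(1, 0), c(11, 77))
  comp <- partition_composition(assign_all, labels)
  expect_identical(comp$tn_in_enriched, 11L)
  expect_lt(comp$fisher_p, 0.001)
  # uniform split: no association
  set.seed(2)
  assign_unif <- assign_all
  assign_unif$assignment <- rep(c(1L, 2L), 44)
  comp2 <- partition_composition(assign_unif, sample(labels))
  expect_gt(comp2$fisher_p, 0.05)
  expect_error(partition_composition(assign_all, labels[1:10]), "length")
})

test_that("a strong BPE effect co-clusters most TN cases", {
  wins <- 0L
  for (s in 1:20) {
    tab <- generate_feature_table(feature_table_spec(seed = 3000 + s))
    comp <- cluster_bpe(tab, restarts = 25, seed = s)$composition
    if (comp$tn_in_enriched >= 8) wins <- wins + 1L
  }
  expect_gte(wins, 16)
})
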