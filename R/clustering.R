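#' Z-score normalization of a feature scope
#'
#' Standardizes each selected feature column across cases to mean 0 and
#' sample (n-1) standard deviation 1. Zero-variance columns are dropped
#' with a warning; if every column is degenerate this is an error.
#'
#' @param table a [feature_table()].
#' @param scope feature scope (default the BPE textures, the clustering
#'   input); see [feature_scope()].
#' @return Numeric matrix (cases x features) of z-scores.
#' @export
zscore_normalize <- function(table, scope = "bpe") {
  cols <- feature_scope(table, scope)
  X <- as.matrix(as.data.frame(table)[cols])
  storage.mode(X) <- "double"
  if (nrow(X) < 2L) stop("need at least 2 cases to z-score")
  sg <- apply(X, 2, sd)
  drop <- sg == 0
  if (all(drop)) stop("all columns have zero variance")
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance column(s)")
    X <- X[, !drop, drop = FALSE]
    sg <- sg[!drop]
  }
  scale(X, center = colMeans(X), scale = sg)
}

# k-means++ seeding on rows of X
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    pick <- if (sum(d2) == 0) sample.int(n, 1L)
            else sample.int(n, 1L, prob = d2)
    centers[j, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Two-partition k-means of z-scored features
#'
#' Lloyd's algorithm with Euclidean distance and k-means++ initialization,
#' run `restarts` times; the solution with the lowest within-cluster sum of
#' squares (inertia) is kept. Deterministic given the seed. Partition
#' indices are arbitrary labels.
#'
#' @param X numeric matrix (cases x features), typically from
#'   [zscore_normalize()].
#' @param k number of partitions (default 2).
#' @param restarts independent initializations (default 50).
#' @param seed RNG seed.
#' @return Object of class `cluster_result`: list with `assignment` (length
#'   n), `inertia`, `centers`, `restarts_used` and the input matrix `X`.
#' @export
kmeans_partition <- function(X, k = 2L, restarts = 50L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("fewer cases than partitions")
  set.seed(seed)
  best <- NULL
  used <- 0L
  for (r in seq_len(restarts)) {
    init <- kmeanspp_centers(X, k)
    fit <- tryCatch(
      suppressWarnings(kmeans(X, centers = init, iter.max = 100L,
                              algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(fit) || any(fit$size == 0)) next
    used <- used + 1L
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("k-means produced an empty partition in every restart")
  structure(list(assignment = best$cluster, inertia = best$tot.withinss,
                 centers = best$centers, restarts_used = used, X = X),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cases in %d partitions, inertia %.2f\n",
              length(x$assignment), nrow(x$centers), x$inertia))
  print(table(partition = x$assignment))
  invisible(x)
}

#' Subtype composition of the partitions
#'
#' Cross-tabulates partition assignment against the TN label, identifies
#' the TN-enriched partition (the one with the larger TN fraction) and
#' reports Fisher's exact p as a descriptive measure of association.
#'
#' @param result a [kmeans_partition()] result.
#' @param labels binary labels (1 = TN) aligned to the clustered cases.
#' @return List with the `counts` table, `enriched_partition`,
#'   `tn_in_enriched` (how many TN cases fall in it), `tn_total` and
#'   `fisher_p`.
#' @export
partition_composition <- function(result, labels) {
  stopifnot(inherits(result, "cluster_result"))
  if (length(labels) != length(result$assignment))
    stop("labels and assignments have different lengths")
  tab <- table(partition = result$assignment, tn = labels)
  frac <- tab[, "1"] / rowSums(tab)
  enriched <- as.integer(names(which.max(frac)))
  fp <- if (ncol(tab) == 2L && nrow(tab) == 2L)
    fisher.test(tab)$p.value else NA_real_
  list(counts = tab,
       enriched_partition = enriched,
       tn_in_enriched = sum(labels == 1 & result$assignment == enriched),
       tn_total = sum(labels == 1),
       fisher_p = fp)
}

#' Heatmap of a clustering result
#'
#' Cases-by-features z-score heatmap with cases ordered by partition, the
#' usual visualization of BPE texture signatures. Visualization only; needs
#' the pheatmap package.
#'
#' @param x a [kmeans_partition()] result.
#' @param labels optional binary labels (1 = TN) shown as a case annotation.
#' @param filename optional output file (PNG/PDF per extension).
#' @param ... passed to [pheatmap::pheatmap()].
#' @return The pheatmap object, invisibly.
#' @export
plot.cluster_result <- function(x, labels = NULL, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("the heatmap export needs the 'pheatmap' package")
  ord <- order(x$assignment)
  M <- t(x$X[ord, , drop = FALSE])
  colnames(M) <- paste0("case", ord)
  ann <- data.frame(partition = factor(x$assignment[ord]),
                    row.names = colnames(M))
  if (!is.null(labels)) ann$TN <- factor(labels[ord])
  p <- pheatmap::pheatmap(M, cluster_cols = FALSE, annotation_col = ann,
                          show_colnames = FALSE, filename = filename, ...)
  invisible(p)
}

#' Cluster the BPE textures of a feature table
#'
#' Convenience wrapper: z-score the BPE texture features, run two-partition
#' k-means and report the TN composition of the partitions.
#'
#' @param table a [feature_table()].
#' @param restarts,seed passed to [kmeans_partition()].
#' @return List with `result` (the [kmeans_partition()] fit) and
#'   `composition` (the [partition_composition()] report).
#' @export
cluster_bpe <- function(table, restarts = 50L, seed = 1L) {
  Z <- zscore_normalize(table, scope = "bpe")
  res <- kmeans_partition(Z, k = 2L, restarts = restarts, seed = seed)
  comp <- partition_composition(res, table[[attr(table, "label_col")]])
  list(result = res, composition = comp)
}
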