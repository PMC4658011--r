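## Small numeric helpers ----------------------------------------------------

# Mann-Whitney AUC of scores for the positive class (midranks handle ties)
fast_auc <- function(scores, y) {
  y <- y == 1
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx[sample.int(length(idx))]] <-
      rep_len(sample.int(k), length(idx))
  }
  fold
}

## Chi-squared ranking -------------------------------------------------------

#' Rank features by the chi-squared statistic
#'
#' Each numeric feature is discretized on the training values (default: 10
#' equal-frequency bins; features with few distinct values use those values
#' as bins) and the chi-squared statistic of the bin-by-class contingency
#' table is computed, without continuity correction. Features are ranked by
#' descending statistic; ties keep column order (stable).
#'
#' @param X numeric matrix or data frame of training features.
#' @param y binary labels (0/1).
#' @param bins target number of equal-frequency bins.
#' @return Data frame with `feature`, `statistic`, `p.value`, sorted by
#'   descending statistic.
#' @export
chi2_rank <- function(X, y, bins = 10L) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("chi2_rank needs both classes")
  stat <- pval <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ux <- unique(x)
    g <- if (length(ux) <= bins) {
      factor(x)
    } else {
      br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                            names = FALSE, type = 7))
      if (length(br) < 3) factor(x) else
        cut(x, breaks = br, include.lowest = TRUE)
    }
    tab <- table(g, y)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L) { stat[j] <- 0; pval[j] <- 1; next }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    stat[j] <- unname(ct$statistic)
    pval[j] <- ct$p.value
  }
  out <- data.frame(feature = colnames(X), statistic = stat,
                    p.value = pval, stringsAsFactors = FALSE)
  out[order(-out$statistic), , drop = FALSE]
}

## Linear SVM wrappers -------------------------------------------------------

# fit on a pre-scaled matrix; returns model plus the orientation needed so
# that larger decision values always score the positive class
fit_linear_svm <- function(X, y, cost = 1) {
  yf <- factor(y, levels = c(0, 1))
  m <- e1071::svm(x = X, y = yf, kernel = "linear", cost = cost,
                  scale = FALSE)
  w <- crossprod(m$SV, m$coefs)
  pos_first <- levels(yf)[m$labels[1]] == "1"
  list(w = if (pos_first) w else -w,
       b = if (pos_first) m$rho else -m$rho)
}

svm_decision <- function(fit, X) as.numeric(X %*% fit$w - fit$b)

# mean held-out AUC of the linear SVM over fixed internal folds
subset_cv_auc <- function(X, y, cols, inner, cost) {
  aucs <- rep(NA_real_, length(inner))
  for (f in seq_along(inner)) {
    te <- inner[[f]]
    fit <- fit_linear_svm(X[-te, cols, drop = FALSE], y[-te], cost)
    aucs[f] <- fast_auc(svm_decision(fit, X[te, cols, drop = FALSE]), y[te])
  }
  mean(aucs, na.rm = TRUE)
}

## Sequential forward floating selection -------------------------------------

#' Sequential forward floating feature selection
#'
#' Classic SFFS wrapped around a linear SVM: forward steps add the candidate
#' that maximizes the criterion — the mean held-out AUC of the SVM under
#' internal stratified cross-validation on the training data only — and each
#' forward step is followed by conditional backward steps that remove any
#' feature whose exclusion improves on the best criterion previously seen at
#' that subset size. Search stops at `max_size` or when no candidate
#' improves the criterion.
#'
#' @param X numeric matrix of training features (pre-scaled).
#' @param y binary training labels (0/1).
#' @param candidates column names to search over (e.g. the top of a
#'   [chi2_rank()]); defaults to all columns.
#' @param max_size cap on the subset size.
#' @param inner_folds internal CV folds for the criterion.
#' @param cost SVM regularization parameter.
#' @return Character vector of selected features with attribute `value`
#'   (the criterion of the returned subset).
#' @export
sffs_select <- function(X, y, candidates = colnames(X), max_size = 10L,
                        inner_folds = 5L, cost = 1) {
  X <- as.matrix(X)
  if (!length(candidates)) stop("no candidate features")
  candidates <- intersect(candidates, colnames(X))
  k <- min(inner_folds, min(table(y)))
  fold_id <- stratified_folds(y, max(2L, k))
  inner <- split(seq_along(y), fold_id)
  crit <- function(cols) subset_cv_auc(X, y, cols, inner, cost)
  eps <- 1e-9

  sel <- character(0)
  value <- -Inf
  best_at_size <- rep(-Inf, max_size)
  repeat {
    if (length(sel) >= max_size) break
    rest <- setdiff(candidates, sel)
    if (!length(rest)) break
    vals <- vapply(rest, function(f) crit(c(sel, f)), numeric(1))
    best <- which.max(vals)
    if (length(sel) && vals[best] <= value + eps) break
    sel <- c(sel, rest[best])
    value <- vals[best]
    best_at_size[length(sel)] <- max(best_at_size[length(sel)], value)
    # floating backward: drop features while that beats the best subset
    # previously seen at the smaller size
    while (length(sel) > 2L) {
      drop_vals <- vapply(sel, function(f) crit(setdiff(sel, f)), numeric(1))
      bd <- which.max(drop_vals)
      if (drop_vals[bd] > best_at_size[length(sel) - 1L] + eps) {
        sel <- setdiff(sel, sel[bd])
        value <- drop_vals[bd]
        best_at_size[length(sel)] <- value
      } else break
    }
  }
  structure(sel, value = value)
}

## Nested cross-validated evaluation -----------------------------------------

#' Cross-validation configuration
#'
#' @param folds outer stratified folds (default 10).
#' @param repetitions repeated runs of the full cross-validation, each with a
#'   freshly drawn stratified partition (default 10); summary confidence
#'   intervals are percentile intervals over the repetition means.
#' @param rank_keep features retained after chi-squared ranking (default 30).
#' @param sffs_max_size cap on the SFFS subset size (default 10).
#' @param inner_folds internal folds for the SFFS criterion (default 5).
#' @param cost linear-SVM regularization parameter (default 1).
#' @param seed integer seed governing every random draw of the run.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(folds = 10L, repetitions = 10L, rank_keep = 30L,
                      sffs_max_size = 10L, inner_folds = 5L, cost = 1,
                      seed = 1L) {
  stopifnot(folds >= 2, repetitions >= 1, cost > 0, rank_keep >= 1,
            sffs_max_size >= 1)
  structure(list(folds = as.integer(folds),
                 repetitions = as.integer(repetitions),
                 rank_keep = as.integer(rank_keep),
                 sffs_max_size = as.integer(sffs_max_size),
                 inner_folds = as.integer(inner_folds),
                 cost = cost, seed = as.integer(seed)),
            class = "cv_config")
}

#' Nested cross-validated SVM with fold-encapsulated feature selection
#'
#' Evaluates the full modeling chain under repeated stratified k-fold
#' cross-validation. Within every training fold — and only there — features
#' are ranked by [chi2_rank()], the top `rank_keep` enter [sffs_select()],
#' and a linear SVM is fitted on the selected subset (features standardized
#' by training-fold statistics). The held-out fold is scored with class
#' predictions at the SVM decision boundary (accuracy, sensitivity,
#' specificity) and with raw decision values (AUC). Encapsulating both
#' selection steps inside the fold is what prevents selection bias.
#'
#' @param table a [feature_table()].
#' @param config a [cv_config()].
#' @param scope feature scope passed to [feature_scope()].
#' @return Object of class `cv_result`: list with `folds` (per repetition
#'   x fold metrics), `selected` (per-fold feature subsets), `summary`
#'   (mean and percentile 95% CI per metric), `partition` (n x repetitions
#'   fold assignments, used to verify pairing), `config`, `scope`, `n`.
#' @export
run_nested_cv <- function(table, config = cv_config(),
                          scope = "tumor+bpe") {
  stopifnot(inherits(table, "feature_table"), inherits(config, "cv_config"))
  cols <- feature_scope(table, scope)
  if (length(cols) < 2L) stop("scope leaves fewer than 2 features")
  X0 <- as.matrix(as.data.frame(table)[cols])
  storage.mode(X0) <- "double"
  y <- table[[attr(table, "label_col")]]
  n <- length(y)
  if (min(table(y)) < 2L) stop("need at least 2 cases per class")
  if (min(table(y)) < config$folds)
    warning("a class has fewer cases than folds; ",
            "some test folds will miss it")

  set.seed(config$seed)
  rows <- list(); selected <- list()
  partition <- matrix(NA_integer_, n, config$repetitions)
  ri <- 0L
  for (rep in seq_len(config$repetitions)) {
    fold_id <- stratified_folds(y, config$folds)
    partition[, rep] <- fold_id
    for (f in seq_len(config$folds)) {
      te <- which(fold_id == f)
      tr <- which(fold_id != f)
      if (length(unique(y[tr])) < 2L)
        stop("training fold lost a class; reduce folds")
      Xtr <- X0[tr, , drop = FALSE]
      keep <- apply(Xtr, 2, function(v) diff(range(v)) > 0)
      Xtr <- Xtr[, keep, drop = FALSE]
      mu <- colMeans(Xtr); sg <- apply(Xtr, 2, sd)
      Xtr <- scale(Xtr, center = mu, scale = sg)
      Xte <- scale(X0[te, keep, drop = FALSE], center = mu, scale = sg)

      ranked <- chi2_rank(Xtr, y[tr], bins = 10L)
      cand <- head(ranked$feature, config$rank_keep)
      sel <- sffs_select(Xtr, y[tr], candidates = cand,
                         max_size = config$sffs_max_size,
                         inner_folds = config$inner_folds,
                         cost = config$cost)
      fit <- fit_linear_svm(Xtr[, sel, drop = FALSE], y[tr], config$cost)
      dec <- svm_decision(fit, Xte[, sel, drop = FALSE])
      pred <- as.integer(dec > 0)
      yt <- y[te]
      tp <- sum(pred == 1 & yt == 1); tn <- sum(pred == 0 & yt == 0)
      P <- sum(yt == 1); N <- sum(yt == 0)
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        repetition = rep, fold = f,
        accuracy = (tp + tn) / length(yt),
        sensitivity = if (P > 0) tp / P else NA_real_,
        specificity = if (N > 0) tn / N else NA_real_,
        auc = fast_auc(dec, yt))
      selected[[ri]] <- as.character(sel)
    }
  }
  folds_df <- do.call(rbind, rows)
  summ <- summarize_cv(folds_df)
  structure(list(folds = folds_df, selected = selected, summary = summ,
                 partition = partition, config = config, scope = scope,
                 n = n),
            class = "cv_result")
}

summarize_cv <- function(folds_df) {
  metrics <- c("accuracy", "sensitivity", "specificity", "auc")
  out <- lapply(metrics, function(m) {
    v <- folds_df[[m]]
    rep_means <- tapply(v, folds_df$repetition,
                        function(z) mean(z, na.rm = TRUE))
    ci <- quantile(rep_means, c(0.025, 0.975), names = FALSE)
    data.frame(metric = m, mean = mean(v, na.rm = TRUE),
               ci_lower = ci[1], ci_upper = ci[2])
  })
  do.call(rbind, out)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> scope '%s', n = %d, %d x %d-fold CV\n",
              x$scope, x$n, x$config$repetitions, x$config$folds))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    scale <- if (s$metric[i] == "auc") 1 else 100
    fmt <- if (s$metric[i] == "auc") "  %-12s %.3f (%.3f, %.3f)\n"
           else "  %-12s %.1f (%.1f, %.1f)\n"
    cat(sprintf(fmt, s$metric[i], s$mean[i] * scale,
                s$ci_lower[i] * scale, s$ci_upper[i] * scale))
  }
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) object$summary

#' Paired Wilcoxon signed-rank comparison of two cross-validation results
#'
#' Tests, per metric, whether the paired per-fold values of two models
#' differ. The two results must come from identical partitions (same table,
#' folds, repetitions and seed) so the fold values pair; this is verified
#' against the stored partitions.
#'
#' @param a,b two [run_nested_cv()] results on the same partitions.
#' @param metrics metrics to compare.
#' @return Data frame with metric, the signed-rank statistic, `p.value` and
#'   the number of informative (non-zero-difference) pairs.
#' @export
compare_models <- function(a, b, metrics = c("accuracy", "sensitivity",
                                             "specificity", "auc")) {
  stopifnot(inherits(a, "cv_result"), inherits(b, "cv_result"))
  if (!identical(dim(a$partition), dim(b$partition)) ||
      !identical(a$partition, b$partition))
    stop("results are not paired: partitions differ (use one seed and table)")
  out <- lapply(metrics, function(m) {
    w <- wilcoxon_signed_rank(a$folds[[m]], b$folds[[m]])
    data.frame(metric = m, statistic = w$statistic, p.value = w$p.value,
               n_pairs = w$n)
  })
  do.call(rbind, out)
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped (if all
#' differences are zero the p-value is 1). For up to `exact_max` informative
#' pairs the exact conditional null distribution of the statistic is
#' enumerated by dynamic programming over the observed (tie-adjusted,
#' doubled-to-integer) ranks; beyond that, the normal approximation with
#' tie correction and continuity correction is used.
#'
#' @param x,y paired samples (`y` omitted: `x` are the differences).
#' @param exact_max largest number of pairs for the exact distribution.
#' @return List with `statistic` (V, sum of positive ranks), `p.value`,
#'   `n` informative pairs and `method`.
#' @examples
#' wilcoxon_signed_rank(rep(1, 10), rep(0, 10))$p.value  # 2/1024
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p.value = 1, n = 0L, method = "degenerate"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))          # doubled midranks are integers
    total <- sum(r2)
    dp <- numeric(total + 1); dp[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), dp[seq_len(total + 1 - rr)])
      dp <- dp + shifted
    }
    dp <- dp / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(dp[seq_len(v2 + 1)])
    p_ge <- sum(dp[(v2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = V, p.value = p, n = n, method = method)
}

#' Feature selection frequency across cross-validation folds
#'
#' Percentage of all repetition-by-fold training folds in which each feature
#' survived selection — a simple indicator of a feature's prevalence in the
#' fitted models.
#'
#' @param result a [run_nested_cv()] result.
#' @param floor report only features selected in at least this percentage of
#'   folds (default 0; 50 reproduces a "majority of folds" display).
#' @return Data frame with `feature` and `frequency` (percent), sorted
#'   descending.
#' @export
selection_frequency <- function(result, floor = 0) {
  stopifnot(inherits(result, "cv_result"))
  total <- length(result$selected)
  counts <- table(unlist(result$selected))
  out <- data.frame(feature = names(counts),
                    frequency = 100 * as.numeric(counts) / total,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out[out$frequency >= floor, , drop = FALSE]
}
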