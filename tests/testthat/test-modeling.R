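test_that("chi-squared statistic is exact on a perfectly aligned binary feature", {
  X <- matrix(rep(c(0, 1), each = 20), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c(0, 1), each = 20)
  r <- chi2_rank(X, y)
  expect_equal(r$statistic, 40)
  expect_error(chi2_rank(X, rep(1, 40)), "both classes")
})

test_that("independent features rarely reach chi-squared significance", {
  sig <- sapply(1:50, function(s) {
    set.seed(s)
    x <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "f"))
    y <- rbinom(1000, 1, 0.5)
    chi2_rank(x, y)$p.value < 0.05
  })
  expect_gte(mean(!sig), 0.9)
})

test_that("ranking decorrelates under label permutation", {
  tab <- tiny_table(seed = 3, n = 120)
  cols <- feature_scope(tab, c("clinical", "tumor_texture", "bpe_texture"))
  X <- as.matrix(as.data.frame(tab)[cols])
  y <- tab$label
  r0 <- chi2_rank(X, y)
  rho <- sapply(1:20, function(s) {
    set.seed(100 + s)
    rp <- chi2_rank(X, sample(y))
    cor(match(colnames(X), r0$feature), match(colnames(X), rp$feature),
        method = "spearman")
  })
  expect_lt(mean(abs(rho)), 0.35)
})

test_that("rank-based AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- rnorm(60) + y
    expect_equal(radbpe:::fast_auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  }
})

test_that("SFFS keeps a dominant feature and matches exhaustive size-1 search", {
  set.seed(11)
  n <- 120
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(sep = y * 10 + rnorm(n, sd = 0.1),
             matrix(rnorm(n * 8), n, 8,
                    dimnames = list(NULL, paste0("noise", 1:8))))
  sel <- sffs_select(X, y)
  expect_identical(as.character(sel)[1], "sep")
  # with max_size = 1 the result equals the exhaustive single-feature argmax
  set.seed(21)
  Xr <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  Xr[, 3] <- Xr[, 3] + 0.8 * y
  set.seed(31)
  s1 <- sffs_select(Xr, y, max_size = 1)
  best <- which.max(apply(Xr, 2, function(v) radbpe:::fast_auc(v, y)))
  expect_identical(as.character(s1), names(best))
})

test_that("SFFS assembles a complementary pair hidden by shared variance", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 400
    y <- rep(c(0, 1), each = n / 2)
    z <- rnorm(n, sd = 3)                       # shared nuisance
    X <- cbind(a = z + 0.5 * y + rnorm(n, sd = 0.3),
               b = z - 0.5 * y + rnorm(n, sd = 0.3),
               matrix(rnorm(n * 8), n, 8,
                      dimnames = list(NULL, paste0("noise", 1:8))))
    sel <- sffs_select(X, y, max_size = 5)
    if (all(c("a", "b") %in% sel)) hits <- hits + 1L
  }
  expect_gte(hits, 16)
})

test_that("nested CV is deterministic and refuses unpaired comparisons", {
  tab <- tiny_table(seed = 2)
  cfg <- cv_config(folds = 5, repetitions = 2, rank_keep = 6,
                   sffs_max_size = 3, seed = 7)
  a <- run_nested_cv(tab, cfg, scope = "bpe_texture")
  b <- run_nested_cv(tab, cfg, scope = "bpe_texture")
  expect_identical(a$folds, b$folds)
  expect_identical(a$selected, b$selected)
  c2 <- run_nested_cv(tab, cv_config(folds = 5, repetitions = 2,
                                     rank_keep = 6, sffs_max_size = 3,
                                     seed = 8), scope = "bpe_texture")
  expect_error(compare_models(a, c2), "not paired")
})

test_that("confusion-derived metrics are internally consistent", {
  tab <- tiny_table(seed = 4)
  cfg <- cv_config(folds = 5, repetitions = 1, rank_keep = 6,
                   sffs_max_size = 3, seed = 1)
  r <- run_nested_cv(tab, cfg, scope = "tumor+bpe")
  f <- r$folds
  expect_true(all(f$accuracy >= 0 & f$accuracy <= 1))
  expect_true(all(f$auc >= 0 & f$auc <= 1, na.rm = TRUE))
  s <- r$summary
  expect_true(all(s$ci_lower <= s$mean + 1e-12 &
                  s$mean <= s$ci_upper + 1e-12))
  # every case lands in exactly one test fold per repetition
  expect_true(all(table(r$partition[, 1]) >= 1))
  expect_identical(length(r$partition[, 1]), nrow(tab))
})

test_that("truncation by the ranking filter makes pure noise irrelevant", {
  tab <- tiny_table(seed = 6)
  cfg <- cv_config(folds = 5, repetitions = 1, rank_keep = 3,
                   sffs_max_size = 2, seed = 3)
  a <- run_nested_cv(tab, cfg, scope = "bpe_texture")
  # append noise columns that chi-squared ranking will truncate away
  df <- as.data.frame(tab)
  set.seed(99)
  for (j in 1:4) df[[paste("parenchyma extra", j)]] <- rnorm(nrow(df)) * 1e-3
  tab2 <- feature_table(df)
  b <- run_nested_cv(tab2, cfg, scope = "bpe_texture")
  expect_equal(a$summary$mean, b$summary$mean, tolerance = 0.02)
})

test_that("signed-rank test: exactness, degeneracy, and agreement with stats", {
  # all ten differences positive: exact two-sided p = 2/1024
  w <- wilcoxon_signed_rank(rep(1, 10), rep(0, 10))
  expect_equal(w$p.value, 2 / 1024)
  expect_identical(w$method, "exact")
  # identical samples: all differences zero
  expect_equal(wilcoxon_signed_rank(1:5, 1:5)$p.value, 1)
  # tie-free case agrees with the reference implementation exactly
  set.seed(12)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(wilcoxon_signed_rank(x, y)$p.value,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  # large-n path agrees with the reference normal approximation
  set.seed(13)
  x <- rnorm(60); y <- rnorm(60, 0.3)
  expect_equal(wilcoxon_signed_rank(x, y)$p.value,
               wilcox.test(x, y, paired = TRUE, exact = FALSE,
                           correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("selection frequency counts folds and honors the display floor", {
  tab <- tiny_table(seed = 8)
  cfg <- cv_config(folds = 5, repetitions = 2, rank_keep = 4,
                   sffs_max_size = 2, seed = 2)
  r <- run_nested_cv(tab, cfg, scope = "bpe_texture")
  sf <- selection_frequency(r)
  expect_true(all(sf$frequency > 0 & sf$frequency <= 100))
  expect_true(all(selection_frequency(r, floor = 50)$frequency >= 50))
  total <- sum(sapply(r$selected, length))
  expect_equal(sum(sf$frequency) / 100 * length(r$selected), total)
})
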