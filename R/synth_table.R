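#' Specify a synthetic radiomic feature table
#'
#' Describes a labeled feature table in the standard lesion-table layout:
#' clinical, densitometric, tumor-texture and BPE-texture
#' feature blocks plus a binary TN label. Features are unit-variance
#' Gaussian with an equicorrelation structure within each block, and every
#' column of a block is shifted between classes by that block's effect size
#' (a standardized mean difference). Defaults mirror a realistic cohort
#' (88 lesions, 11 TN) with the class signal concentrated in the BPE
#' textures (effect 1.5) over the tumor textures and clinical features
#' (effect 0.6); breast density carries a weak effect (0.3).
#'
#' @param n_cases number of lesions.
#' @param prevalence fraction of TN (positive) cases, in (0, 1).
#' @param blocks named list of blocks, each a list with `n` (columns,
#'   >= 1), `effect` (standardized mean difference between classes) and
#'   `rho` (within-block equicorrelation, in [0, 1)). Recognized block
#'   names get conventional lesion-table column names.
#' @param label_mode `"fixed"` draws exactly `round(prevalence * n_cases)`
#'   positives (small-sample reproducibility); `"binomial"` draws each label
#'   independently.
#' @param subtypes also generate `subtype`/`er`/`pr`/`her2` metadata columns
#'   with the cohort's composition (among non-TN: Luminal A, Luminal B and
#'   HER2-only in proportion 45:28:4; ER+ are the luminal cases; PR+ a
#'   63/73 subset of them), enabling the per-subtype task filters.
#' @param seed integer RNG seed.
#' @return An object of class `feature_table_spec`.
#' @seealso [generate_feature_table()]
#' @export
feature_table_spec <- function(n_cases = 88,
                               prevalence = 11 / 88,
                               blocks = list(
                                 clinical      = list(n = 5,  effect = 0.6, rho = 0.3),
                                 density       = list(n = 1,  effect = 0.3, rho = 0),
                                 tumor_texture = list(n = 39, effect = 0.6, rho = 0.3),
                                 bpe_texture   = list(n = 39, effect = 1.5, rho = 0.3)),
                               label_mode = c("fixed", "binomial"),
                               subtypes = TRUE,
                               seed = 1L) {
  label_mode <- match.arg(label_mode)
  if (!(prevalence > 0 && prevalence < 1))
    stop("`prevalence` must be in (0, 1)")
  if (n_cases < 4) stop("`n_cases` too small")
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    stop("`blocks` must be a named list")
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (is.null(b$n) || b$n < 1) stop("block counts must be >= 1")
    if (is.null(b$rho)) blocks[[nm]]$rho <- 0
    else if (b$rho < 0 || b$rho >= 1)
      stop("within-block correlation must be in [0, 1)")
    if (is.null(b$effect)) blocks[[nm]]$effect <- 0
  }
  structure(list(n_cases = as.integer(n_cases), prevalence = prevalence,
                 blocks = blocks, label_mode = label_mode,
                 subtypes = isTRUE(subtypes), seed = as.integer(seed)),
            class = "feature_table_spec")
}

# conventional lesion-table names for the 13 statistics x 3 maps of a compartment
texture_feature_names <- function(compartment, n = 39) {
  maps <- c("rate in", "PE", "SER")
  stats <- c("mean", "std", "skewness", "kurtosis",
             "Energy", "Contrast", "Correlation", "Variance",
             "Homogeneity", "SumMean", "Entropy", "Inertia", "ClusterShade")
  full <- as.vector(t(outer(maps, stats, function(m, s)
    paste(compartment, m, s))))
  if (n <= length(full)) full[seq_len(n)]
  else c(full, paste(compartment, "extra", seq_len(n - length(full))))
}

block_column_names <- function(block, n) {
  switch(block,
    clinical = {
      base <- c("morphology", "mass size", "mass shape",
                "mass margin", "internal enhancement")
      if (n <= 5) base[seq_len(n)] else c(base, paste0("clinical ", 6:n))
    },
    density = if (n == 1) "breast density" else paste("breast density", seq_len(n)),
    tumor_texture = texture_feature_names("tumor", n),
    bpe_texture = texture_feature_names("parenchyma", n),
    paste(block, seq_len(n)))
}

# draw exactly k of n positions (deterministic count), as a 0/1 vector
fixed_count_labels <- function(n, k) {
  y <- integer(n)
  y[sample.int(n, k)] <- 1L
  y
}

#' Generate a synthetic labeled feature table
#'
#' Samples the table described by a [feature_table_spec()]: labels at the
#' stated prevalence, then per block an equicorrelated Gaussian matrix
#' (`X = sqrt(rho) z_block + sqrt(1 - rho) noise`, unit marginal variance)
#' with every column shifted by the block effect size in the TN class.
#' Deterministic given the spec (which includes its seed).
#'
#' @param spec a [feature_table_spec()].
#' @return A [feature_table()] with a `label` column (1 = TN), `case_id`,
#'   and, when `spec$subtypes`, `subtype`/`er`/`pr`/`her2` metadata.
#' @examples
#' tab <- generate_feature_table(feature_table_spec(seed = 7))
#' table(tab$label)
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "feature_table_spec"))
  set.seed(spec$seed)
  n <- spec$n_cases
  k <- max(1L, min(n - 1L, round(spec$prevalence * n)))
  y <- if (spec$label_mode == "fixed") fixed_count_labels(n, k)
       else {
         yy <- rbinom(n, 1L, spec$prevalence)
         # guard the degenerate draw so the table stays two-class
         if (sum(yy) == 0L) yy[sample.int(n, 1L)] <- 1L
         if (sum(yy) == n) yy[sample.int(n, 1L)] <- 0L
         yy
       }

  cols <- list()
  blocks <- character(0)
  for (nm in names(spec$blocks)) {
    b <- spec$blocks[[nm]]
    z <- rnorm(n)
    X <- sqrt(b$rho) * z + sqrt(1 - b$rho) * matrix(rnorm(n * b$n), n, b$n)
    X <- X + b$effect * y
    colnames(X) <- block_column_names(nm, b$n)
    for (j in seq_len(ncol(X))) cols[[colnames(X)[j]]] <- X[, j]
    blocks <- c(blocks, setNames(rep(nm, b$n), colnames(X)))
  }

  df <- data.frame(case_id = sprintf("case_%03d", seq_len(n)),
                   cols, label = y, check.names = FALSE)
  if (spec$subtypes) {
    sub <- rep("TN", n)
    neg <- which(y == 0)
    # cohort composition among non-TN, scaled to the table size
    prop <- c(LumA = 45, LumB = 28, HER2 = 4) / 77
    nA <- round(prop["LumA"] * length(neg))
    nB <- round(prop["LumB"] * length(neg))
    nH <- length(neg) - nA - nB
    sub[neg] <- sample(rep(c("LumA", "LumB", "HER2"), c(nA, nB, nH)))
    lum <- which(sub %in% c("LumA", "LumB"))
    pr <- integer(n)
    if (length(lum))
      pr[sample(lum, round(63 / 73 * length(lum)))] <- 1L
    df$subtype <- sub
    df$er <- as.integer(sub %in% c("LumA", "LumB"))
    df$pr <- pr
    df$her2 <- as.integer(sub == "HER2")
  }
  feature_table(df, blocks = blocks)
}
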