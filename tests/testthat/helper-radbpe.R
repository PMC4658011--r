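# shared fixtures and independent oracles, built in code at test time

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# brute-force 3-D co-occurrence oracle: explicit loops over every voxel and
# every 26-neighborhood offset, with an independently written feature
# computation. Deliberately naive; used only to check the engine.
oracle_glcm_features <- function(levels, mask, G) {
  dm <- dim(levels)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  feats <- matrix(NA_real_, nrow(offs), 9)
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    C <- matrix(0, G, G)
    for (x in seq_len(dm[1])) for (y in seq_len(dm[2]))
      for (z in seq_len(dm[3])) {
        if (!mask[x, y, z]) next
        p <- c(x, y, z) + d
        if (any(p < 1) || any(p > dm)) next
        if (!mask[p[1], p[2], p[3]]) next
        i <- levels[x, y, z]; j <- levels[p[1], p[2], p[3]]
        C[i + 1, j + 1] <- C[i + 1, j + 1] + 1
      }
    n <- sum(C)
    if (n == 0) next
    feats[r, ] <- oracle_features_from_counts(C / n)
  }
  ok <- !is.na(feats[, 1])
  if (!any(ok)) stop("oracle: no pairs")
  colMeans(feats[ok, , drop = FALSE])
}

oracle_features_from_counts <- function(P) {
  G <- nrow(P)
  en <- ctr <- vr <- hom <- sm <- ent <- ine <- cs <- 0
  mux <- muy <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    p <- P[i + 1, j + 1]
    mux <- mux + i * p
    muy <- muy + j * p
  }
  sx2 <- sy2 <- 0
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    p <- P[i + 1, j + 1]
    sx2 <- sx2 + (i - mux)^2 * p
    sy2 <- sy2 + (j - muy)^2 * p
  }
  corr_num <- 0
  mu <- (mux + muy) / 2
  for (i in 0:(G - 1)) for (j in 0:(G - 1)) {
    p <- P[i + 1, j + 1]
    en <- en + p^2
    ctr <- ctr + abs(i - j) * p
    corr_num <- corr_num + (i - mux) * (j - muy) * p
    vr <- vr + (i - mu)^2 * p
    hom <- hom + p / (1 + abs(i - j))
    sm <- sm + 0.5 * (i + j) * p
    if (p > 0) ent <- ent - p * log(p)
    ine <- ine + (i - j)^2 * p
    cs <- cs + (i + j - mux - muy)^3 * p
  }
  corr <- if (sx2 > 0 && sy2 > 0) corr_num / sqrt(sx2 * sy2) else 0
  c(en, ctr, corr, vr, hom, sm, ent, ine, cs)
}

# small noiseless homogeneous phantom used across tests
quiet_phantom <- function(...) {
  generate_dce_phantom(phantom_spec(
    noise_sd = 0, bpe_heterogeneity = list(variance = 0, corr_length = 6),
    ...))
}

# a tiny two-class table for fast modeling tests
tiny_table <- function(seed = 1, n = 60, effect = 2) {
  generate_feature_table(feature_table_spec(
    n_cases = n, prevalence = 0.25,
    blocks = list(clinical = list(n = 2, effect = 0, rho = 0),
                  tumor_texture = list(n = 4, effect = 0, rho = 0),
                  bpe_texture = list(n = 4, effect = effect, rho = 0)),
    subtypes = FALSE, seed = seed))
}
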