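#' First-order statistics of a masked map
#'
#' Sample mean, standard deviation (n-1 denominator), Fisher skewness `g1`
#' and excess kurtosis `g2` (0 for a normal distribution). Moments that need
#' more samples than available — or that are 0/0 on a constant input — are
#' returned as `NA`, never as 0.
#'
#' @param x numeric vector of valid map samples.
#' @return Named numeric vector `mean`, `std`, `skewness`, `kurtosis`.
#' @examples
#' first_order_stats(1:5)
#' @export
first_order_stats <- function(x) {
  x <- as.numeric(x)
  if (!length(x)) stop("no valid samples")
  n <- length(x)
  mu <- mean(x)
  std <- if (n >= 2) sd(x) else NA_real_
  m2 <- mean((x - mu)^2)
  skw <- kur <- NA_real_
  if (m2 > 0) {
    if (n >= 3) skw <- mean((x - mu)^3) / m2^1.5
    if (n >= 4) kur <- mean((x - mu)^4) / m2^2 - 3
  }
  c(mean = mu, std = std, skewness = skw, kurtosis = kur)
}

#' Quantize a map to G gray levels
#'
#' Uniform binning of the in-mask value range into `G` equal-width bins,
#' yielding integer levels `0..G-1` (the maximum maps to `G-1`). Default
#' `G = 8` (3-bit), the rescaling used ahead of co-occurrence analysis.
#' A constant region quantizes to all-zero levels and is flagged.
#'
#' @param map numeric 3-D array.
#' @param mask logical 3-D mask of valid voxels (non-finite map values are
#'   additionally excluded).
#' @param G number of gray levels.
#' @return Object of class `quantized_volume`: list with `levels` (integer
#'   array, NA outside the mask), `G`, `mask`, `bounds`, and
#'   `constant_region` flag.
#' @export
quantize <- function(map, mask, G = 8L) {
  stopifnot(identical(dim(map), dim(mask)), G >= 2)
  G <- as.integer(G)
  valid <- mask & is.finite(map)
  if (!any(valid)) stop("no valid voxels to quantize")
  x <- map[valid]
  b <- range(x)
  levels <- array(NA_integer_, dim = dim(map))
  constant <- b[1] == b[2]
  if (constant) {
    levels[valid] <- 0L
  } else {
    lv <- as.integer((x - b[1]) / (b[2] - b[1]) * G)
    levels[valid] <- pmin(lv, G - 1L)
  }
  structure(list(levels = levels, G = as.integer(G), mask = valid,
                 bounds = b, constant_region = constant),
            class = "quantized_volume")
}

# shift a numeric/integer array by an integer offset, padding with NA
shift_vals <- function(arr, d) {
  dm <- dim(arr)
  out <- array(arr[1][NA], dim = dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d[ax]); dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]; dst[[ax]] <- src[[ax]] + d[ax]
    }
    if (!length(src[[ax]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# the 9 co-occurrence features of one normalized GLCM (levels 0..G-1).
# contrast is the absolute-difference (dissimilarity) form and inertia the
# classic squared-difference form: Haralick's contrast and inertia coincide,
# so the two are separated this way to keep 9 distinct features.
glcm_features_from_matrix <- function(P) {
  G <- nrow(P)
  i <- matrix(0:(G - 1), G, G)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  lev <- 0:(G - 1)
  mux <- sum(lev * px); muy <- sum(lev * py)
  sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
  mu <- (mux + muy) / 2
  entropy <- -sum(P[P > 0] * log(P[P > 0]))
  correlation <- if (sx * sy > 0)
    sum((i - mux) * (j - muy) * P) / (sx * sy) else 0
  c(Energy       = sum(P^2),
    Contrast     = sum(abs(i - j) * P),
    Correlation  = correlation,
    Variance     = sum((i - mu)^2 * P),
    Homogeneity  = sum(P / (1 + abs(i - j))),
    SumMean      = 0.5 * sum((i + j) * P),
    Entropy      = entropy,
    Inertia      = sum((i - j)^2 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P))
}

#' 3-D gray-level co-occurrence features
#'
#' For each of the 26 unit-offset directions of 3-D space (scaled by
#' `offset`), counts co-occurring level pairs whose both endpoints lie in
#' the mask, normalizes to a joint probability `p(i, j)` and computes nine
#' co-occurrence statistics; feature values are averaged over the
#' directions that contain at least one valid pair (empty directions are
#' dropped from the average, not counted as zero).
#'
#' The statistics, with `px`, `py` the marginals and `mux`, `muy`, `sx`,
#' `sy` their means and standard deviations, are: energy `sum p^2`;
#' contrast `sum |i-j| p` (dissimilarity form); correlation
#' `sum (i-mux)(j-muy) p / (sx sy)` (0 when a marginal is degenerate);
#' variance `sum (i-mu)^2 p` with `mu = (mux+muy)/2`; homogeneity
#' `sum p / (1+|i-j|)`; sum mean `0.5 sum (i+j) p`; entropy
#' `-sum p log p` (natural log); inertia `sum (i-j)^2 p` (the classic
#' squared-difference contrast); cluster shade `sum (i+j-mux-muy)^3 p`.
#'
#' @param q a [quantize()]d volume.
#' @param offset voxel distance of the co-occurrence offset (default 1).
#' @return Named numeric vector of the 9 direction-averaged features, with
#'   attributes `per_direction` (26 x 9 matrix) and `pairs_per_direction`.
#' @export
glcm_3d <- function(q, offset = 1L) {
  stopifnot(inherits(q, "quantized_volume"))
  dirs <- neighbor_offsets(26) * as.integer(offset)
  G <- q$G
  per_dir <- matrix(NA_real_, nrow(dirs), 9)
  npairs <- integer(nrow(dirs))
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    both <- q$mask & shift_vals(q$mask, -d)
    both[is.na(both)] <- FALSE
    n <- sum(both)
    npairs[r] <- n
    if (n == 0) next
    iv <- q$levels[both]
    jv <- shift_vals(q$levels, -d)[both]
    counts <- tabulate(iv * G + jv + 1L, G * G)
    P <- matrix(counts / n, G, G, byrow = TRUE)
    per_dir[r, ] <- glcm_features_from_matrix(P)
  }
  if (all(npairs == 0)) stop("no valid co-occurring pairs in any direction")
  feats <- colMeans(per_dir[npairs > 0, , drop = FALSE])
  names(feats) <- c("Energy", "Contrast", "Correlation", "Variance",
                    "Homogeneity", "SumMean", "Entropy", "Inertia",
                    "ClusterShade")
  colnames(per_dir) <- names(feats)
  structure(feats, per_direction = per_dir, pairs_per_direction = npairs)
}

#' Extract the 39 texture features of one compartment
#'
#' For each of the three parametric maps (rate-in, PE, SER) restricted to a
#' compartment mask: the 4 first-order statistics of the valid voxel values
#' and the 9 direction-averaged 3-D co-occurrence features after 8-level
#' quantization — 13 statistics x 3 maps = 39 features, named in the
#' conventional lesion-table style (e.g. `"parenchyma SER skewness"`).
#'
#' @param maps a [parametric_maps()].
#' @param mask logical compartment mask.
#' @param compartment name prefix, e.g. `"tumor"` or `"parenchyma"`.
#' @param G gray levels for quantization (default 8).
#' @return Named numeric vector of 39 features.
#' @export
extract_compartment_features <- function(maps, mask, compartment = "tumor",
                                         G = 8L) {
  stopifnot(inherits(maps, "parametric_maps"),
            identical(dim(mask), dim(maps$mask)))
  if (!any(mask)) stop("compartment mask is empty")
  out <- numeric(0)
  for (nm in c("rate_in", "pe", "ser")) {
    disp <- c(rate_in = "rate in", pe = "PE", ser = "SER")[[nm]]
    valid <- mask & maps[[paste0("valid_", nm)]] & is.finite(maps[[nm]])
    res <- tryCatch({
      fo <- first_order_stats(maps[[nm]][valid])
      gl <- glcm_3d(quantize(maps[[nm]], valid, G))
      c(fo, gl)
    }, error = function(e)
      stop(sprintf("feature extraction failed for %s %s: %s",
                   compartment, disp, conditionMessage(e)), call. = FALSE))
    names(res) <- paste(compartment, disp, names(res))
    out <- c(out, res)
  }
  out
}

#' One-lesion feature record from segmented phantom or patient volumes
#'
#' Convenience wrapper producing the full imaging-feature row for one
#' lesion: 39 tumor textures, 39 parenchyma (BPE) textures and volumetric
#' breast density — 79 imaging features.
#'
#' @param maps a [parametric_maps()] over the breast.
#' @param masks a [compartment_masks()].
#' @param G gray levels for quantization.
#' @return Named numeric vector of 79 features.
#' @export
extract_lesion_features <- function(maps, masks, G = 8L) {
  stopifnot(inherits(masks, "compartment_masks"))
  c(extract_compartment_features(maps, masks$tumor, "tumor", G),
    extract_compartment_features(maps, masks$parenchyma, "parenchyma", G),
    "breast density" = breast_density(masks))
}
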