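## 3-D mask utilities -------------------------------------------------------

# the 26 unit offsets of a 3-D Moore neighborhood (and the 6-connected subset)
neighbor_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  else if (connectivity != 26) stop("connectivity must be 6 or 26")
  unname(g)
}

# vectorized frontier flood fill from seed linear indices over `open` voxels
flood_fill <- function(open, seeds, offsets) {
  dm <- dim(open)
  visited <- array(FALSE, dim = dm)
  seeds <- seeds[open[seeds]]
  visited[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    idx <- arrayInd(frontier, dm)
    nb <- vector("list", nrow(offsets))
    for (r in seq_len(nrow(offsets))) {
      p <- idx + matrix(offsets[r, ], nrow(idx), 3, byrow = TRUE)
      ok <- p[, 1] >= 1 & p[, 1] <= dm[1] &
            p[, 2] >= 1 & p[, 2] <= dm[2] &
            p[, 3] >= 1 & p[, 3] <= dm[3]
      p <- p[ok, , drop = FALSE]
      nb[[r]] <- p[, 1] + dm[1] * (p[, 2] - 1L) + dm[1] * dm[2] * (p[, 3] - 1L)
    }
    nb <- unique(unlist(nb))
    nb <- nb[open[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

# largest 26-connected component of a logical array
largest_component <- function(mask, connectivity = 26) {
  offsets <- neighbor_offsets(connectivity)
  remaining <- mask
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- flood_fill(remaining, seed, offsets)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  best
}

# shift a logical array by an integer offset, padding with FALSE
shift_mask <- function(mask, d) {
  dm <- dim(mask)
  out <- array(FALSE, dim = dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]
      dst[[ax]] <- src[[ax]] + d[ax]
    }
    if (!length(src[[ax]])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    mask[src[[1]], src[[2]], src[[3]]]
  out
}

# 3x3x3 box dilation / erosion / closing
dilate3 <- function(mask) {
  out <- mask
  for (r in seq_len(nrow(.box_offsets)))
    out <- out | shift_mask(mask, .box_offsets[r, ])
  out
}
erode3 <- function(mask) {
  out <- mask
  for (r in seq_len(nrow(.box_offsets)))
    out <- out & shift_mask(mask, .box_offsets[r, ])
  out
}
.box_offsets <- local({
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
})
close3 <- function(mask) erode3(dilate3(mask))

# Otsu threshold(s) on a numeric vector: maximal between-class variance over
# a 256-bin histogram. `k = 1` is the classic two-class method; `k = 2`
# returns the two thresholds of the three-class partition (exhaustive
# search), whose lower one is the air/tissue boundary on a frame containing
# air, fat and enhancing tissue.
otsu_threshold <- function(x, k = 1L, nbins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(r[1], k))
  h <- tabulate(pmin(as.integer((x - r[1]) / (r[2] - r[1]) * nbins) + 1L,
                     nbins), nbins)
  p <- h / sum(h)
  mids <- r[1] + (seq_len(nbins) - 0.5) * (r[2] - r[1]) / nbins
  W0 <- c(0, cumsum(p))
  M0 <- c(0, cumsum(p * mids))
  # between-class variance contribution of bins (a+1)..b
  wm2 <- function(a, b) {
    w <- W0[b + 1L] - W0[a + 1L]
    m <- M0[b + 1L] - M0[a + 1L]
    ifelse(w > 0, m^2 / w, 0)
  }
  if (k == 1L) {
    bc <- vapply(1:(nbins - 1), function(t) wm2(0, t) + wm2(t, nbins),
                 numeric(1))
    return(mids[which.max(bc)])
  }
  if (k != 2L) stop("k must be 1 or 2")
  best <- -Inf; bt <- c(1L, 2L)
  for (t1 in 1:(nbins - 2)) {
    t2 <- (t1 + 1):(nbins - 1)
    bc <- wm2(0, t1) + wm2(t1, t2) + wm2(t2, nbins)
    j <- which.max(bc)
    if (bc[j] > best) { best <- bc[j]; bt <- c(t1, t2[j]) }
  }
  mids[bt]
}

## Breast segmentation -------------------------------------------------------

#' Chest-wall exclusion plane
#'
#' Builds a logical exclusion mask (TRUE = chest-wall side, to be removed
#' from the breast) from an axis-aligned plane, the scriptable counterpart
#' of interactive chest-wall delineation.
#'
#' @param grid_dim integer length-3 grid dimension.
#' @param axis axis index (1, 2 or 3).
#' @param k slice index of the plane.
#' @param side `"le"` excludes slices with index <= k, `"ge"` those >= k.
#' @return Logical 3-D array, TRUE where excluded.
#' @export
chest_wall_plane <- function(grid_dim, axis = 3, k, side = c("le", "ge")) {
  side <- match.arg(side)
  idx <- slice.index(array(0L, dim = grid_dim), axis)
  if (side == "le") idx <= k else idx >= k
}

#' Segment the breast by skin-edge thresholding
#'
#' Thresholds the t3 frame (near maximal intensity for all tissues), removes
#' the chest-wall side, keeps the largest 26-connected component and applies
#' a 3x3x3 morphological closing. The automatic threshold is Otsu's method
#' on the selected frame, in its three-class (two-threshold) form with the
#' lower threshold taken as the skin edge — the frame is at least trimodal
#' (air, suppressed fat, enhancing tissue), and the air/tissue boundary is
#' the lowest split.
#'
#' @param volume a [dce_volume()].
#' @param timepoint frame used for contouring (default 3).
#' @param skin_threshold `"auto"` (Otsu) or a signal-unit threshold.
#' @param chest_wall `NULL`, or a logical exclusion mask (TRUE = remove),
#'   e.g. from [chest_wall_plane()].
#' @param closing apply the morphological closing (default TRUE).
#' @return Logical breast mask with attribute `threshold`.
#' @export
segment_breast <- function(volume, timepoint = 3, skin_threshold = "auto",
                           chest_wall = NULL, closing = TRUE) {
  stopifnot(inherits(volume, "dce_volume"))
  v <- vol_frame(volume, timepoint)
  thr <- if (identical(skin_threshold, "auto"))
           otsu_threshold(as.vector(v), k = 2L)[1]
         else as.numeric(skin_threshold)
  bw <- v > thr
  if (!is.null(chest_wall)) {
    stopifnot(identical(dim(chest_wall), dim(v)))
    bw <- bw & !chest_wall
  }
  if (!any(bw)) stop("no breast found (empty mask after thresholding)")
  mask <- largest_component(bw)
  if (closing) {
    mask <- close3(mask)
    if (!is.null(chest_wall)) mask <- mask & !chest_wall
  }
  structure(mask, threshold = thr)
}

#' Seeded 3-D region growing for tumor segmentation
#'
#' Grows the maximal 26-connected region containing the seed voxel whose
#' intensities at the chosen timepoint all lie within `intensity_band`
#' (inclusive), the scriptable counterpart of operator-driven gray-level
#' threshold region growing. [apply_mask_edit()] mirrors the manual mask
#' correction step.
#'
#' @param volume a [dce_volume()].
#' @param seed_point integer length-3 voxel index of the seed.
#' @param intensity_band numeric length-2 `[low, high]` band, signal units.
#' @param timepoint frame used (default 3, where tumor contrast is best).
#' @param connectivity 26 (default) or 6.
#' @return Logical tumor mask with attribute `touches_boundary`; a warning
#'   is emitted when the grown region reaches the volume boundary.
#' @export
region_grow_tumor <- function(volume, seed_point, intensity_band,
                              timepoint = 3, connectivity = 26) {
  stopifnot(inherits(volume, "dce_volume"),
            length(seed_point) == 3L, length(intensity_band) == 2L)
  v <- vol_frame(volume, timepoint)
  dm <- dim(v)
  if (any(seed_point < 1) || any(seed_point > dm))
    stop("invalid seed: outside the volume")
  sval <- v[seed_point[1], seed_point[2], seed_point[3]]
  if (sval < intensity_band[1] || sval > intensity_band[2])
    stop("invalid seed: seed intensity outside the band")
  open <- v >= intensity_band[1] & v <= intensity_band[2]
  seed_lin <- seed_point[1] + dm[1] * (seed_point[2] - 1L) +
    dm[1] * dm[2] * (seed_point[3] - 1L)
  mask <- flood_fill(open, seed_lin, neighbor_offsets(connectivity))
  idx <- which(mask, arr.ind = TRUE)
  touches <- any(idx == 1L) || any(t(idx) == dm)
  if (touches) warning("grown region touches the volume boundary")
  structure(mask, touches_boundary = touches)
}

#' @rdname region_grow_tumor
#' @param mask logical mask to edit.
#' @param patch logical array of the same dimension; voxels flagged TRUE are
#'   toggled (XOR), reproducing a manual add/remove correction.
#' @export
apply_mask_edit <- function(mask, patch) {
  stopifnot(identical(dim(mask), dim(patch)))
  xor(mask, patch)
}

## Fuzzy c-means parenchyma / adipose split ---------------------------------

# fuzzy c-means on a numeric vector; returns centers and the n x k
# membership matrix. Convergence: max centroid change < tol.
fcm_1d <- function(x, centers, m = 2, tol = 1e-5, max_iter = 300L) {
  k <- length(centers)
  expo <- 2 / (m - 1)
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    zero <- d < .Machine$double.eps
    d[zero] <- .Machine$double.eps
    w <- d^(-expo)
    u <- w / rowSums(w)
    u[rowSums(zero) > 0, ] <- 0
    u[zero] <- 1
    um <- u^m
    new_centers <- colSums(um * x) / colSums(um)
    delta <- max(abs(new_centers - centers))
    centers <- new_centers
    if (delta < tol) break
  }
  list(centers = centers, membership = u, iterations = it)
}

#' Parenchyma/adipose split by fuzzy c-means
#'
#' Two-class fuzzy c-means on the pre-contrast (t1) intensities of the
#' non-tumor breast, assigning each voxel to its larger-membership class.
#' On fat-suppressed T1-weighted images fibroglandular tissue is typically
#' brighter than suppressed fat, so by default the brighter class is
#' labeled parenchyma (`parenchyma_is = "darker"` flips this).
#'
#' @param volume a [dce_volume()].
#' @param mask logical mask of voxels to cluster (breast minus tumor).
#' @param timepoint frame used (default 1, pre-contrast).
#' @param clusters number of classes (2).
#' @param m fuzzifier, > 1 (default 2).
#' @param tol convergence tolerance on the maximal centroid change.
#' @param max_iter iteration cap.
#' @param init_seeds optional numeric length-2 initial centroid intensities;
#'   by default centroids are initialized k-means++-style from `seed`.
#' @param parenchyma_is which class is parenchyma: `"brighter"` (default)
#'   or `"darker"` on t1.
#' @param seed RNG seed for centroid initialization.
#' @return List with logical `parenchyma` and `adipose` masks, the `centers`
#'   (sorted with the parenchyma center first), the per-voxel `membership`
#'   matrix (columns in center order) and `iterations`.
#' @export
fuzzy_cmeans_partition <- function(volume, mask, timepoint = 1, clusters = 2,
                                   m = 2, tol = 1e-5, max_iter = 300,
                                   init_seeds = NULL,
                                   parenchyma_is = c("brighter", "darker"),
                                   seed = 1L) {
  parenchyma_is <- match.arg(parenchyma_is)
  stopifnot(inherits(volume, "dce_volume"), m > 1, clusters == 2)
  v <- vol_frame(volume, timepoint)
  stopifnot(identical(dim(mask), dim(v)))
  if (!any(mask)) stop("mask is empty")
  x <- v[mask]
  if (max(x) == min(x)) stop("degenerate clustering: all intensities equal")
  if (is.null(init_seeds)) {
    set.seed(seed)
    c1 <- x[sample.int(length(x), 1L)]
    w <- (x - c1)^2
    c2 <- if (sum(w) == 0) max(x) else x[sample.int(length(x), 1L, prob = w)]
    init_seeds <- c(c1, c2)
  }
  if (abs(diff(init_seeds)) < .Machine$double.eps)
    init_seeds <- range(x)
  fit <- fcm_1d(x, centers = as.numeric(init_seeds), m = m,
                tol = tol, max_iter = max_iter)
  ord <- order(fit$centers,
               decreasing = (parenchyma_is == "brighter"))
  centers <- fit$centers[ord]
  u <- fit$membership[, ord, drop = FALSE]
  par_vox <- u[, 1] > u[, 2]
  parenchyma <- adipose <- array(FALSE, dim = dim(mask))
  parenchyma[mask] <- par_vox
  adipose[mask] <- !par_vox
  list(parenchyma = parenchyma, adipose = adipose,
       centers = centers, membership = u, iterations = fit$iterations)
}

#' Volumetric breast density
#'
#' Percentage of breast volume occupied by fibroglandular parenchyma,
#' computed from voxel counts (spacing cancels on a uniform grid).
#'
#' @param masks a [compartment_masks()].
#' @return Density in percent, in [0, 100].
#' @export
breast_density <- function(masks) {
  stopifnot(inherits(masks, "compartment_masks"))
  nb <- sum(masks$breast)
  if (nb == 0) stop("empty breast mask: density undefined")
  100 * sum(masks$parenchyma) / nb
}
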