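#' Specify a digital DCE breast phantom
#'
#' Describes a half-ellipsoid breast whose flat face plays the role of the
#' chest wall, containing a spherical tumor and a central fibroglandular
#' (parenchymal) core occupying a prescribed fraction of the breast volume;
#' the remainder is adipose tissue. Each compartment follows a fixed
#' 4-timepoint enhancement time course. Parenchymal enhancement amplitude is
#' additionally modulated by a smooth multiplicative Gaussian random field,
#' whose variance differs between the TN and non-TN presets — emulating the
#' greater spatial heterogeneity of background parenchymal enhancement seen
#' in triple-negative disease.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing numeric length-3, mm per voxel.
#' @param breast_center,breast_radii half-ellipsoid center and radii in mm.
#'   The half is taken on the +z side of the center plane: the flat face
#'   (chest wall) sits at `z = breast_center[3]`. Defaults center the breast
#'   in-plane with the chest wall one voxel above the grid floor.
#' @param tumor_center,tumor_radius tumor sphere center (mm; default on the
#'   breast axis, mid-depth) and radius (mm).
#' @param parenchyma_fraction target fraction of breast volume occupied by
#'   parenchyma, in (0, 1).
#' @param kinetics named list with numeric length-4 signal time courses (t1
#'   to t4, arbitrary units, all non-negative) for `adipose`, `parenchyma`
#'   and `tumor`. The defaults give a fat-suppressed appearance (dim, barely
#'   enhancing fat), a persistent parenchymal curve peaking at 2 min, and a
#'   tumor washout curve.
#' @param bpe_heterogeneity list with `variance` (of the multiplicative
#'   field, >= 0) and `corr_length` (mm, Gaussian correlation length). When
#'   `NULL`, a preset keyed on `class_label` is used: variance 0.09 for
#'   `"TN"`, 0.01 for `"non-TN"`, correlation length 6 mm.
#' @param noise_sd additive Gaussian noise, signal units.
#' @param class_label `"TN"` or `"non-TN"`; selects the heterogeneity preset.
#' @param seed integer RNG seed; the phantom is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_dce_phantom()]
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 28),
                         voxel_spacing = c(2, 2, 2),
                         breast_center = NULL,
                         breast_radii = c(40, 40, 44),
                         tumor_center = NULL,
                         tumor_radius = 8,
                         parenchyma_fraction = 0.25,
                         kinetics = list(adipose    = c(60, 70, 75, 72),
                                         parenchyma = c(100, 180, 200, 190),
                                         tumor      = c(100, 250, 300, 280)),
                         bpe_heterogeneity = NULL,
                         noise_sd = 2,
                         class_label = c("non-TN", "TN"),
                         seed = 1L) {
  class_label <- match.arg(class_label)
  grid_shape <- as.integer(grid_shape)
  voxel_spacing <- as.numeric(voxel_spacing)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            length(voxel_spacing) == 3L, all(voxel_spacing > 0))
  extent <- grid_shape * voxel_spacing
  if (is.null(breast_center))
    breast_center <- c(extent[1] / 2, extent[2] / 2, voxel_spacing[3])
  if (is.null(tumor_center))
    tumor_center <- breast_center + c(0, 0, 0.45 * breast_radii[3])
  if (!(parenchyma_fraction > 0 && parenchyma_fraction < 1))
    stop("`parenchyma_fraction` must be in (0, 1)")
  stopifnot(length(breast_radii) == 3L, all(breast_radii > 0),
            length(tumor_radius) == 1L, tumor_radius > 0)
  for (nm in c("adipose", "parenchyma", "tumor")) {
    k <- kinetics[[nm]]
    if (is.null(k) || length(k) != 4L || any(k < 0))
      stop(sprintf("kinetics$%s must be 4 non-negative signal values", nm))
  }
  if (is.null(bpe_heterogeneity))
    bpe_heterogeneity <- list(
      variance = if (class_label == "TN") 0.09 else 0.01,
      corr_length = 6)
  if (bpe_heterogeneity$variance < 0)
    stop("bpe_heterogeneity$variance must be >= 0")
  if (bpe_heterogeneity$corr_length <= 0)
    stop("bpe_heterogeneity$corr_length must be > 0 (mm)")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")

  # conservative analytic containment check: the tumor sphere must fit in
  # the half-ellipsoid shrunk by the tumor radius on every axis
  shrunk <- breast_radii - tumor_radius
  if (any(shrunk <= 0))
    stop("geometry error: tumor radius too large for the breast ellipsoid")
  rel <- (tumor_center - breast_center) / shrunk
  if (sum(rel^2) > 1 || tumor_center[3] - tumor_radius < breast_center[3])
    stop("geometry error: tumor sphere not strictly inside the breast")

  structure(list(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                 breast_center = breast_center, breast_radii = breast_radii,
                 tumor_center = tumor_center, tumor_radius = tumor_radius,
                 parenchyma_fraction = parenchyma_fraction,
                 kinetics = kinetics, bpe_heterogeneity = bpe_heterogeneity,
                 noise_sd = noise_sd, class_label = class_label,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable 3-D Gaussian smoothing; kernel rows renormalised at the edges so
# the filter preserves a constant field
gauss_smooth3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * s^2))
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    m <- matrix(a, nrow = n)
    a <- array(K %*% m, dim = d[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

#' Generate a 4-D DCE phantom
#'
#' Builds the voxel grid described by a [phantom_spec()]: ground-truth
#' compartment masks, a noiseless per-compartment signal model, the
#' parenchymal heterogeneity field, and additive Gaussian noise. Every voxel
#' of a compartment follows that compartment's kinetics exactly, except
#' parenchyma, where the enhancement amplitude (signal above baseline) is
#' scaled by `1 + field` with `field` a zero-mean Gaussian random field of
#' the specified variance and correlation length.
#'
#' The parenchymal core is constructed by ranking non-tumor breast voxels by
#' their normalized ellipsoidal radius and keeping the innermost voxels until
#' the target volume fraction is met, so the ground-truth breast density
#' matches `parenchyma_fraction` to within one voxel.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{`volume`}{a [dce_volume()] with the noisy 4-D signal;}
#'     \item{`masks`}{ground-truth [compartment_masks()];}
#'     \item{`truth`}{list with the spec kinetics, achieved breast density
#'       (percent), the heterogeneity field summary and the seed.}
#'   }
#' @examples
#' ph <- generate_dce_phantom(phantom_spec(noise_sd = 0))
#' ph$truth$density
#' @export
generate_dce_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  g <- spec$grid_shape; sp <- spec$voxel_spacing
  # voxel-center coordinates in mm
  cx <- (seq_len(g[1]) - 0.5) * sp[1]
  cy <- (seq_len(g[2]) - 0.5) * sp[2]
  cz <- (seq_len(g[3]) - 0.5) * sp[3]

  bx <- ((cx - spec$breast_center[1]) / spec$breast_radii[1])^2
  by <- ((cy - spec$breast_center[2]) / spec$breast_radii[2])^2
  bz <- ((cz - spec$breast_center[3]) / spec$breast_radii[3])^2
  E <- outer(outer(bx, by, "+"), bz, "+")          # squared ellipsoid radius
  Z <- array(rep(cz, each = g[1] * g[2]), dim = g)
  breast <- E <= 1 & Z >= spec$breast_center[3]

  tx <- (cx - spec$tumor_center[1])^2
  ty <- (cy - spec$tumor_center[2])^2
  tz <- (cz - spec$tumor_center[3])^2
  D2 <- outer(outer(tx, ty, "+"), tz, "+")
  tumor <- D2 <= spec$tumor_radius^2
  if (!any(tumor))
    stop("geometry error: tumor sphere contains no voxel at this spacing")
  if (any(tumor & !breast))
    stop("geometry error: tumor sphere not strictly inside the breast")

  cand <- which(breast & !tumor)
  target <- round(spec$parenchyma_fraction * sum(breast))
  if (target > length(cand))
    stop("geometry error: parenchyma_fraction unattainable beside the tumor")
  parenchyma <- array(FALSE, dim = g)
  parenchyma[cand[order(E[cand])[seq_len(target)]]] <- TRUE
  masks <- compartment_masks(breast, tumor, parenchyma)

  # parenchymal heterogeneity field (drawn before noise: a fixed seed gives
  # a fixed field regardless of noise_sd)
  h <- spec$bpe_heterogeneity
  if (h$variance > 0) {
    field <- array(rnorm(prod(g)), dim = g)
    field <- gauss_smooth3(field, h$corr_length / sp)
    field <- (field - mean(field)) / sd(field) * sqrt(h$variance)
  } else {
    field <- array(0, dim = g)
  }
  mult <- pmax(1 + field, 0.05)

  kin <- spec$kinetics
  data <- array(0, dim = c(g, 4L))
  for (t in 1:4) {
    s <- array(0, dim = g)
    s[masks$adipose] <- kin$adipose[t]
    s[tumor] <- kin$tumor[t]
    s[parenchyma] <- kin$parenchyma[1] +
      (kin$parenchyma[t] - kin$parenchyma[1]) * mult[parenchyma]
    data[, , , t] <- s
  }
  if (spec$noise_sd > 0)
    data <- data + rnorm(length(data), sd = spec$noise_sd)
  data <- pmax(data, 0)

  truth <- list(kinetics = kin,
                density = 100 * sum(parenchyma) / sum(breast),
                class_label = spec$class_label,
                field_variance = h$variance,
                field_sd_in_parenchyma = sd(mult[parenchyma]),
                seed = spec$seed)
  list(volume = dce_volume(data, spacing = sp),
       masks = masks, truth = truth)
}
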