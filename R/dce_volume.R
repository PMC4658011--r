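#' 4-D DCE-MRI volume
#'
#' Container for a dynamic contrast-enhanced acquisition with exactly four
#' timepoints: `t1` pre-contrast, `t2`/`t3` early phase and `t4` late phase.
#' Signal units are arbitrary; only differences and ratios between timepoints
#' carry meaning downstream.
#'
#' @param data 4-D numeric array `(x, y, z, timepoint)` with 4 timepoints;
#'   finite and non-negative.
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param times numeric length-4, acquisition times in minutes. The default
#'   `c(0, 1, 2, 6)` places the early post-contrast frames at 1 and 2 minutes
#'   and the late frame at 6 minutes.
#' @return An object of class `dce_volume`: a list with elements `data`,
#'   `spacing` and `times`.
#' @examples
#' v <- dce_volume(array(1, c(4, 4, 2, 4)), spacing = c(1, 1, 1))
#' dim(v$data)
#' @export
dce_volume <- function(data, spacing, times = c(0, 1, 2, 6)) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4-D array (x, y, z, timepoint)")
  if (dim(data)[4] != 4L)
    stop("`data` must have exactly 4 timepoints")
  if (anyNA(data) || any(!is.finite(data)))
    stop("`data` must be finite")
  if (any(data < 0))
    stop("`data` must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  times <- as.numeric(times)
  if (length(times) != 4L || is.unsorted(times, strictly = TRUE))
    stop("`times` must be 4 strictly increasing acquisition times (minutes)")
  structure(list(data = data, spacing = spacing, times = times),
            class = "dce_volume")
}

# one timepoint as a 3-D array (singleton axes preserved)
vol_frame <- function(volume, timepoint) {
  d <- dim(volume$data)
  array(volume$data[, , , timepoint], dim = d[1:3])
}

#' @export
print.dce_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dce_volume> %d x %d x %d voxels, 4 timepoints\n",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing: %s mm; times: %s min\n",
              paste(signif(x$spacing, 3), collapse = " x "),
              paste(x$times, collapse = ", ")))
  cat(sprintf("  signal range: [%.3g, %.3g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Aligned compartment masks
#'
#' Binary 3-D masks for the breast and its sub-compartments on the grid of a
#' [dce_volume()]. The compartments partition the breast: the tumor and
#' parenchyma are disjoint subsets, and adipose tissue is the remainder
#' `breast \ (tumor U parenchyma)`.
#'
#' @param breast,tumor,parenchyma,adipose logical 3-D arrays of identical
#'   dimension. `adipose` may be omitted, in which case it is derived as the
#'   breast remainder.
#' @return An object of class `compartment_masks`.
#' @export
compartment_masks <- function(breast, tumor, parenchyma, adipose = NULL) {
  for (m in list(breast, tumor, parenchyma))
    if (!is.logical(m) || length(dim(m)) != 3L)
      stop("masks must be logical 3-D arrays")
  dm <- dim(breast)
  if (!identical(dim(tumor), dm) || !identical(dim(parenchyma), dm))
    stop("masks must share one grid")
  if (any(tumor & !breast)) stop("tumor mask extends outside the breast")
  if (any(parenchyma & !breast)) stop("parenchyma mask extends outside the breast")
  if (any(tumor & parenchyma)) stop("tumor and parenchyma masks overlap")
  if (is.null(adipose)) adipose <- breast & !tumor & !parenchyma
  if (!identical(dim(adipose), dm)) stop("masks must share one grid")
  if (any(adipose & (tumor | parenchyma | !breast)))
    stop("adipose mask must be the breast remainder")
  structure(list(breast = breast, tumor = tumor,
                 parenchyma = parenchyma, adipose = adipose),
            class = "compartment_masks")
}

#' @export
print.compartment_masks <- function(x, ...) {
  cat("<compartment_masks> voxel counts:\n")
  for (nm in names(x))
    cat(sprintf("  %-11s %d\n", nm, sum(x[[nm]])))
  invisible(x)
}

#' Read and write volumes as NIfTI-1
#'
#' `write_volume_nifti()` stores the 4-D signal of a [dce_volume()] as a
#' single 4-D NIfTI-1 file with the voxel spacing in the header;
#' `read_volume_nifti()` reads it back. `write_mask_nifti()` /
#' `read_mask_nifti()` do the same for binary masks, stored as uint8.
#'
#' @param volume a [dce_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param times acquisition times (minutes) to attach on read.
#' @return `read_volume_nifti()` returns a [dce_volume()];
#'   `read_mask_nifti()` a logical 3-D array. The writers return `path`
#'   invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "dce_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- c(volume$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, times = c(0, 1, 2, 6)) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  dce_volume(arr, spacing = sp, times = times)
}

#' @rdname write_volume_nifti
#' @param mask logical 3-D array.
#' @export
write_mask_nifti <- function(mask, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim = dim(img))
}
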