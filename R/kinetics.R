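#' Pharmacokinetic parametric maps
#'
#' Derives the three standard enhancement maps from a 4-timepoint DCE
#' acquisition, per voxel within a mask. Writing `S1..S4` for the signal at
#' `t1..t4` and `Smax` for the maximum over the post-contrast frames
#' `t2..t4` (attained at time `tmax`; the baseline is excluded so flat or
#' decreasing courses give non-positive enhancement rather than 0/0):
#' \describe{
#'   \item{rate-in}{`(Smax - S1) / (tmax - t1)`, signal units per minute —
#'     the speed of contrast uptake;}
#'   \item{PE}{`100 (Smax - S1) / S1`, percent enhancement;}
#'   \item{SER}{`(Smax - S1) / (S4 - S1)`, the signal enhancement ratio;
#'     SER = 1 when the maximum occurs at t4 and SER > 1 indicates washout.}
#' }
#' Voxels where a denominator is too small are flagged invalid rather than
#' imputed: PE needs `S1 >= baseline_floor`, SER needs
#' `|S4 - S1| >= denom_floor`.
#'
#' @param volume a [dce_volume()].
#' @param mask logical 3-D mask of voxels to map (e.g. the breast).
#' @param baseline_floor minimal baseline signal for PE validity (default 1).
#' @param denom_floor minimal `|S4 - S1|` for SER validity (default 1).
#' @return An object of class `parametric_maps`: list with 3-D arrays
#'   `rate_in`, `pe`, `ser` (NA outside the mask or where invalid), logical
#'   validity masks `valid_rate_in`, `valid_pe`, `valid_ser`, and `mask`.
#' @examples
#' v <- dce_volume(array(rep(c(100, 250, 300, 280), each = 8),
#'                       c(2, 2, 2, 4)), spacing = c(1, 1, 1))
#' m <- parametric_maps(v, array(TRUE, c(2, 2, 2)))
#' m$pe[1]   # 200
#' m$ser[1]  # 200/180
#' @export
parametric_maps <- function(volume, mask, baseline_floor = 1,
                            denom_floor = 1) {
  stopifnot(inherits(volume, "dce_volume"))
  dm <- dim(volume$data)[1:3]
  stopifnot(identical(dim(mask), dm))
  idx <- which(mask)
  n <- length(idx)
  if (n == 0) stop("mask is empty")
  S <- matrix(NA_real_, n, 4)
  for (t in 1:4) S[, t] <- vol_frame(volume, t)[idx]
  post <- S[, 2:4, drop = FALSE]
  amax <- max.col(post, ties.method = "first")      # earliest max on ties
  smax <- post[cbind(seq_len(n), amax)]
  tmax <- volume$times[amax + 1L]
  s1 <- S[, 1]; s4 <- S[, 4]

  rate <- (smax - s1) / (tmax - volume$times[1])
  pe_valid <- s1 >= baseline_floor
  pe <- ifelse(pe_valid, 100 * (smax - s1) / s1, NA_real_)
  ser_valid <- abs(s4 - s1) >= denom_floor
  ser <- ifelse(ser_valid, (smax - s1) / (s4 - s1), NA_real_)

  put <- function(vals) {
    a <- array(NA_real_, dim = dm); a[idx] <- vals; a
  }
  putl <- function(vals) {
    a <- array(FALSE, dim = dm); a[idx] <- vals; a
  }
  structure(list(rate_in = put(rate), pe = put(pe), ser = put(ser),
                 valid_rate_in = putl(TRUE), valid_pe = putl(pe_valid),
                 valid_ser = putl(ser_valid), mask = mask),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("<parametric_maps> %d mapped voxels\n", sum(x$mask)))
  for (nm in c("rate_in", "pe", "ser")) {
    v <- x[[nm]][x[[paste0("valid_", nm)]]]
    cat(sprintf("  %-8s valid %d, range [%.3g, %.3g]\n",
                nm, length(v), min(v), max(v)))
  }
  invisible(x)
}

#' @rdname parametric_maps
#' @export
compute_rate_in <- function(volume, mask)
  parametric_maps(volume, mask)$rate_in

#' @rdname parametric_maps
#' @export
compute_pe <- function(volume, mask, baseline_floor = 1)
  parametric_maps(volume, mask, baseline_floor = baseline_floor)$pe

#' @rdname parametric_maps
#' @export
compute_ser <- function(volume, mask, denom_floor = 1)
  parametric_maps(volume, mask, denom_floor = denom_floor)$ser

#' Write parametric maps as NIfTI
#'
#' One float32 NIfTI per map plus a paired uint8 validity mask.
#'
#' @param maps a [parametric_maps()].
#' @param dir output directory (created if needed).
#' @param spacing voxel spacing (mm) recorded in the headers.
#' @return The directory, invisibly.
#' @export
write_maps_nifti <- function(maps, dir, spacing = c(1, 1, 1)) {
  stopifnot(inherits(maps, "parametric_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("rate_in", "pe", "ser")) {
    a <- maps[[nm]]
    a[is.na(a)] <- 0
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")),
                       datatype = "float")
    write_mask_nifti(maps[[paste0("valid_", nm)]],
                     file.path(dir, paste0(nm, "_valid.nii.gz")))
  }
  invisible(dir)
}
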