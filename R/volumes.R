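## Volume containers and Gaussian smoothing.
##
## Volumes are plain 3-D arrays. World (mm) coordinates follow the convention
## mm = (voxel_index - 1) * voxel_size along each axis, i.e. the first voxel
## sits at the world origin; NIfTI affines written by the package encode the
## same convention.

#' Quantitative parameter map
#'
#' A lightweight container for a 3-D scalar volume of one quantitative
#' parameter together with its physical metadata and a validity mask.
#'
#' @param data 3-D numeric array.
#' @param kind One of `"R1"`, `"R2s"`, `"MTsat"`, `"AMP"`, `"GMvol"`,
#'   `"WMvol"`.
#' @param units Unit string; defaults follow the kind (`s^-1` for rates,
#'   `p.u.` for MT saturation, `a.u.` for amplitude, `probability` for
#'   tissue-volume maps).
#' @param voxel_size_mm Positive numeric triple, voxel edge lengths in mm.
#' @param space `"native"` or `"standard"`.
#' @param mask Optional logical array of the same shape marking voxels where
#'   the value is defined; `NULL` means all voxels valid.
#' @return An object of class `param_map`.
#' @export
param_map <- function(data, kind, units = NULL,
                      voxel_size_mm = c(1, 1, 1),
                      space = c("native", "standard"),
                      mask = NULL) {
  kinds <- c("R1", "R2s", "MTsat", "AMP", "GMvol", "WMvol")
  kind <- match.arg(kind, kinds)
  if (!(is.array(data) && length(dim(data)) == 3L))
    vbq_stop("'data' must be a 3-D array")
  space <- match.arg(space)
  check_triple(voxel_size_mm, "voxel_size_mm")
  if (is.null(units)) {
    units <- switch(kind,
      R1 = "s^-1", R2s = "s^-1", MTsat = "p.u.", AMP = "a.u.",
      GMvol = "probability", WMvol = "probability")
  }
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data)))
      vbq_stop("'mask' shape does not match 'data'")
    mask <- array(as.logical(mask), dim(data))
    if (any(!is.finite(data[mask])))
      vbq_stop("non-finite values inside the validity mask")
  }
  structure(list(data = data, kind = kind, units = units,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 space = space, mask = mask),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  dm <- dim(x$data)
  nv <- if (is.null(x$mask)) prod(dm) else sum(x$mask)
  rng <- range(if (is.null(x$mask)) x$data else x$data[x$mask], finite = TRUE)
  cat(sprintf("<param_map> %s [%s], %s space, %dx%dx%d @ %.3g mm\n",
              x$kind, x$units, x$space, dm[1], dm[2], dm[3],
              x$voxel_size_mm[1]))
  cat(sprintf("  valid voxels: %d / %d; range %.4g .. %.4g\n",
              nv, prod(dm), rng[1], rng[2]))
  invisible(x)
}

## ---- Gaussian smoothing ----------------------------------------------------

#' Separable 1-D Gaussian kernel for a given FWHM
#'
#' The kernel is defined on an integer voxel grid with
#' `sigma = fwhm_mm / (sqrt(8 * log(2)) * voxel_mm)`, truncated at 4 sigma and
#' renormalised to unit sum. A FWHM of 0 gives the identity kernel `1`.
#'
#' @param fwhm_mm Full width at half maximum in mm (>= 0).
#' @param voxel_mm Voxel size along the axis in mm.
#' @return Numeric vector of odd length summing to 1.
#' @export
gauss_kernel_1d <- function(fwhm_mm, voxel_mm) {
  if (fwhm_mm < 0) vbq_stop("'fwhm_mm' must be >= 0")
  sigma <- fwhm_mm / (sqrt(8 * log(2)) * voxel_mm)
  if (sigma == 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## convolve a 3-D array along one axis with zero padding (vectorised shifts)
conv_axis <- function(vol, k, axis) {
  nk <- length(k)
  if (nk == 1L) return(vol * k)
  r <- (nk - 1L) %/% 2L
  dm <- dim(vol)
  n <- dm[axis]
  out <- array(0, dm)
  idx <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
  for (j in seq_len(nk)) {
    off <- j - r - 1L            # source = target + off
    src <- idx; dst <- idx
    lo <- max(1L, 1L - off); hi <- min(n, n - off)
    if (lo > hi) next
    dst[[axis]] <- lo:hi
    src[[axis]] <- (lo + off):(hi + off)
    out[dst[[1]], dst[[2]], dst[[3]]] <-
      out[dst[[1]], dst[[2]], dst[[3]]] +
      k[j] * vol[src[[1]], src[[2]], src[[3]]]
  }
  out
}

#' Isotropic Gaussian smoothing of a 3-D volume
#'
#' Separable discrete Gaussian convolution with zero-padded borders. The
#' kernel along each axis is truncated at 4 sigma and renormalised to unit
#' sum, so a constant volume is preserved in the interior; `fwhm_mm = 0`
#' returns the input unchanged.
#'
#' @param vol 3-D numeric array.
#' @param fwhm_mm Kernel FWHM in mm (>= 0).
#' @param voxel_size_mm Voxel size triple in mm.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(vol, fwhm_mm, voxel_size_mm = c(1, 1, 1)) {
  if (!(is.array(vol) && length(dim(vol)) == 3L))
    vbq_stop("'vol' must be a 3-D array")
  check_triple(voxel_size_mm, "voxel_size_mm")
  if (fwhm_mm < 0) vbq_stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(vol)
  for (ax in 1:3)
    vol <- conv_axis(vol, gauss_kernel_1d(fwhm_mm, voxel_size_mm[ax]), ax)
  vol
}

## ---- NIfTI I/O -------------------------------------------------------------

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (array), `affine` (4x4 voxel-to-mm matrix) and
#'   `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) vbq_stop("file not found: %s", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = dim(aff))
  if (abs(det(aff)) < .Machine$double.eps)
    vbq_stop("degenerate affine (zero determinant) in %s", path)
  dat <- as.array(img)
  attributes(dat) <- list(dim = dim(dat))
  ## the affine is authoritative for voxel size
  vox <- sqrt(colSums(aff[1:3, 1:3]^2))
  list(data = dat, affine = aff, voxel_size_mm = as.numeric(vox))
}

#' Write a NIfTI-1 volume
#'
#' If no affine is supplied, a diagonal affine placing the first voxel at the
#' world origin with the given voxel size is used.
#'
#' @param data 3-D or 4-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel size triple in mm.
#' @param affine Optional 4x4 voxel-to-mm matrix.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, voxel_size_mm = c(1, 1, 1),
                         affine = NULL) {
  check_triple(voxel_size_mm, "voxel_size_mm")
  if (!is.null(affine))
    voxel_size_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(data)
  nd <- length(dim(data))
  RNifti::pixdim(img) <- c(voxel_size_mm, rep(1, max(0L, nd - 3L)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(img, path)
  invisible(path)
}
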