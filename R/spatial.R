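## Spatial normalisation machinery: Jacobian determinants of deformation
## fields, pull-back warping, tissue weights w = |Dphi| * t(phi), and the
## combined weighting/smoothing that preserves quantitative values.

## finite differences of a 3-D array along one axis (central interior,
## one-sided borders), grid spacing h
fd_axis <- function(vol, axis, h) {
  dm <- dim(vol)
  n <- dm[axis]
  idx <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
  sl <- function(i) { ix <- idx; ix[[axis]] <- i; vol[ix[[1]], ix[[2]], ix[[3]], drop = FALSE] }
  out <- array(0, dm)
  if (n == 1L) return(out)
  ctr <- idx; ctr[[axis]] <- 2:(n - 1)
  if (n > 2L)
    out[ctr[[1]], ctr[[2]], ctr[[3]]] <- (sl(3:n) - sl(1:(n - 2))) / (2 * h)
  lo <- idx; lo[[axis]] <- 1L
  out[lo[[1]], lo[[2]], lo[[3]]] <- (sl(2L) - sl(1L)) / h
  hi <- idx; hi[[axis]] <- n
  out[hi[[1]], hi[[2]], hi[[3]]] <- (sl(n) - sl(n - 1L)) / h
  out
}

#' Jacobian determinant of a deformation field
#'
#' The deformation maps standard-space world coordinates to native-space
#' world coordinates, `phi(x) = x + u(x)` with the displacement `u` in mm.
#' The 3x3 gradient of `phi` is computed by central differences in the
#' interior and one-sided differences at the borders; the identity field
#' gives exactly 1 everywhere. Negative values are allowed in the output
#' (they indicate folding) and should be screened downstream.
#'
#' @param def A `deformation_field`.
#' @return 3-D array of determinants (dimensionless).
#' @export
jacobian_determinant <- function(def) {
  if (!inherits(def, "deformation_field"))
    vbq_stop("'def' must be a deformation_field")
  u <- def$displacement
  if (any(!is.finite(u))) vbq_stop("deformation field contains non-finite values")
  vox <- def$voxel_size_mm
  g <- vector("list", 9L)   # g[[3*(j-1)+i]] = d u_i / d x_j
  for (j in 1:3) for (i in 1:3)
    g[[3 * (j - 1) + i]] <- fd_axis(u[, , , i], j, vox[j])
  ## J_ij = delta_ij + d u_i / d x_j
  j11 <- 1 + g[[1]]; j21 <- g[[2]]; j31 <- g[[3]]
  j12 <- g[[4]]; j22 <- 1 + g[[5]]; j32 <- g[[6]]
  j13 <- g[[7]]; j23 <- g[[8]]; j33 <- 1 + g[[9]]
  j11 * (j22 * j33 - j23 * j32) -
    j12 * (j21 * j33 - j23 * j31) +
    j13 * (j21 * j32 - j22 * j31)
}

## Keys cubic-convolution kernel (a = -0.5)
cubic_kernel <- function(t) {
  at <- abs(t)
  ifelse(at <= 1, 1.5 * at^3 - 2.5 * at^2 + 1,
         ifelse(at < 2, -0.5 * at^3 + 2.5 * at^2 - 4 * at + 2, 0))
}

## sample `vol` at fractional voxel coordinates (1-based), matrices ix/iy/iz;
## returns NA outside the field of view
sample_volume <- function(vol, ix, iy, iz, order) {
  dm <- dim(vol)
  n <- length(ix)
  if (order == 0L) {
    rx <- round(ix); ry <- round(iy); rz <- round(iz)
    ok <- rx >= 1 & rx <= dm[1] & ry >= 1 & ry <= dm[2] & rz >= 1 & rz <= dm[3]
    out <- rep(NA_real_, n)
    out[ok] <- vol[cbind(rx[ok], ry[ok], rz[ok])]
    return(out)
  }
  half <- if (order == 1L) 0L else 1L      # neighbourhood reach below floor
  span <- if (order == 1L) 0:1 else -1:2
  fx <- floor(ix); fy <- floor(iy); fz <- floor(iz)
  ok <- ix >= 1 & ix <= dm[1] & iy >= 1 & iy <= dm[2] & iz >= 1 & iz <= dm[3]
  out <- rep(NA_real_, n)
  if (!any(ok)) return(out)
  ixo <- ix[ok]; iyo <- iy[ok]; izo <- iz[ok]
  fxo <- floor(ixo); fyo <- floor(iyo); fzo <- floor(izo)
  acc <- numeric(sum(ok))
  wsum <- numeric(sum(ok))
  for (dx in span) for (dy in span) for (dz in span) {
    px <- fxo + dx; py <- fyo + dy; pz <- fzo + dz
    if (order == 1L) {
      wx <- 1 - abs(ixo - px); wy <- 1 - abs(iyo - py); wz <- 1 - abs(izo - pz)
      wx <- pmax(wx, 0); wy <- pmax(wy, 0); wz <- pmax(wz, 0)
    } else {
      wx <- cubic_kernel(ixo - px); wy <- cubic_kernel(iyo - py)
      wz <- cubic_kernel(izo - pz)
    }
    w <- wx * wy * wz
    cx <- pmin(pmax(px, 1), dm[1]); cy <- pmin(pmax(py, 1), dm[2])
    cz <- pmin(pmax(pz, 1), dm[3])     # clamp support at the border
    acc <- acc + w * vol[cbind(cx, cy, cz)]
    wsum <- wsum + w
  }
  out[ok] <- acc / wsum
  out
}

#' Warp a native-space volume to the standard grid (pull-back)
#'
#' Every standard-grid voxel `x` is filled with `vol(phi(x))`, sampling the
#' native volume at the deformed world coordinate by interpolation of the
#' requested order (0 = nearest neighbour, 1 = trilinear, 3 = cubic).
#' Standard and native grids share the package's world-coordinate
#' convention (first voxel at the origin, mm = (index-1) * voxel size).
#' Samples falling outside the native field of view are returned as `NA`.
#'
#' @param vol Native-space 3-D array.
#' @param def A `deformation_field` on the standard grid.
#' @param order Interpolation order, one of 0, 1, 3.
#' @param voxel_size_native Voxel size of the native grid (defaults to the
#'   deformation grid's).
#' @return Standard-space array with `NA` marking out-of-view samples.
#' @export
warp_volume <- function(vol, def, order = 1L,
                        voxel_size_native = def$voxel_size_mm) {
  if (!inherits(def, "deformation_field"))
    vbq_stop("'def' must be a deformation_field")
  if (!order %in% c(0L, 1L, 3L)) vbq_stop("'order' must be 0, 1 or 3")
  dm <- dim(def$displacement)[1:3]
  vox <- def$voxel_size_mm
  ## world coords of the standard grid
  xs <- (seq_len(dm[1]) - 1) * vox[1]
  ys <- (seq_len(dm[2]) - 1) * vox[2]
  zs <- (seq_len(dm[3]) - 1) * vox[3]
  X <- array(rep(xs, times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(ys, each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(zs, each = dm[1] * dm[2]), dm)
  px <- X + def$displacement[, , , 1]
  py <- Y + def$displacement[, , , 2]
  pz <- Z + def$displacement[, , , 3]
  ## native world -> native fractional voxel index (1-based)
  out <- sample_volume(vol,
                       px / voxel_size_native[1] + 1,
                       py / voxel_size_native[2] + 1,
                       pz / voxel_size_native[3] + 1,
                       as.integer(order))
  array(out, dm)
}

#' Tissue weights in standard space
#'
#' Elementwise product `w = |Dphi| * t(phi)` of the Jacobian determinant and
#' the warped tissue probability, clipped below at zero. `NA` tissue samples
#' (outside the native field of view) get weight zero.
#'
#' @param jac Jacobian determinant array on the standard grid.
#' @param tissue_warped Warped tissue probability array in `[0, 1]`.
#' @param tissue `"GM"` or `"WM"`.
#' @return An object of class `tissue_weights` (fields `w`, `tissue`).
#' @export
compute_weights <- function(jac, tissue_warped, tissue = c("GM", "WM")) {
  tissue <- match.arg(tissue)
  if (!identical(dim(jac), dim(tissue_warped)))
    vbq_stop("'jac' and 'tissue_warped' shapes differ")
  tw <- tissue_warped
  tw[is.na(tw)] <- 0
  if (any(tw < -1e-9 | tw > 1 + 1e-9))
    vbq_stop("'tissue_warped' must lie in [0, 1]")
  structure(list(w = pmax(jac * tw, 0), tissue = tissue),
            class = "tissue_weights")
}

#' Tissue-weighted smoothing of a standard-space parameter map
#'
#' Computes `g*(w s) / g*(w)` with one and the same zero-padded Gaussian
#' kernel in numerator and denominator, so the result is a kernel-weighted
#' average of the parameter restricted to the tissue's support: a constant
#' map stays constant, values never bleed in from voxels with zero weight,
#' and the output range is bounded by the input range on the weight support.
#' Voxels where the smoothed weight falls below `eps_rel` times its maximum
#' are masked invalid.
#'
#' @param s Standard-space [param_map()] (or bare 3-D array); `NA` values
#'   (e.g. outside the warped field of view) are treated as zero-weight.
#' @param w A [compute_weights()] object or bare nonnegative array.
#' @param fwhm_mm Kernel FWHM in mm (>= 0; 0 reproduces `s` on the support).
#' @param voxel_size_mm Used when `s` is a bare array.
#' @param eps_rel Relative floor for the smoothed weight.
#' @return A `param_map` in standard space whose `mask` flags valid voxels;
#'   invalid voxels hold `NA`.
#' @export
tissue_weighted_smooth <- function(s, w, fwhm_mm,
                                   voxel_size_mm = NULL, eps_rel = 1e-6) {
  if (inherits(s, "param_map")) {
    vox <- s$voxel_size_mm; sdat <- s$data
    kind <- s$kind; units <- s$units
    if (!is.null(s$mask)) sdat[!s$mask] <- NA
  } else {
    if (is.null(voxel_size_mm))
      vbq_stop("'voxel_size_mm' is required when 's' is a bare array")
    vox <- voxel_size_mm; sdat <- s; kind <- "AMP"; units <- "a.u."
  }
  wdat <- if (inherits(w, "tissue_weights")) w$w else w
  if (!identical(dim(wdat), dim(sdat))) vbq_stop("shape mismatch between s and w")
  if (any(wdat < 0)) vbq_stop("weights must be nonnegative")
  if (fwhm_mm < 0) vbq_stop("'fwhm_mm' must be >= 0")
  bad <- is.na(sdat)
  if (any(bad)) { wdat[bad] <- 0; sdat[bad] <- 0 }
  if (all(wdat == 0)) {
    warning("all weights are zero: output fully masked")
    out <- array(NA_real_, dim(sdat))
    return(param_map(out, kind, units, vox, "standard",
                     mask = array(FALSE, dim(sdat))))
  }
  num <- gaussian_smooth(wdat * sdat, fwhm_mm, vox)
  den <- gaussian_smooth(wdat, fwhm_mm, vox)
  valid <- den >= eps_rel * max(den)
  out <- array(NA_real_, dim(sdat))
  out[valid] <- num[valid] / den[valid]
  param_map(out, kind, units, vox, "standard", mask = valid)
}

#' Jacobian-modulated, smoothed tissue-volume map
#'
#' `g*(t(phi) * |Dphi|)`: the warped tissue probability is multiplied by the
#' Jacobian determinant so values represent local tissue volume rather than
#' concentration, then smoothed with the standard Gaussian kernel. This is
#' the input to voxel-based morphometry of tissue volume.
#'
#' @param tissue_warped Warped tissue probability array (`NA` treated as 0).
#' @param jac Jacobian determinant array.
#' @param fwhm_mm Kernel FWHM in mm.
#' @param voxel_size_mm Voxel size triple.
#' @param tissue `"GM"` or `"WM"` (sets the output kind).
#' @return A `param_map` of kind `GMvol`/`WMvol` in standard space.
#' @export
modulate_and_smooth <- function(tissue_warped, jac, fwhm_mm,
                                voxel_size_mm = c(1, 1, 1),
                                tissue = c("GM", "WM")) {
  tissue <- match.arg(tissue)
  if (!identical(dim(tissue_warped), dim(jac)))
    vbq_stop("'tissue_warped' and 'jac' shapes differ")
  tw <- tissue_warped
  tw[is.na(tw)] <- 0
  out <- gaussian_smooth(tw * jac, fwhm_mm, voxel_size_mm)
  param_map(out, if (tissue == "GM") "GMvol" else "WMvol",
            "tissue volume density", voxel_size_mm, "standard")
}
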