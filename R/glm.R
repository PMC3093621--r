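## Mass-univariate statistics: tissue masks, block-diagonal multi-parameter
## design, voxelwise OLS, two-tailed T maps, family-wise error control and
## overlap label maps.

#' Exclusive GM/WM analysis masks from warped tissue maps
#'
#' Averages the warped GM and WM probability maps across subjects and
#' assigns each voxel exclusively: a voxel enters the GM mask iff mean GM
#' probability is at least `threshold` *and* strictly exceeds mean WM
#' probability (the WM mask analogously), so the two masks are disjoint and
#' ties are excluded.
#'
#' @param gm_maps,wm_maps Lists of warped probability arrays (one per
#'   subject); `NA` values count as 0.
#' @param threshold Probability threshold in (0, 1), default 0.2.
#' @return List with logical arrays `gm_mask`, `wm_mask` and the mean maps.
#' @export
build_tissue_masks <- function(gm_maps, wm_maps, threshold = 0.2) {
  if (length(gm_maps) < 1L || length(wm_maps) < 1L)
    vbq_stop("need at least one subject")
  if (!(threshold > 0 && threshold < 1)) vbq_stop("'threshold' must be in (0,1)")
  avg <- function(maps) {
    acc <- Reduce(`+`, lapply(maps, function(m) { m[is.na(m)] <- 0; m }))
    acc / length(maps)
  }
  mgm <- avg(gm_maps); mwm <- avg(wm_maps)
  gm_mask <- mgm >= threshold & mgm > mwm
  wm_mask <- mwm >= threshold & mwm > mgm
  if (!any(gm_mask)) warning("GM mask is empty after thresholding")
  if (!any(wm_mask)) warning("WM mask is empty after thresholding")
  list(gm_mask = gm_mask, wm_mask = wm_mask, mean_gm = mgm, mean_wm = mwm)
}

## small dense block-diagonal helper
block_diag <- function(blocks) {
  nr <- vapply(blocks, nrow, 1L); nc <- vapply(blocks, ncol, 1L)
  out <- matrix(0, sum(nr), sum(nc))
  r0 <- c(0L, cumsum(nr)); c0 <- c(0L, cumsum(nc))
  for (i in seq_along(blocks))
    out[(r0[i] + 1):r0[i + 1], (c0[i] + 1):c0[i + 1]] <- blocks[[i]]
  out
}

#' Block-diagonal multi-parameter design from a covariate table
#'
#' Builds one identical per-parameter block with columns intercept, age,
#' gender (coded +1/2 male, -1/2 female) and total intracranial volume; all
#' non-intercept columns are mean-centred so the intercept estimates the
#' cohort mean. The concatenated design is block-diagonal with one block per
#' parameter, which reproduces the per-parameter beta estimates exactly
#' while allowing parameter-specific variance components.
#'
#' @param covariates Data frame/tibble with columns `subject_id`, `age`,
#'   `gender` (`"M"`/`"F"`), `tiv`.
#' @param parameters Character vector of parameter tags (one block each).
#' @return An object of class `vbq_design`: list with `block` (n x r
#'   matrix), `design` (block-diagonal (P n) x (P r)), `regressors`,
#'   `parameters`, `n`.
#' @export
build_design <- function(covariates, parameters) {
  need <- c("subject_id", "age", "gender", "tiv")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) vbq_stop("covariates lack columns: %s", paste(miss, collapse = ", "))
  if (anyNA(covariates[need])) vbq_stop("covariates contain missing values")
  n <- nrow(covariates)
  g <- ifelse(covariates$gender %in% c("M", "male", "1"), 0.5, -0.5)
  blk <- cbind(intercept = rep(1, n),
               age = covariates$age - mean(covariates$age),
               gender = g - mean(g),
               tiv = covariates$tiv - mean(covariates$tiv))
  if (n < ncol(blk) + 2L)
    vbq_stop("need at least %d subjects for %d regressors", ncol(blk) + 2L, ncol(blk))
  qrb <- qr(blk)
  if (qrb$rank < ncol(blk)) {
    dropped <- colnames(blk)[qrb$pivot[(qrb$rank + 1):ncol(blk)]]
    vbq_stop("design is rank deficient; collinear column(s): %s",
             paste(dropped, collapse = ", "))
  }
  design <- block_diag(rep(list(blk), length(parameters)))
  colnames(design) <- as.vector(outer(colnames(blk), parameters,
                                      function(r, p) paste(p, r, sep = ".")))
  structure(list(block = blk, design = design,
                 regressors = colnames(blk),
                 parameters = parameters, n = n),
            class = "vbq_design")
}

#' Voxelwise OLS of the block-diagonal multi-parameter model
#'
#' The concatenated block-diagonal system is solved in one pass (betas are
#' algebraically identical to separate per-parameter fits); residual
#' variance is estimated per voxel independently for each parameter block,
#' with `dof = n - rank(block)`.
#'
#' @param data Named list (one entry per parameter, same order as
#'   `design$parameters`) of n x V matrices of masked voxel data.
#' @param design A [build_design()] object.
#' @param mask Optional logical 3-D array with `sum(mask) == V`, carried
#'   through for peak tables and label volumes.
#' @param voxel_size_mm Voxel size triple of the standard grid.
#' @return An object of class `vbq_glm`: per-parameter list of `beta`
#'   (r x V), `sigma2` (V), plus shared `dof`, `xtx_inv`, `mask`, `data`.
#' @export
fit_glm <- function(data, design, mask = NULL, voxel_size_mm = c(1, 1, 1)) {
  if (!inherits(design, "vbq_design")) vbq_stop("'design' must be a vbq_design")
  pars <- design$parameters
  if (!identical(sort(names(data)), sort(pars)))
    vbq_stop("'data' names must match design parameters")
  data <- data[pars]
  n <- design$n
  V <- ncol(data[[1]])
  for (p in pars) {
    if (nrow(data[[p]]) != n) vbq_stop("block '%s' has wrong number of rows", p)
    if (ncol(data[[p]]) != V) vbq_stop("block '%s' has wrong number of voxels", p)
  }
  r <- ncol(design$block)
  if (n <= r) vbq_stop("more regressors than subjects")
  ## one concatenated solve of the block-diagonal system
  Ycat <- do.call(rbind, data)
  qrX <- qr(design$design)
  Bcat <- qr.coef(qrX, Ycat)
  dof <- n - r
  xtx_inv <- chol2inv(chol(crossprod(design$block)))
  blocks <- list()
  for (i in seq_along(pars)) {
    rows <- ((i - 1) * r + 1):(i * r)
    beta <- Bcat[rows, , drop = FALSE]
    rownames(beta) <- design$regressors
    res <- data[[i]] - design$block %*% beta
    sigma2 <- colSums(res^2) / dof
    blocks[[pars[i]]] <- list(beta = beta, sigma2 = sigma2)
  }
  structure(list(blocks = blocks, design = design, dof = dof,
                 xtx_inv = xtx_inv, mask = mask,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 data = data, n_voxels = V),
            class = "vbq_glm")
}

#' @export
print.vbq_glm <- function(x, ...) {
  cat(sprintf("<vbq_glm> %d parameter block(s), n = %d, dof = %d, %d voxels\n",
              length(x$blocks), x$design$n, x$dof, x$n_voxels))
  invisible(x)
}

#' T and two-tailed p maps for a contrast on one parameter block
#'
#' `T = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)` with the block's per-voxel OLS
#' variance; `p = 2 * (1 - F_t(|T|; dof))`. Voxels with zero residual
#' variance are masked (`NA`).
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Numeric contrast over the block regressors, or a
#'   regressor name (e.g. `"age"`).
#' @param parameter Which block to test (default: first).
#' @return List with vectors `t`, `p` (length V), `dof`, and the parameter.
#' @export
t_map <- function(fit, contrast = "age", parameter = NULL) {
  if (!inherits(fit, "vbq_glm")) vbq_stop("'fit' must be a vbq_glm")
  if (is.null(parameter)) parameter <- names(fit$blocks)[1]
  blk <- fit$blocks[[parameter]]
  if (is.null(blk)) vbq_stop("unknown parameter block '%s'", parameter)
  regs <- fit$design$regressors
  if (is.character(contrast)) {
    cvec <- as.numeric(regs == contrast)
    if (!any(cvec != 0)) vbq_stop("unknown regressor '%s'", contrast)
  } else {
    cvec <- as.numeric(contrast)
    if (length(cvec) != length(regs))
      vbq_stop("contrast length %d != number of regressors %d",
               length(cvec), length(regs))
  }
  eff <- as.vector(crossprod(cvec, blk$beta))
  cvar <- as.numeric(t(cvec) %*% fit$xtx_inv %*% cvec)
  se2 <- blk$sigma2 * cvar
  tv <- rep(NA_real_, length(eff))
  ok <- se2 > 0
  tv[ok] <- eff[ok] / sqrt(se2[ok])
  pv <- 2 * pt(-abs(tv), fit$dof)
  list(t = tv, p = pv, dof = fit$dof, parameter = parameter,
       contrast = cvec, effect = eff)
}

## equivalent z from a two-tailed t p-value, sign carried over
equiv_z <- function(tv, dof) {
  z <- sign(tv) * qnorm(pt(abs(tv), dof, lower.tail = FALSE,
                           log.p = TRUE), log.p = TRUE, lower.tail = FALSE)
  z
}

#' Family-wise-error thresholding of a T map
#'
#' Voxelwise FWE control at level `alpha` over the analysis mask, by
#' Bonferroni (default) or by a max-|T| permutation null built by permuting
#' the age regressor residualised against the nuisance regressors. A
#' separate "trend" set is thresholded at the uncorrected auxiliary level
#' `aux_unc`. A peak table lists local maxima of |T| (18-connectivity) among
#' suprathreshold voxels with world (mm) coordinates.
#'
#' @param fit A [fit_glm()] result (must carry a `mask` for peak
#'   coordinates; otherwise coordinates are voxel indices of the vector).
#' @param tres A [t_map()] result on the same fit.
#' @param alpha FWE level (default 0.05).
#' @param method `"bonferroni"` or `"permutation"`.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param aux_unc Auxiliary uncorrected threshold (default 0.001).
#' @param seed Seed for the permutation draw.
#' @return List: logical vectors `fwe` and `trend`, `t_crit`, the
#'   permutation `max_t` null (if used) and `peaks`
#'   (tibble: parameter, x_mm, y_mm, z_mm, t, z, p_unc, p_fwe).
#' @export
fwe_threshold <- function(fit, tres, alpha = 0.05,
                          method = c("bonferroni", "permutation"),
                          n_perm = 1000L, aux_unc = 0.001, seed = 1L) {
  method <- match.arg(method)
  nv <- sum(is.finite(tres$t))
  if (nv < 1L) vbq_stop("empty mask: no finite T values")
  tv <- tres$t
  max_t <- NULL
  if (method == "bonferroni") {
    fwe <- is.finite(tv) & tres$p <= alpha / nv
    t_crit <- qt(alpha / nv / 2, fit$dof, lower.tail = FALSE)
    p_fwe <- pmin(1, tres$p * nv)
  } else {
    n_perm <- as.integer(n_perm)
    if (n_perm < 100L) vbq_stop("'n_perm' must be >= 100")
    X <- fit$design$block
    cvec <- tres$contrast
    ## residualise the tested regressor against the nuisance columns
    a <- as.vector(X %*% cvec)
    Z <- X[, cvec == 0, drop = FALSE]
    ar <- as.vector(a - Z %*% qr.coef(qr(Z), a))
    Y <- fit$data[[tres$parameter]]
    Yr <- Y - Z %*% qr.coef(qr(Z), Y)
    n <- nrow(Y)
    P <- withr::with_seed(seed, {
      t(vapply(seq_len(n_perm), function(i) sample.int(n), integer(n)))
    })
    AP <- matrix(ar[P], nrow = n_perm)                # permuted regressor
    ## re-orthogonalise each permuted regressor against the nuisance space
    ## (the data are nuisance-residualised, so skipping this deflates the
    ## permutation statistics and inflates the FWER)
    AP <- AP - (AP %*% Z) %*% solve(crossprod(Z), t(Z))
    saa_p <- rowSums(AP^2)
    A <- AP %*% Yr                                    # n_perm x V
    cssy <- colSums(Yr^2)
    dof <- fit$dof
    ss_res <- sweep(-(A^2) / saa_p, 2, cssy, `+`)
    ss_res[ss_res < 0] <- 0
    tmat <- (A / saa_p) / sqrt(ss_res / dof / saa_p)
    max_t <- apply(abs(tmat), 1, max, na.rm = TRUE)
    p_fwe <- vapply(tv, function(t0)
      if (is.finite(t0)) (1 + sum(max_t >= abs(t0))) / (n_perm + 1)
      else NA_real_, 1)
    fwe <- is.finite(tv) & p_fwe <= alpha
    k <- max(1L, floor(alpha * (n_perm + 1)))
    t_crit <- sort(max_t, decreasing = TRUE)[k]
  }
  trend <- is.finite(tv) & tres$p <= aux_unc
  peaks <- peak_table(fit, tv, tres$p, p_fwe, fwe | trend, tres$parameter)
  list(fwe = fwe, trend = trend, t_crit = t_crit, method = method,
       max_t = max_t, alpha = alpha, aux_unc = aux_unc, peaks = peaks)
}

## local maxima of |T| over 18-connectivity among `sel` voxels
peak_table <- function(fit, tv, pv, p_fwe, sel, parameter) {
  empty <- tibble::tibble(parameter = character(), x_mm = numeric(),
                          y_mm = numeric(), z_mm = numeric(), t = numeric(),
                          z = numeric(), p_unc = numeric(), p_fwe = numeric())
  if (is.null(fit$mask) || !any(sel, na.rm = TRUE)) return(empty)
  dm <- dim(fit$mask)
  vol <- array(NA_real_, dm)
  vol[fit$mask] <- abs(tv)
  selvol <- array(FALSE, dm)
  selvol[fit$mask] <- sel
  idx <- which(selvol, arr.ind = TRUE)
  ## 18-connectivity offsets (|dx|+|dy|+|dz| <= 2, excluding self)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0 & rowSums(abs(offs)) <= 2, ]
  is_peak <- rep(TRUE, nrow(idx))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(idx, 2, as.numeric(offs[o, ]), `+`)
    inb <- nb[, 1] >= 1 & nb[, 1] <= dm[1] & nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    v <- rep(-Inf, nrow(idx))
    v[inb] <- vol[nb[inb, , drop = FALSE]]
    v[is.na(v)] <- -Inf
    is_peak <- is_peak & vol[idx] >= v
  }
  pk <- idx[is_peak, , drop = FALSE]
  if (nrow(pk) == 0L) return(empty)
  lin <- pk[, 1] + dm[1] * (pk[, 2] - 1) + dm[1] * dm[2] * (pk[, 3] - 1)
  maskpos <- which(fit$mask)
  vi <- match(lin, maskpos)
  vox <- fit$voxel_size_mm
  ord <- order(-abs(tv[vi]))
  tibble::tibble(parameter = parameter,
                 x_mm = (pk[, 1] - 1) * vox[1],
                 y_mm = (pk[, 2] - 1) * vox[2],
                 z_mm = (pk[, 3] - 1) * vox[3],
                 t = tv[vi], z = equiv_z(tv[vi], fit$dof),
                 p_unc = pv[vi], p_fwe = p_fwe[vi])[ord, ]
}

#' Overlap label map across parameter contrasts
#'
#' Binarises each parameter's T map by direction at the uncorrected
#' threshold `p_unc` and assigns one integer label to every distinct
#' combination of suprathreshold indicators, with a legend describing each
#' combination (e.g. `"MTsat-, R2s+"`). Voxels below threshold everywhere
#' get label 0.
#'
#' @param tmaps Named list of [t_map()] results (name = parameter).
#' @param p_unc Uncorrected two-tailed threshold (default 0.001).
#' @return List: integer vector `labels` (length V) and `legend`
#'   (tibble: label, combination).
#' @export
overlap_labels <- function(tmaps, p_unc = 0.001) {
  if (length(tmaps) < 1L) vbq_stop("need at least one T map")
  V <- length(tmaps[[1]]$t)
  ind <- matrix(0L, V, 2L * length(tmaps))
  nms <- character(2L * length(tmaps))
  for (i in seq_along(tmaps)) {
    tm <- tmaps[[i]]
    sup <- is.finite(tm$t) & tm$p <= p_unc
    ind[, 2 * i - 1] <- as.integer(sup & tm$t > 0)
    ind[, 2 * i] <- as.integer(sup & tm$t < 0)
    nms[2 * i - 1] <- paste0(names(tmaps)[i], "+")
    nms[2 * i] <- paste0(names(tmaps)[i], "-")
  }
  key <- as.vector(ind %*% 2L^(seq_len(ncol(ind)) - 1L))
  combos <- sort(setdiff(unique(key), 0))
  labels <- match(key, combos, nomatch = 0L)
  legend <- tibble::tibble(
    label = seq_along(combos),
    combination = vapply(combos, function(k) {
      bits <- as.integer(intToBits(k))[seq_along(nms)]
      paste(nms[bits == 1], collapse = ", ")
    }, "")
  )
  list(labels = labels, legend = legend)
}
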