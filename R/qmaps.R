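## Quantitative map estimation from multi-echo FLASH: echo averaging,
## log-linear R2* fitting, dual-flip-angle R1/amplitude estimation, MT
## saturation, and transmit-bias correction of R1.
##
## All estimator formulas use flip angles in radians and times in seconds.

#' Average the first n echoes of a series
#'
#' Arithmetic mean of the first `n` echo volumes, used to raise SNR before
#' computing R1, amplitude and MT saturation.
#'
#' @param series A [multiecho_series()].
#' @param n Number of leading echoes to average (default 6).
#' @return 3-D array.
#' @export
average_echoes <- function(series, n = 6L) {
  if (!inherits(series, "multiecho_series"))
    vbq_stop("'series' must be a multiecho_series")
  n <- as.integer(n)
  if (n < 1L || n > length(series$echoes))
    vbq_stop("'n' must be between 1 and the number of echoes (%d)",
             length(series$echoes))
  Reduce(`+`, series$echoes[seq_len(n)]) / n
}

#' R2* from a log-linear fit over echoes
#'
#' Per voxel, ordinary least squares of `log(S)` against echo time in
#' seconds; `R2* = -slope` and the exponentiated intercept is retained as
#' the TE = 0 amplitude. Echoes with non-positive signal are excluded
#' voxelwise; voxels with fewer than three positive echoes are masked
#' invalid rather than raising an error.
#'
#' @param series A [multiecho_series()] with at least 3 echoes.
#' @return A list: `r2s` ([param_map()], s^-1, with validity mask), `s0`
#'   (TE = 0 amplitude array, `NA` where masked).
#' @export
fit_r2star <- function(series) {
  if (!inherits(series, "multiecho_series"))
    vbq_stop("'series' must be a multiecho_series")
  te <- series$seq$te_ms / 1000
  ne <- length(te)
  if (ne < 3L) vbq_stop("at least 3 echoes are required")
  if (anyDuplicated(te)) vbq_stop("echo times must be distinct")
  dm <- dim(series$echoes[[1]])
  nv <- prod(dm)
  S <- matrix(unlist(series$echoes, use.names = FALSE), nrow = nv, ncol = ne)
  pos <- S > 0
  npos <- rowSums(pos)
  slope <- rep(NA_real_, nv)
  icpt <- rep(NA_real_, nv)
  full <- npos == ne
  if (any(full)) {
    ## closed-form OLS, all echoes present
    L <- log(S[full, , drop = FALSE])
    mt <- mean(te); ct <- te - mt
    sxx <- sum(ct^2)
    b <- as.vector(L %*% ct) / sxx
    a <- rowMeans(L) - b * mt
    slope[full] <- b; icpt[full] <- a
  }
  part <- which(!full & npos >= 3L)
  for (v in part) {
    u <- pos[v, ]
    tv <- te[u]; lv <- log(S[v, u])
    ct <- tv - mean(tv)
    b <- sum(ct * lv) / sum(ct^2)
    slope[v] <- b
    icpt[v] <- mean(lv) - b * mean(tv)
  }
  mask <- array(!is.na(slope), dm)
  r2s <- array(-slope, dm)
  r2s[!mask] <- NA_real_
  s0 <- array(exp(icpt), dm)
  list(r2s = param_map(r2s, "R2s", voxel_size_mm = series$voxel_size_mm,
                       space = "native", mask = mask),
       s0 = s0)
}

## robust maximum used for denominator floors
robust_max <- function(x) as.numeric(quantile(abs(x[is.finite(x)]), 0.99))

#' R1 and amplitude from two differently weighted FLASH signals
#'
#' Dual-flip-angle estimators based on the small-angle rational
#' approximation of the spoiled gradient-echo steady state (alpha in
#' radians, TR in seconds):
#' \deqn{R1 = \frac{1}{2}\,\frac{S_{T1}\alpha_{T1}/TR_{T1} -
#'   S_{PD}\alpha_{PD}/TR_{PD}}{S_{PD}/\alpha_{PD} - S_{T1}/\alpha_{T1}}}
#' \deqn{A = S_{PD} S_{T1}\,\frac{TR_{PD}\alpha_{T1}/\alpha_{PD} -
#'   TR_{T1}\alpha_{PD}/\alpha_{T1}}{S_{T1} TR_{PD}\alpha_{T1} -
#'   S_{PD} TR_{T1}\alpha_{PD}}}
#' Voxels where a denominator magnitude falls below `floor_rel` times the
#' denominator volume's robust (99th-percentile) maximum are masked. When
#' the achieved flip angle is `b1 * alpha`, the apparent R1 equals the true
#' R1 divided by `b1^2` (see [correct_r1_bias()]).
#'
#' @param s_t1,s_pd Echo-averaged T1- and PD-weighted signal arrays.
#' @param seq_t1,seq_pd Their [seq_params()]; the (flip, TR) pairs must
#'   differ.
#' @param voxel_size_mm Voxel size triple.
#' @param floor_rel Relative denominator floor.
#' @return List of `param_map`s: `r1` (s^-1), `amp` (a.u.), both masked
#'   where the estimate is unstable.
#' @export
estimate_r1_amplitude <- function(s_t1, s_pd, seq_t1, seq_pd,
                                  voxel_size_mm = c(1, 1, 1),
                                  floor_rel = 1e-6) {
  if (!identical(dim(s_t1), dim(s_pd))) vbq_stop("signal shapes differ")
  a1 <- seq_t1$flip_deg * pi / 180; a2 <- seq_pd$flip_deg * pi / 180
  tr1 <- seq_t1$tr_ms / 1000; tr2 <- seq_pd$tr_ms / 1000
  if (isTRUE(all.equal(a1, a2)) && isTRUE(all.equal(tr1, tr2)))
    vbq_stop("the two inputs have identical (flip angle, TR); R1 is not identifiable")
  den_r1 <- s_pd / a2 - s_t1 / a1
  den_amp <- s_t1 * tr2 * a1 - s_pd * tr1 * a2
  ok <- abs(den_r1) >= floor_rel * robust_max(den_r1) &
    abs(den_amp) >= floor_rel * robust_max(den_amp) &
    is.finite(s_t1) & is.finite(s_pd)
  r1 <- amp <- array(NA_real_, dim(s_t1))
  r1[ok] <- 0.5 * (s_t1[ok] * a1 / tr1 - s_pd[ok] * a2 / tr2) / den_r1[ok]
  amp[ok] <- s_pd[ok] * s_t1[ok] * (tr2 * a1 / a2 - tr1 * a2 / a1) / den_amp[ok]
  list(r1 = param_map(r1, "R1", voxel_size_mm = voxel_size_mm,
                      space = "native", mask = ok),
       amp = param_map(amp, "AMP", voxel_size_mm = voxel_size_mm,
                       space = "native", mask = ok))
}

#' MT saturation from the MT-weighted signal
#'
#' Percentage loss of longitudinal magnetization per MT pulse:
#' `delta = (A * alpha / S_MT - 1) * R1 * TR - alpha^2 / 2` (fractional;
#' output in p.u. = 100 * delta). The construction makes the measure
#' insensitive to relaxation-time and, to first order, flip-angle (B1)
#' differences. Negative values may occur under noise; they are kept but
#' counted in the QC attribute. Voxels with non-positive MT-weighted signal
#' are masked.
#'
#' @param s_mt Echo-averaged MT-weighted signal array.
#' @param amp,r1 Amplitude and R1 `param_map`s in native space.
#' @param seq_mt [seq_params()] of the MT-weighted acquisition.
#' @return A `param_map` of kind `MTsat` (p.u.) with attribute
#'   `qc = list(frac_negative)`.
#' @export
compute_mtsat <- function(s_mt, amp, r1, seq_mt) {
  if (!inherits(amp, "param_map") || !inherits(r1, "param_map"))
    vbq_stop("'amp' and 'r1' must be param_map objects")
  if (amp$space != "native" || r1$space != "native")
    vbq_stop("'amp' and 'r1' must be in native space")
  if (!identical(dim(s_mt), dim(amp$data))) vbq_stop("shape mismatch")
  a <- seq_mt$flip_deg * pi / 180
  tr <- seq_mt$tr_ms / 1000
  ok <- s_mt > 0 & is.finite(s_mt)
  if (!is.null(amp$mask)) ok <- ok & amp$mask
  if (!is.null(r1$mask)) ok <- ok & r1$mask
  mt <- array(NA_real_, dim(s_mt))
  mt[ok] <- 100 * ((amp$data[ok] * a / s_mt[ok] - 1) * r1$data[ok] * tr -
                     a^2 / 2)
  out <- param_map(mt, "MTsat", voxel_size_mm = amp$voxel_size_mm,
                   space = "native", mask = ok)
  attr(out, "qc") <- list(frac_negative = mean(mt[ok] < 0))
  out
}

## 3-D polynomial basis (total degree <= order, without the constant term)
## on normalised [-1,1] coordinates, returned as an (n_voxel x n_term) matrix
poly_basis <- function(shape, order) {
  g <- lapply(1:3, function(i) seq(-1, 1, length.out = shape[i]))
  x <- array(rep(g[[1]], times = shape[2] * shape[3]), shape)
  y <- array(rep(rep(g[[2]], each = shape[1]), times = shape[3]), shape)
  z <- array(rep(g[[3]], each = shape[1] * shape[2]), shape)
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i)) for (k in 0:(order - i - j)) {
    if (i + j + k == 0) next
    cols[[length(cols) + 1L]] <- as.vector(x^i * y^j * z^k)
  }
  do.call(cbind, cols)
}

#' Correct apparent R1 for transmit (flip-angle) bias
#'
#' With an achieved flip angle `b1 * alpha`, the dual-flip-angle apparent R1
#' carries a multiplicative bias field of `1 / b1^2`. Two correction paths:
#'
#' * analytic, when a measured `b1` map is supplied: the bias `1/b1^2` is
#'   divided out (`R1 = r1_app * b1^2`);
#' * estimation, when only tissue probabilities are supplied: a smooth
#'   multiplicative field (low-order 3-D polynomial in the log domain) is
#'   estimated by minimising intra-tissue log-R1 variance over
#'   high-probability (>= 0.9) GM/WM voxels, normalised to unit geometric
#'   mean, and divided out.
#'
#' @param r1_app Apparent-R1 `param_map`.
#' @param b1 Optional positive bias-factor array (achieved/nominal flip).
#' @param tissues Optional `tissue_probs` for estimation mode.
#' @param poly_order Total polynomial degree of the estimated log-field.
#' @return List: `r1` (corrected `param_map`) and `bias` (the multiplicative
#'   field removed from the apparent map).
#' @export
correct_r1_bias <- function(r1_app, b1 = NULL, tissues = NULL,
                            poly_order = 3L) {
  if (!inherits(r1_app, "param_map")) vbq_stop("'r1_app' must be a param_map")
  if (is.null(b1) && is.null(tissues))
    vbq_stop("provide at least one of 'b1' or 'tissues'")
  dm <- dim(r1_app$data)
  if (!is.null(b1)) {
    if (!identical(dim(b1), dm)) vbq_stop("'b1' shape mismatch")
    if (any(b1 <= 0)) vbq_stop("'b1' must be strictly positive everywhere")
    bias <- 1 / b1^2
  } else {
    use <- (tissues$gm >= 0.9 | tissues$wm >= 0.9) &
      is.finite(r1_app$data) & r1_app$data > 0
    if (!is.null(r1_app$mask)) use <- use & r1_app$mask
    if (sum(use) < 50L)
      vbq_stop("too few high-probability tissue voxels (%d) to estimate the bias field", sum(use))
    B <- poly_basis(dm, poly_order)
    cls <- ifelse(tissues$wm >= 0.9, 1L, 2L)[use]    # WM wins ties
    X <- cbind(model_dummies(cls), B[as.vector(use), , drop = FALSE])
    y <- log(r1_app$data[use])
    cf <- qr.coef(qr(X), y)
    cf[is.na(cf)] <- 0
    nb <- ncol(X) - ncol(B)
    logf <- as.vector(B %*% cf[(nb + 1):length(cf)])
    logf <- logf - mean(logf[as.vector(use)])        # unit geometric mean
    bias <- array(exp(logf), dm)
  }
  corr <- r1_app$data / bias
  list(r1 = param_map(corr, "R1", voxel_size_mm = r1_app$voxel_size_mm,
                      space = r1_app$space, mask = r1_app$mask),
       bias = bias)
}

## one-hot class dummies (no reference level; basis has no intercept)
model_dummies <- function(cls) {
  lev <- sort(unique(cls))
  vapply(lev, function(l) as.numeric(cls == l), numeric(length(cls)))
}

#' Full map-fitting pipeline for one subject
#'
#' Echo-averages the three weightings, fits R2* from the PD-weighted
#' multi-echo series, estimates R1 and amplitude from the averaged T1-/PD-
#' weighted signals, computes MT saturation, optionally corrects the
#' amplitude for the mean T2* decay over the averaged echoes (so it refers
#' to TE = 0), and corrects R1 for transmit bias when a B1 map or tissue
#' maps are given.
#'
#' @param t1w,pdw,mtw [multiecho_series()] for the three weightings.
#' @param b1 Optional B1 bias array for analytic R1 correction.
#' @param tissues Optional `tissue_probs` for estimated R1 correction.
#' @param n_avg Echoes to average (default 6).
#' @param decay_correct_amp Divide the amplitude by
#'   `mean(exp(-TE * R2*))` over the averaged echo times.
#' @param r2s_all_weightings If `TRUE`, pool all three weightings' echoes
#'   for the R2* fit (off by default; the default fit uses the PD-weighted
#'   echoes only).
#' @return List of `param_map`s `r1`, `r2s`, `mtsat`, `amp` plus `qc`.
#' @export
fit_parameter_maps <- function(t1w, pdw, mtw, b1 = NULL, tissues = NULL,
                               n_avg = 6L, decay_correct_amp = TRUE,
                               r2s_all_weightings = FALSE) {
  s_t1 <- average_echoes(t1w, n_avg)
  s_pd <- average_echoes(pdw, n_avg)
  s_mt <- average_echoes(mtw, n_avg)
  if (r2s_all_weightings) {
    ## pool echoes: fit each weighting separately and average the rates
    fits <- lapply(list(t1w, pdw, mtw), fit_r2star)
    r2s_dat <- (fits[[1]]$r2s$data + fits[[2]]$r2s$data + fits[[3]]$r2s$data) / 3
    msk <- fits[[1]]$r2s$mask & fits[[2]]$r2s$mask & fits[[3]]$r2s$mask
    r2s_dat[!msk] <- NA_real_
    r2s <- param_map(r2s_dat, "R2s", voxel_size_mm = pdw$voxel_size_mm,
                     space = "native", mask = msk)
  } else {
    r2s <- fit_r2star(pdw)$r2s
  }
  ra <- estimate_r1_amplitude(s_t1, s_pd, t1w$seq, pdw$seq,
                              voxel_size_mm = pdw$voxel_size_mm)
  ## MT saturation must use the amplitude on the echo-averaged signal scale
  ## (the mean T2* decay factor then cancels between amplitude and s_mt)
  mtsat <- compute_mtsat(s_mt, ra$amp, ra$r1, mtw$seq)
  amp <- ra$amp
  if (decay_correct_amp) {
    te_s <- t1w$seq$te_ms[seq_len(n_avg)] / 1000
    ok <- amp$mask & r2s$mask
    k <- vapply(seq_along(te_s), function(i) exp(-te_s[i] * r2s$data[ok]),
                numeric(sum(ok)))
    dat <- amp$data
    dat[ok] <- dat[ok] / rowMeans(k)
    dat[!ok] <- NA_real_
    amp <- param_map(dat, "AMP", voxel_size_mm = amp$voxel_size_mm,
                     space = "native", mask = ok)
  }
  r1 <- ra$r1
  bias <- NULL
  if (!is.null(b1) || !is.null(tissues)) {
    cb <- correct_r1_bias(ra$r1, b1 = b1, tissues = tissues)
    r1 <- cb$r1; bias <- cb$bias
  }
  qc <- list(frac_negative_mtsat = attr(mtsat, "qc")$frac_negative,
             frac_masked = mean(!(r1$mask & r2s$mask & mtsat$mask)))
  list(r1 = r1, r2s = r2s, mtsat = mtsat, amp = amp, bias = bias, qc = qc)
}
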