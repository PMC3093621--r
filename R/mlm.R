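## Multivariate linear model of age effects: eigenvariates of the
## nuisance-residualised age-effect matrix across parameters, with
## split-sample Lawley-Hotelling trace inference.

## residualise columns of Y against design columns Z (rank-safe: within a
## split half a nuisance column may become constant)
residualise <- function(Y, Z) Y - qr.fitted(qr(Z), Y)

## Lawley-Hotelling trace test with the standard F approximation.
## trace = tr(H E^-1) from a MANOVA with p response variables, q hypothesis
## df and v error df; for q = 1 this is exact (Hotelling T^2).
lh_trace_test <- function(trace, p, q, v) {
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  nn <- (v - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- 2 * (s * nn + 1)
  if (df2 <= 0) return(list(f = NA_real_, df1 = df1, df2 = df2, p = NA_real_))
  f <- df2 * trace / (s^2 * (2 * m + s + 1))
  list(f = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE))
}

#' Eigenvariates of multi-parameter age effects
#'
#' Per parameter, the voxelwise data are standardised (centred, unit SD
#' across subjects) and residualised against the nuisance regressors
#' (everything except age). The fitted age-effect matrix `E` (voxels x
#' parameters) is decomposed by singular value decomposition
#' `E = U D V'`: eigenvariate `k` has spatial map `U_k d_k`, unit-norm
#' parameter loading vector `V_k` and variance-explained fraction
#' `d_k^2 / sum(d^2)`.
#'
#' Per-component significance uses a Lawley-Hotelling trace statistic with
#' its F approximation on split samples: the loadings/maps are estimated on
#' one half of the subjects and the trace test is evaluated on the held-out
#' half's component scores, which keeps the test calibrated (estimating and
#' testing on the same subjects would inflate the statistic).
#'
#' @param data Named list (one per parameter) of n x V data matrices on a
#'   common mask.
#' @param design A [build_design()] object for the same subjects.
#' @param age_regressor Name of the regressor of interest (default
#'   `"age"`).
#' @param sd_floor Voxels whose SD falls below `sd_floor` times the median
#'   SD are dropped from standardisation (kept at zero).
#' @param seed Seed for the split-half assignment.
#' @return An object of class `vbq_mlm`: `maps` (V x K), `loadings`
#'   (P x K, unit columns), `d` (singular values), `var_frac`
#'   (sums to 1), `p` (split-sample trace-test p per component),
#'   `parameters`.
#' @export
mlm_age_eigen <- function(data, design, age_regressor = "age",
                          sd_floor = 1e-8, seed = 1L) {
  if (!inherits(design, "vbq_design")) vbq_stop("'design' must be a vbq_design")
  if (length(data) < 2L) vbq_stop("need at least two parameters")
  keep <- vapply(data, function(m) any(m != 0), TRUE)
  if (!all(keep)) {
    warning(sprintf("excluding all-zero parameter(s): %s",
                    paste(names(data)[!keep], collapse = ", ")))
    data <- data[keep]
  }
  if (length(data) < 2L) vbq_stop("fewer than two non-degenerate parameters")
  pars <- names(data)
  n <- nrow(data[[1]])
  V <- ncol(data[[1]])
  P <- length(pars)
  X <- design$block
  ai <- which(design$regressors == age_regressor)
  if (!length(ai)) vbq_stop("no regressor named '%s'", age_regressor)
  Z <- X[, -ai, drop = FALSE]
  a <- X[, ai]

  std_res <- function(Y, rows) {
    Ys <- Y[rows, , drop = FALSE]
    mu <- colMeans(Ys)
    sdv <- apply(Ys, 2, sd)
    lo <- sdv < sd_floor * median(sdv[sdv > 0])
    sdv[lo | sdv == 0] <- Inf               # degenerate voxels -> zeros
    Ys <- sweep(sweep(Ys, 2, mu), 2, sdv, `/`)
    residualise(Ys, Z[rows, , drop = FALSE])
  }
  effect_matrix <- function(rows) {
    ar <- residualise(matrix(a[rows]), Z[rows, , drop = FALSE])
    saa <- sum(ar^2)
    E <- matrix(0, V, P)
    for (j in seq_len(P))
      E[, j] <- as.vector(crossprod(std_res(data[[j]], rows), ar)) / saa
    E
  }

  all_rows <- seq_len(n)
  E <- effect_matrix(all_rows)
  sv <- svd(E)
  K <- min(P, V)
  d <- sv$d[seq_len(K)]
  var_frac <- d^2 / sum(d^2)

  ## split-sample trace inference
  split <- withr::with_seed(seed, sample(all_rows))
  half1 <- sort(split[seq_len(floor(n / 2))])
  half2 <- sort(setdiff(all_rows, half1))
  pvals <- rep(NA_real_, K)
  v_err <- length(half2) - ncol(X)
  if (v_err - P - 1 > -1) {
    E1 <- effect_matrix(half1)
    U1 <- svd(E1)$u
    ar2 <- residualise(matrix(a[half2]), Z[half2, , drop = FALSE])
    saa2 <- sum(ar2^2)
    res2 <- lapply(pars, function(p) std_res(data[[p]], half2))
    for (k in seq_len(K)) {
      ## held-out component scores per parameter: n2 x P
      S <- vapply(res2, function(R) as.vector(R %*% U1[, k]), numeric(length(half2)))
      bh <- crossprod(S, ar2) / saa2               # P x 1 age effects
      H <- (saa2) * tcrossprod(bh)                 # hypothesis SSP
      Eres <- crossprod(S - ar2 %*% t(bh))         # error SSP
      tr <- tryCatch(sum(diag(H %*% solve(Eres))), error = function(e) NA_real_)
      if (is.finite(tr))
        pvals[k] <- lh_trace_test(tr / v_err * v_err, P, 1, v_err)$p
    }
  }
  structure(list(maps = sv$u[, seq_len(K), drop = FALSE] %*% diag(d, K),
                 loadings = sv$v[, seq_len(K), drop = FALSE],
                 d = d, var_frac = var_frac, p = pvals,
                 parameters = pars, n = n),
            class = "vbq_mlm")
}

#' @export
print.vbq_mlm <- function(x, ...) {
  cat(sprintf("<vbq_mlm> %d parameters, %d components\n",
              length(x$parameters), length(x$d)))
  for (k in seq_along(x$d))
    cat(sprintf("  component %d: %.1f%% variance, p = %.3g\n",
                k, 100 * x$var_frac[k], x$p[k]))
  invisible(x)
}
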