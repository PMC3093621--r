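test_that("exclusive tissue masks follow the threshold and dominance rules", {
  mk <- function(g, w) {
    gm <- array(g, c(2, 2, 2)); wm <- array(w, c(2, 2, 2))
    build_tissue_masks(list(gm), list(wm))
  }
  m <- suppressWarnings(mk(0.5, 0.1))
  expect_true(all(m$gm_mask) && !any(m$wm_mask))
  ## tie: neither mask
  m2 <- suppressWarnings(mk(0.5, 0.5))
  expect_false(any(m2$gm_mask) || any(m2$wm_mask))
  ## below threshold: neither
  m3 <- suppressWarnings(mk(0.15, 0.1))
  expect_false(any(m3$gm_mask) || any(m3$wm_mask))
  ## disjoint by construction on random maps
  withr::with_seed(2, {
    gms <- lapply(1:4, function(i) array(runif(64), c(4, 4, 4)))
    wms <- lapply(1:4, function(i) array(runif(64), c(4, 4, 4)))
  })
  m4 <- build_tissue_masks(gms, wms)
  expect_false(any(m4$gm_mask & m4$wm_mask))
})

test_that("block-diagonal design has centred regressors and detects collinearity", {
  cov <- demo_covariates()
  des <- build_design(cov, c("mtsat", "r1"))
  expect_equal(dim(des$design), c(52L, 8L))
  expect_lt(abs(sum(des$block[, "age"])), 1e-10)
  expect_lt(abs(sum(des$block[, "gender"])), 1e-10)
  expect_setequal(sort(unique(des$block[, "gender"] - min(des$block[, "gender"]))),
                  c(0, 1))
  cov2 <- cov; cov2$tiv <- 5
  expect_error(build_design(cov2, "mtsat"), "tiv")
  cov3 <- cov[, c("subject_id", "age", "tiv")]
  expect_error(build_design(cov3, "mtsat"), "gender")
})

test_that("concatenated block-diagonal fit equals separate per-parameter fits", {
  cov <- demo_covariates()
  pars <- paste0("p", 1:5)
  des <- build_design(cov, pars)
  data <- withr::with_seed(8, {
    d <- lapply(pars, function(p) matrix(rnorm(26 * 150), 26, 150))
    names(d) <- pars; d
  })
  fit <- fit_glm(data, des)
  for (p in pars) {
    sep <- qr.coef(qr(des$block), data[[p]])    # independent per-block solve
    expect_lt(max(abs(sep - fit$blocks[[p]]$beta)), 1e-10)
  }
  ## exact recovery of noise-free coefficients, zero residual variance
  beta <- withr::with_seed(9, matrix(rnorm(4 * 30), 4, 30))
  y <- des$block %*% beta
  f2 <- fit_glm(list(p1 = y), build_design(cov, "p1"))
  expect_lt(max(abs(f2$blocks$p1$beta - beta)), 1e-10)
  expect_lt(max(f2$blocks$p1$sigma2), 1e-20)
  expect_equal(fit$dof, 22L)
})

test_that("t maps match a small-sample regression oracle and its symmetries", {
  cov <- demo_covariates()
  des <- build_design(cov, "p1")
  y <- withr::with_seed(10, matrix(rnorm(26 * 40), 26, 40))
  fit <- fit_glm(list(p1 = y), des)
  tm <- t_map(fit, "age")
  o <- summary(lm(y[, 7] ~ des$block[, -1]))$coefficients
  expect_equal(tm$t[7], o[2, "t value"], tolerance = 1e-10)
  expect_equal(tm$p[7], o[2, "Pr(>|t|)"], tolerance = 1e-10)
  tn <- t_map(fit, c(0, -1, 0, 0))
  expect_equal(tn$t, -tm$t)
  expect_equal(tn$p, tm$p)
  ## null-contrast voxel: noise orthogonal to the age regressor -> T ~ 0, p ~ 1
  X <- des$block
  ar <- resid(lm(X[, "age"] ~ X[, -2]))
  y2 <- y
  y2[, 3] <- y[, 3] - ar * sum(ar * y[, 3]) / sum(ar^2)
  f3 <- fit_glm(list(p1 = y2), des)
  t3 <- t_map(f3, "age")
  expect_equal(t3$t[3], 0, tolerance = 1e-7)
  expect_gt(t3$p[3], 0.999999)
})

test_that("FWE thresholding flags extremes and respects the Bonferroni bound", {
  cov <- demo_covariates()
  des <- build_design(cov, "p1")
  y <- withr::with_seed(12, matrix(rnorm(26 * 500), 26, 500))
  y[, 100] <- y[, 100] + des$block[, "age"] * 2
  fit <- fit_glm(list(p1 = y), des)
  tm <- t_map(fit, "age")
  fw <- fwe_threshold(fit, tm, method = "bonferroni")
  expect_true(fw$fwe[100])
  expect_true(all(tm$p[fw$fwe] <= 0.05 / 500))
  expect_true(all(fw$fwe | !fw$trend | tm$p <= 0.001))
  fwp <- fwe_threshold(fit, tm, method = "permutation", n_perm = 500, seed = 3)
  expect_true(fwp$fwe[100])
  expect_length(fwp$max_t, 500)
  expect_error(fwe_threshold(fit, tm, method = "permutation", n_perm = 50),
               ">= 100")
  ## single-voxel mask: FWE threshold equals the uncorrected level
  f1 <- fit_glm(list(p1 = y[, 100, drop = FALSE]), des)
  t1 <- t_map(f1, "age")
  fw1 <- fwe_threshold(f1, t1, method = "bonferroni")
  expect_equal(fw1$t_crit, qt(0.025, f1$dof, lower.tail = FALSE))
})

test_that("peak tables report local maxima with world coordinates", {
  cov <- demo_covariates()
  des <- build_design(cov, "p1")
  mask <- array(TRUE, c(8, 8, 8))
  y <- withr::with_seed(14, matrix(rnorm(26 * 512, 0, 0.1), 26, 512))
  peak_vox <- 3 + 8 * (4 - 1) + 64 * (5 - 1)    # voxel (3,4,5)
  y[, peak_vox] <- y[, peak_vox] + des$block[, "age"] * 1
  fit <- fit_glm(list(p1 = y), des, mask = mask, voxel_size_mm = c(2, 2, 2))
  tm <- t_map(fit, "age")
  fw <- fwe_threshold(fit, tm, method = "bonferroni")
  expect_gte(nrow(fw$peaks), 1)
  top <- fw$peaks[1, ]
  expect_equal(c(top$x_mm, top$y_mm, top$z_mm), c(2 * 2, 3 * 2, 4 * 2))
  expect_true(top$p_fwe <= 0.05)
  expect_equal(sign(top$z), sign(top$t))
})

test_that("overlap labels encode direction combinations uniquely", {
  mk_tm <- function(t, p) list(t = t, p = p)
  n <- 6
  t1 <- c(5, -5, 0, 5, 0, 0); p1 <- c(1e-5, 1e-5, 1, 1e-5, 1, 1)
  t2 <- c(0, 4, 0, 4, -4, 0); p2 <- c(1, 1e-4, 1, 1e-4, 1e-4, 1)
  lab <- overlap_labels(list(MTsat = mk_tm(t1, p1), R2s = mk_tm(t2, p2)))
  expect_equal(lab$labels[3], 0L)
  expect_equal(lab$labels[6], 0L)
  ## same combination -> same label; distinct combinations -> distinct labels
  expect_false(lab$labels[1] == lab$labels[2])
  expect_false(lab$labels[2] == lab$labels[4])
  expect_equal(length(unique(lab$labels[lab$labels > 0])), 4L)
  expect_true(any(grepl("MTsat\\+, R2s\\+", lab$legend$combination)))
  ## nothing suprathreshold -> all zero
  lab0 <- overlap_labels(list(a = mk_tm(rep(0, 4), rep(1, 4))))
  expect_true(all(lab0$labels == 0))
  ## two maps with disjoint suprathreshold sets -> exactly two labels
  labd <- overlap_labels(list(a = mk_tm(c(5, 0), c(1e-5, 1)),
                              b = mk_tm(c(0, 5), c(1, 1e-5))))
  expect_equal(sort(unique(labd$labels)), c(1L, 2L))
})
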