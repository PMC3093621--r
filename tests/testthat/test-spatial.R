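test_that("jacobian determinant handles identity, scaling and random fields", {
  def0 <- identity_deformation(c(12, 12, 12))
  expect_lt(max(abs(jacobian_determinant(def0) - 1)), 1e-12)
  ## uniform 1.1x scaling: phi(x) = 1.1 x, so u = 0.1 x
  sh <- c(12, 12, 12)
  xs <- seq_len(12) - 1
  def0$displacement[, , , 1] <- 0.1 * array(rep(xs, 144), sh)
  def0$displacement[, , , 2] <- 0.1 * array(rep(rep(xs, each = 12), 12), sh)
  def0$displacement[, , , 3] <- 0.1 * array(rep(xs, each = 144), sh)
  j <- jacobian_determinant(def0)
  expect_lt(max(abs(j[2:11, 2:11, 2:11] - 1.1^3)), 1e-12)
  ## random smooth field vs independent finite-difference oracle
  def <- make_deformation(c(12, 12, 12), amplitude_mm = 2, seed = 3)
  j2 <- jacobian_determinant(def)
  u <- def$displacement
  num_grad <- function(comp, axis) {
    d <- array(NA_real_, c(12, 12, 12))
    for (i in 2:11) {
      idx <- list(1:12, 1:12, 1:12); idx[[axis]] <- i
      hi <- idx; hi[[axis]] <- i + 1
      lo <- idx; lo[[axis]] <- i - 1
      d[idx[[1]], idx[[2]], idx[[3]]] <-
        (u[hi[[1]], hi[[2]], hi[[3]], comp] - u[lo[[1]], lo[[2]], lo[[3]], comp]) / 2
    }
    d
  }
  v <- c(6, 7, 5)
  J <- diag(3)
  for (i in 1:3) for (k in 1:3)
    J[i, k] <- J[i, k] + num_grad(i, k)[v[1], v[2], v[3]]
  expect_lt(abs(det(J) - j2[v[1], v[2], v[3]]), 1e-6)
})

test_that("warping: identity pull-back, constants, shifted impulses", {
  sh <- c(12, 12, 12)
  def0 <- identity_deformation(sh)
  v <- array(rnorm(prod(sh)), sh)
  for (ord in c(0L, 1L, 3L))
    expect_equal(warp_volume(v, def0, ord), v,
                 tolerance = if (ord == 3) 1e-10 else 0)
  ## constant volume stays constant wherever defined
  w <- warp_volume(array(4, sh), make_deformation(sh, amplitude_mm = 1, seed = 2), 1)
  expect_lt(max(abs(w[!is.na(w)] - 4)), 1e-12)
  ## +3 mm displacement along x pulls the impulse 3 voxels down
  defs <- identity_deformation(sh)
  defs$displacement[, , , 1] <- 3
  d <- array(0, sh); d[9, 6, 6] <- 1
  wd <- warp_volume(d, defs, 1)
  expect_equal(wd[6, 6, 6], 1)
  expect_equal(sum(wd, na.rm = TRUE), 1)
  expect_error(warp_volume(v, def0, 2L), "order")
  ## out-of-view samples are NA
  defo <- identity_deformation(sh)
  defo$displacement[, , , 1] <- -100
  expect_true(all(is.na(warp_volume(v, defo, 1))))
})

test_that("tissue weights are the clipped product of Jacobian and probability", {
  j <- array(2, c(4, 4, 4)); t_ <- array(0.5, c(4, 4, 4))
  expect_equal(compute_weights(j, t_, "GM")$w, array(1, c(4, 4, 4)))
  expect_equal(compute_weights(array(1, dim(j)), array(1, dim(j)), "WM")$w,
               array(1, c(4, 4, 4)))
  expect_true(all(compute_weights(j, array(0, dim(j)), "GM")$w == 0))
  expect_error(compute_weights(j, array(0.5, c(3, 4, 4)), "GM"), "differ")
})

test_that("gaussian smoothing matches a dense convolution oracle", {
  expect_equal(gauss_kernel_1d(0, 1), 1)
  k <- gauss_kernel_1d(6, 1)
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(length(k), 2 * ceiling(4 * 6 / sqrt(8 * log(2))) + 1)
  v <- withr::with_seed(1, array(rnorm(16^3), c(16, 16, 16)))
  expect_identical(gaussian_smooth(v, 0), v)
  sm <- gaussian_smooth(v, 6, c(1, 1, 1))
  expect_lt(max(abs(sm - dense_smooth_oracle(v, 6))), 1e-10)
  ## constant preserved in the interior
  cst <- gaussian_smooth(array(3, c(24, 24, 24)), 4, c(1, 1, 1))
  expect_lt(max(abs(cst[12:13, 12:13, 12:13] - 3)), 1e-12)
})

test_that("tissue-weighted smoothing preserves constants, support and range", {
  sh <- c(16, 16, 16)
  withr::with_seed(5, {
    w <- array(runif(prod(sh)), sh)
    w[sample(prod(sh), 1500)] <- 0
    s <- array(rnorm(prod(sh)), sh)
  })
  out <- tissue_weighted_smooth(s, w, 5, voxel_size_mm = c(1, 1, 1))
  ## defining identity g*(ws) = out * g*(w)
  num <- gaussian_smooth(w * s, 5); den <- gaussian_smooth(w, 5)
  expect_lt(max(abs(out$data[out$mask] * den[out$mask] - num[out$mask])), 1e-12)
  ## range preservation on the weight support
  rng <- range(s[w > 0])
  expect_true(all(out$data[out$mask] >= rng[1] - 1e-12 &
                    out$data[out$mask] <= rng[2] + 1e-12))
  ## no bleed: off-support values are irrelevant
  s2 <- array(2, sh); s2[w == 0] <- 1e9
  out2 <- tissue_weighted_smooth(s2, w, 5, voxel_size_mm = c(1, 1, 1))
  expect_lt(max(abs(out2$data[out2$mask] - 2)), 1e-10)
  ## zero FWHM reproduces the input on the support
  out0 <- tissue_weighted_smooth(s, w, 0, voxel_size_mm = c(1, 1, 1))
  expect_lt(max(abs(out0$data[w > 0] - s[w > 0])), 1e-12)
  expect_warning(tissue_weighted_smooth(s, array(0, sh), 5,
                                        voxel_size_mm = c(1, 1, 1)),
                 "all weights")
})

test_that("tissue-weighted smoothing equals the direct per-voxel oracle", {
  sh <- c(16, 16, 16)
  withr::with_seed(11, {
    w <- array(runif(prod(sh)), sh); w[sample(prod(sh), 800)] <- 0
    s <- array(rnorm(prod(sh), 1, 2), sh)
  })
  out <- tissue_weighted_smooth(s, w, 6, voxel_size_mm = c(1, 1, 1))
  onum <- dense_smooth_oracle(w * s, 6)
  oden <- dense_smooth_oracle(w, 6)
  sel <- out$mask
  expect_lt(max(abs(out$data[sel] - onum[sel] / oden[sel])), 1e-10)
})

test_that("modulation multiplies by the Jacobian before smoothing", {
  sh <- c(12, 12, 12)
  t_ <- withr::with_seed(3, array(runif(prod(sh)), sh))
  j1 <- array(1, sh)
  expect_equal(modulate_and_smooth(t_, j1, 0)$data, t_)
  out <- modulate_and_smooth(array(1, sh), array(0.5, sh), 2)
  expect_lt(max(abs(out$data[6:7, 6:7, 6:7] - 0.5)), 1e-9)
  ## mass conservation for compact support away from borders
  tc <- array(0, sh); tc[5:8, 5:8, 5:8] <- 1
  jc <- array(0.8, sh)
  sm <- modulate_and_smooth(tc, jc, 2)
  expect_lt(abs(sum(sm$data) / sum(tc * jc) - 1), 1e-3)
})
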