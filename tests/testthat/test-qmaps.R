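test_that("echo averaging is the arithmetic mean of the leading echoes", {
  sq <- seq_params(25, 6, 1:6, "PDw")
  echoes <- lapply(1:6, function(i) array(i, c(4, 4, 4)))
  ser <- multiecho_series(echoes, sq)
  expect_equal(average_echoes(ser, 6), array(3.5, c(4, 4, 4)))
  expect_equal(average_echoes(ser, 1), array(1, c(4, 4, 4)))
  expect_error(average_echoes(ser, 7), "between 1 and")
  ## noiseless decaying echoes: mean equals S0 * mean(exp(-TE * R2*))
  ph <- noiseless_phantom()
  avg <- average_echoes(ph$series$pdw, 6)
  te <- ph$seqs$pdw$te_ms[1:6] / 1000
  s0 <- ph$series$pdw$echoes[[1]] / exp(-te[1] * ph$gt$r2s)
  k <- Reduce(`+`, lapply(te, function(t) exp(-t * ph$gt$r2s))) / 6
  expect_lt(max(abs(avg - s0 * k)), 1e-9)
})

test_that("R2* log-linear fit is exact on noiseless decays and masks bad voxels", {
  te <- c(2.2, 4.7, 7.2, 9.7, 12.2, 14.7, 17.2, 19.7)
  sq <- seq_params(23.7, 6, te, "PDw")
  dm <- c(4, 4, 4)
  echoes <- lapply(te / 1000, function(t) array(100 * exp(-50 * t), dm))
  fit <- fit_r2star(multiecho_series(echoes, sq))
  expect_lt(max(abs(fit$r2s$data - 50) / 50), 1e-9)
  expect_lt(max(abs(fit$s0 - 100)), 1e-6)
  ## constant signal -> zero rate
  fitc <- fit_r2star(multiecho_series(lapply(1:8, function(i) array(7, dm)), sq))
  expect_lt(max(abs(fitc$r2s$data)), 1e-12)
  ## a zero echo at one voxel is excluded, the fit uses the rest
  echoes2 <- echoes; echoes2[[4]][2, 2, 2] <- 0
  fit2 <- fit_r2star(multiecho_series(echoes2, sq))
  expect_true(fit2$r2s$mask[2, 2, 2])
  expect_lt(abs(fit2$r2s$data[2, 2, 2] - 50) / 50, 1e-9)
  ## fewer than 3 positive echoes -> masked, not an error
  echoes3 <- echoes
  for (e in 1:6) echoes3[[e]][3, 3, 3] <- -1
  fit3 <- fit_r2star(multiecho_series(echoes3, sq))
  expect_false(fit3$r2s$mask[3, 3, 3])
  expect_true(is.na(fit3$r2s$data[3, 3, 3]))
})

test_that("noiseless rational-model round trip recovers all four maps", {
  ph <- noiseless_phantom()
  m <- fit_parameter_maps(ph$series$t1w, ph$series$pdw, ph$series$mtw)
  for (p in c("r1", "r2s", "mtsat", "amp")) {
    truth <- ph$gt[[p]]
    sel <- m[[p]]$mask & truth > 1e-3
    expect_lt(max(abs(m[[p]]$data[sel] - truth[sel]) / truth[sel]), 1e-6)
  }
})

test_that("identical sequence parameters are rejected for the dual-angle fit", {
  sq <- seq_params(23.7, 6, c(2.2, 4.7, 7.2), "PDw")
  v <- array(1, c(4, 4, 4))
  expect_error(estimate_r1_amplitude(v, v, sq, sq), "identical")
})

test_that("MTsat is zero without saturation and monotone in amplitude", {
  ph <- noiseless_phantom()
  gt0 <- ph$gt; gt0$mtsat[] <- 0
  smt0 <- simulate_multiecho_flash(gt0, ph$seqs$mtw, "rational", 0)
  s_t1 <- average_echoes(ph$series$t1w); s_pd <- average_echoes(ph$series$pdw)
  ra <- estimate_r1_amplitude(s_t1, s_pd, ph$seqs$t1w, ph$seqs$pdw)
  ## the T1w/PDw signals embed the same mean T2* decay as the MTw average
  mt0 <- compute_mtsat(average_echoes(smt0), ra$amp, ra$r1, ph$seqs$mtw)
  expect_lt(max(abs(mt0$data[mt0$mask])), 1e-9)
  ## doubling the amplitude strictly increases MTsat everywhere
  s_mt <- average_echoes(ph$series$mtw)
  amp2 <- ra$amp; amp2$data <- amp2$data * 2
  mt1 <- compute_mtsat(s_mt, ra$amp, ra$r1, ph$seqs$mtw)
  mt2 <- compute_mtsat(s_mt, amp2, ra$r1, ph$seqs$mtw)
  sel <- mt1$mask & mt2$mask
  expect_true(all(mt2$data[sel] > mt1$data[sel]))
})

test_that("MTsat is insensitive to transmit bias while apparent R1 is not", {
  tis <- make_tissue_phantom(c(16, 16, 16), seed = 2)
  gt <- make_true_maps(tis, b1_range = c(0.9, 1.1), seed = 6)
  seqs <- flash_sequences()
  ser <- lapply(seqs, function(sq) simulate_multiecho_flash(gt, sq, "rational", 0))
  m <- fit_parameter_maps(ser$t1w, ser$pdw, ser$mtw)
  sel <- m$mtsat$mask & gt$mtsat > 0.5
  expect_lt(median(abs(m$mtsat$data[sel] - gt$mtsat[sel]) / gt$mtsat[sel]), 5e-6)
  selr <- m$r1$mask & gt$r1 > 0.5
  expect_gt(median(abs(m$r1$data[selr] - gt$r1[selr]) / gt$r1[selr]), 0.01)
})

test_that("transmit-bias correction follows the inverse-square law", {
  ph <- noiseless_phantom()
  tis <- ph$tissues
  gtb <- make_true_maps(tis, b1_range = c(1.1, 1.1), seed = 3)  # constant 1.1
  ser <- lapply(ph$seqs, function(sq) simulate_multiecho_flash(gtb, sq, "rational", 0))
  m <- fit_parameter_maps(ser$t1w, ser$pdw, ser$mtw)
  sel <- m$r1$mask & gtb$r1 > 1e-3
  ## apparent R1 carries the 1/b1^2 bias of the achieved flip angle
  expect_lt(max(abs(m$r1$data[sel] - gtb$r1[sel] / 1.1^2) /
                  (gtb$r1[sel] / 1.1^2)), 1e-6)
  corr <- correct_r1_bias(m$r1, b1 = gtb$b1)
  expect_lt(max(abs(corr$r1$data[sel] - gtb$r1[sel]) / gtb$r1[sel]), 1e-6)
  ## unit bias is a no-op
  same <- correct_r1_bias(m$r1, b1 = array(1, dim(m$r1$data)))
  expect_identical(same$r1$data, m$r1$data)
  expect_error(correct_r1_bias(m$r1), "at least one")
  expect_error(correct_r1_bias(m$r1, b1 = array(-1, dim(m$r1$data))), "positive")
})

test_that("estimated bias field shrinks intra-WM spread at least five-fold", {
  tis <- make_tissue_phantom(c(20, 20, 20), seed = 4)
  gtb <- make_true_maps(tis, b1_range = c(0.8, 1.2), seed = 8)
  seqs <- flash_sequences()
  ser <- lapply(seqs, function(sq) simulate_multiecho_flash(gtb, sq, "rational", 0))
  raw <- fit_parameter_maps(ser$t1w, ser$pdw, ser$mtw)
  est <- correct_r1_bias(raw$r1, tissues = tis)
  wm <- tis$wm >= 0.9
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(raw$r1$data[wm]) / cv(est$r1$data[wm]), 5)
})

test_that("ernst-model inputs keep R1 and MTsat within five percent", {
  ph <- noiseless_phantom()
  ser <- lapply(ph$seqs, function(sq)
    simulate_multiecho_flash(ph$gt, sq, "ernst", 0))
  m <- fit_parameter_maps(ser$t1w, ser$pdw, ser$mtw)
  for (p in c("r1", "mtsat")) {
    truth <- ph$gt[[p]]
    sel <- m[[p]]$mask & truth > 0.1
    expect_lt(max(abs(m[[p]]$data[sel] - truth[sel]) / truth[sel]), 0.05)
  }
})
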