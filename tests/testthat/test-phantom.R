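test_that("tissue phantom respects probability invariants and determinism", {
  tis <- make_tissue_phantom(c(16, 16, 16), seed = 7)
  tot <- tis$gm + tis$wm + tis$csf
  expect_true(all(tot <= 1 + 1e-9))
  expect_true(all(tis$gm >= 0 & tis$gm <= 1))
  expect_true(all(tis$wm >= 0 & tis$wm <= 1))
  expect_identical(tis, make_tissue_phantom(c(16, 16, 16), seed = 7))
  ## partial-volume voxels exist
  tis32 <- make_tissue_phantom(c(32, 32, 32), seed = 1)
  expect_true(any(tis32$gm > 0.2 & tis32$gm < 0.8))
  expect_error(make_tissue_phantom(c(4, 16, 16)), "must be >= 8")
})

test_that("true maps are exact tissue mixtures and honour degenerate b1", {
  tis <- make_tissue_phantom(c(12, 12, 12), seed = 3)
  tv <- default_tissue_values()
  gt <- make_true_maps(tis, tv, b1_range = c(1, 1), seed = 1)
  mixture <- tis$gm * tv["r1", "gm"] + tis$wm * tv["r1", "wm"] +
    tis$csf * tv["r1", "csf"]
  expect_lt(max(abs(gt$r1 - mixture)), 1e-12)
  expect_true(all(gt$b1 == 1))
  ## hand-built half/half voxel
  tis$gm[6, 6, 6] <- 0.5; tis$wm[6, 6, 6] <- 0.5; tis$csf[6, 6, 6] <- 0
  tv2 <- tv; tv2["r1", ] <- c(0.6, 1.0, 0.2)
  gt2 <- make_true_maps(tis, tv2, b1_range = c(1, 1))
  expect_equal(gt2$r1[6, 6, 6], 0.8, tolerance = 1e-12)
  expect_error(make_true_maps(tis, tv - 1), "nonnegative")
})

test_that("flash signals follow the closed-form decay and steady state", {
  tis <- make_tissue_phantom(c(10, 10, 10), seed = 5)
  gt <- make_true_maps(tis, b1_range = c(1, 1), seed = 2)
  seqs <- flash_sequences()
  ## no decay: all echoes equal
  gt0 <- gt; gt0$r2s[] <- 0
  s0 <- simulate_multiecho_flash(gt0, seqs$pdw, "rational", 0)
  for (e in 2:8) expect_equal(s0$echoes[[e]], s0$echoes[[1]])
  ## log-signal slope equals -r2s at the acquisition's echo times
  gt50 <- gt; gt50$r2s[] <- 50
  s50 <- simulate_multiecho_flash(gt50, seqs$pdw, "rational", 0)
  v <- c(5, 5, 5)
  y <- log(vapply(s50$echoes, function(e) e[v[1], v[2], v[3]], 1))
  slope <- coef(lm(y ~ I(seqs$pdw$te_ms / 1000)))[2]
  expect_equal(unname(slope), -50, tolerance = 1e-9)
  ## rational vs ernst steady state within 1% over the tissue regime
  ## (R1*TR between 0.01 and 0.05; the agreement degrades to ~1.02% in the
  ## R1 -> 0 limit at a 20 degree flip)
  se <- simulate_multiecho_flash(gt, seqs$t1w, "ernst", 0)
  sr <- simulate_multiecho_flash(gt, seqs$t1w, "rational", 0)
  inb <- gt$amp > 1 & gt$r1 * 0.0187 >= 0.01 & gt$r1 * 0.0187 <= 0.05
  rel <- abs(se$echoes[[1]][inb] / sr$echoes[[1]][inb] - 1)
  expect_lt(max(rel), 0.01)
  expect_error(simulate_multiecho_flash(gt, seqs$t1w, noise_sd = -1), ">= 0")
})

test_that("deformation generator: identity at zero amplitude, positive Jacobians", {
  def0 <- make_deformation(c(12, 12, 12), amplitude_mm = 0)
  expect_true(all(def0$displacement == 0))
  expect_lt(max(abs(jacobian_determinant(def0) - 1)), 1e-12)
  def <- make_deformation(c(12, 12, 12), amplitude_mm = 2, seed = 7)
  expect_gt(min(jacobian_determinant(def)), 0)
  expect_lte(max(abs(def$displacement)), 2 + 1e-12)
  expect_identical(def, make_deformation(c(12, 12, 12), amplitude_mm = 2, seed = 7))
})

test_that("cohorts are reproducible with the stated covariate structure", {
  tis <- make_tissue_phantom(c(12, 12, 12), seed = 1)
  spc <- cohort_spec(n_subjects = 5, seed = 3,
                     noise_sd = c(r1 = 0, r2s = 0, mtsat = 0, amp = 0))
  coh <- make_cohort(spc, tis, echo_noise_sd = 0, deformation_amplitude_mm = 0.5)
  expect_equal(nrow(coh$covariates), 5)
  expect_named(coh$covariates, c("subject_id", "age", "gender", "tiv"))
  expect_true(all(coh$covariates$age >= 18 & coh$covariates$age <= 85))
  coh2 <- make_cohort(spc, tis, echo_noise_sd = 0, deformation_amplitude_mm = 0.5)
  expect_identical(coh$covariates, coh2$covariates)
  expect_identical(coh$subjects[[3]]$truth$mtsat, coh2$subjects[[3]]$truth$mtsat)
})

test_that("noiseless cohort age effect is recovered exactly by OLS on the truth", {
  tis <- make_tissue_phantom(c(14, 14, 14), seed = 9)
  spc <- cohort_spec(n_subjects = 26, seed = 4,
                     noise_sd = c(r1 = 0, r2s = 0, mtsat = 0, amp = 0))
  coh <- make_cohort(spc, tis, echo_noise_sd = 0, vary_geometry = FALSE,
                     deformation_amplitude_mm = 0)
  M <- coh$effects[[1]]
  ages <- coh$covariates$age
  vals <- vapply(coh$subjects, function(s) mean(s$truth$mtsat[M > 0.5]), 1)
  slope <- coef(lm(vals ~ ages))[2]
  expect_equal(unname(slope), -0.05, tolerance = 1e-10)
  ## null cohort: no age dependence of the truth
  spc0 <- cohort_spec(n_subjects = 6, seed = 4, effect_table = NULL,
                      noise_sd = c(r1 = 0, r2s = 0, mtsat = 0, amp = 0))
  coh0 <- make_cohort(spc0, tis, echo_noise_sd = 0, vary_geometry = FALSE,
                      deformation_amplitude_mm = 0, b1_range = c(1, 1))
  expect_identical(coh0$subjects[[1]]$truth$mtsat, coh0$subjects[[6]]$truth$mtsat)
})
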