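## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

## noiseless rational-model phantom with homogeneous transmit field
noiseless_phantom <- function() fixture("noiseless", function() {
  tis <- make_tissue_phantom(c(20, 20, 20), seed = 1)
  gt <- make_true_maps(tis, b1_range = c(1, 1), seed = 2)
  seqs <- flash_sequences()
  series <- lapply(seqs, function(sq)
    simulate_multiecho_flash(gt, sq, "rational", noise_sd = 0, seed = 3))
  list(tissues = tis, gt = gt, seqs = seqs, series = series)
})

## 26-subject covariate table mirroring the study design
demo_covariates <- function(seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    subject_id = sprintf("s%02d", 1:26),
    age = runif(26, 18, 85),
    gender = sample(c(rep("M", 19), rep("F", 7))),
    tiv = rnorm(26, 1400, 100)))
}

## dense 3-D convolution oracle: explicit shift-and-accumulate with the full
## (non-separable) 3-D kernel, independent of the package's separable path
dense_smooth_oracle <- function(vol, fwhm_mm, voxel_size_mm = c(1, 1, 1)) {
  ks <- lapply(1:3, function(i) gauss_kernel_1d(fwhm_mm, voxel_size_mm[i]))
  rs <- vapply(ks, function(k) (length(k) - 1L) %/% 2L, 1L)
  dm <- dim(vol)
  out <- array(0, dm)
  for (a in -rs[1]:rs[1]) for (b in -rs[2]:rs[2]) for (c_ in -rs[3]:rs[3]) {
    w <- ks[[1]][a + rs[1] + 1] * ks[[2]][b + rs[2] + 1] * ks[[3]][c_ + rs[3] + 1]
    xs <- max(1, 1 + a):min(dm[1], dm[1] + a)
    ys <- max(1, 1 + b):min(dm[2], dm[2] + b)
    zs <- max(1, 1 + c_):min(dm[3], dm[3] + c_)
    out[xs - a, ys - b, zs - c_] <- out[xs - a, ys - b, zs - c_] +
      w * vol[xs, ys, zs]
  }
  out
}

## identity deformation on a grid
identity_deformation <- function(shape, voxel_size_mm = c(1, 1, 1)) {
  make_deformation(shape, voxel_size_mm, amplitude_mm = 0)
}
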