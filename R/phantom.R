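## Synthetic phantom: tissue geometry, ground-truth parameter maps, FLASH
## signal simulation, deformations and age cohorts. The generator is the
## test-bed for every downstream stage; all randomness is seed-controlled and
## bit-reproducible.

## ---- tissue geometry -------------------------------------------------------

## logistic edge profile: 1 well inside, 0 well outside, soft over ~width vox
soft_inside <- function(r, radius, width) 1 / (1 + exp((r - radius) / width))

#' Generate a nested-ellipsoid tissue phantom
#'
#' Builds grey-matter shell / white-matter core / CSF background probability
#' maps with soft (partial-volume) boundaries. The ellipsoid axes, centre and
#' radii are jittered reproducibly from the seed, so different seeds give
#' slightly different anatomies (useful for simulating inter-subject
#' variability).
#'
#' @param shape Integer triple, all dimensions >= 8.
#' @param voxel_size_mm Voxel size triple in mm.
#' @param seed Integer seed; the same seed gives bit-identical output.
#' @param boundary_width_vox Scale of the logistic partial-volume edge in
#'   voxels (the 10--90% transition spans about `4.4 * boundary_width_vox`
#'   voxels; the default 0.4 gives a transition just under two voxels,
#'   matching the point-spread-limited sharpness of real segmentations).
#' @param jitter Relative jitter of radii/centre (0 disables anatomical
#'   variability).
#' @return An object of class `tissue_probs` with fields `gm`, `wm`, `csf`
#'   (arrays in `[0,1]` with `gm + wm + csf <= 1` everywhere),
#'   `voxel_size_mm` and `shape`.
#' @export
make_tissue_phantom <- function(shape, voxel_size_mm = c(1, 1, 1), seed = 1L,
                                boundary_width_vox = 0.4, jitter = 0.02) {
  shape <- as.integer(shape)
  check_triple(shape, "shape")
  check_triple(voxel_size_mm, "voxel_size_mm")
  if (any(shape < 8L))
    vbq_stop("all dimensions of 'shape' must be >= 8 (got %s)",
             paste(shape, collapse = "x"))
  withr::with_seed(seed, {
    centre <- (shape + 1) / 2 + runif(3, -jitter, jitter) * shape
    ax <- 1 + runif(3, -2 * jitter, 2 * jitter)    # ellipsoid axis scales
    r_wm <- 0.34 * min(shape) * (1 + runif(1, -jitter, jitter))
    r_gm <- 0.46 * min(shape) * (1 + runif(1, -jitter, jitter))
    r_head <- 0.58 * min(shape) * (1 + runif(1, -jitter, jitter))
  })
  g <- lapply(1:3, function(i) (seq_len(shape[i]) - centre[i]) / ax[i])
  r <- sqrt(
    outer(outer(g[[1]]^2, g[[2]]^2, `+`), g[[3]]^2, `+`)
  )
  p_wm <- soft_inside(r, r_wm, boundary_width_vox)
  p_brain <- soft_inside(r, r_gm, boundary_width_vox)
  p_head <- soft_inside(r, r_head, boundary_width_vox)  # outside: air
  gm <- pmax(p_brain - p_wm, 0)
  csf <- pmax(p_head - p_brain, 0)
  dim(gm) <- dim(p_wm) <- dim(csf) <- shape
  structure(list(gm = gm, wm = p_wm, csf = csf,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 shape = shape,
                 boundary_width_vox = boundary_width_vox, jitter = jitter),
            class = "tissue_probs")
}

#' @export
print.tissue_probs <- function(x, ...) {
  cat(sprintf("<tissue_probs> %s @ %.3g mm; GM/WM/CSF volume fractions %.2f/%.2f/%.2f\n",
              paste(x$shape, collapse = "x"), x$voxel_size_mm[1],
              mean(x$gm), mean(x$wm), mean(x$csf)))
  invisible(x)
}

## ---- ground truth ----------------------------------------------------------

#' Default per-tissue parameter means
#'
#' Literature-typical 3T values: R1 and R2* in s^-1, MT saturation in p.u.,
#' amplitude in a.u. (proportional to proton density).
#'
#' @return A data frame with rows `r1`, `r2s`, `mtsat`, `amp` and columns
#'   `gm`, `wm`, `csf`.
#' @export
default_tissue_values <- function() {
  data.frame(
    gm  = c(r1 = 0.77, r2s = 18, mtsat = 2.0, amp = 800),
    wm  = c(r1 = 1.10, r2s = 21, mtsat = 4.0, amp = 720),
    csf = c(r1 = 0.25, r2s = 1.5, mtsat = 0.0, amp = 950)
  )
}

## low-order smooth random field: random quadratic polynomial in normalised
## coordinates, affinely rescaled into `range`
smooth_field <- function(shape, range) {
  if (range[1] == range[2]) return(array(range[1], shape))
  g <- lapply(1:3, function(i) seq(-1, 1, length.out = shape[i]))
  cf <- rnorm(10)
  x <- array(rep(g[[1]], times = shape[2] * shape[3]), shape)
  y <- array(rep(rep(g[[2]], each = shape[1]), times = shape[3]), shape)
  z <- array(rep(g[[3]], each = shape[1] * shape[2]), shape)
  f <- cf[1] + cf[2] * x + cf[3] * y + cf[4] * z +
    cf[5] * x * y + cf[6] * x * z + cf[7] * y * z +
    cf[8] * x^2 + cf[9] * y^2 + cf[10] * z^2
  lo <- min(f); hi <- max(f)
  if (hi - lo < .Machine$double.eps) return(array(mean(range), shape))
  range[1] + (f - lo) / (hi - lo) * (range[2] - range[1])
}

#' Ground-truth parameter maps from tissue probabilities
#'
#' Each true map is the probability-weighted mixture of per-tissue means,
#' optionally modulated by a smooth spatial variation field. The transmit
#' (B1) bias field is generated as a low-order smooth field within
#' `b1_range`; a degenerate range such as `c(1, 1)` gives a perfectly
#' homogeneous transmit field.
#'
#' @param tissues A `tissue_probs` object.
#' @param tissue_values Data frame as [default_tissue_values()]; all values
#'   must be nonnegative.
#' @param b1_range Length-2 range of the multiplicative flip-angle bias.
#' @param spatial_cv Coefficient of a smooth multiplicative within-tissue
#'   variation (0 disables it, keeping maps exact mixtures).
#' @param seed Integer seed.
#' @return An object of class `ground_truth` with arrays `r1`, `r2s`,
#'   `mtsat`, `amp`, `b1`.
#' @export
make_true_maps <- function(tissues, tissue_values = default_tissue_values(),
                           b1_range = c(0.8, 1.2), spatial_cv = 0,
                           seed = 1L) {
  if (!inherits(tissues, "tissue_probs")) vbq_stop("'tissues' must be tissue_probs")
  need <- c("r1", "r2s", "mtsat", "amp")
  if (!all(need %in% rownames(tissue_values)) ||
      !all(c("gm", "wm", "csf") %in% colnames(tissue_values)))
    vbq_stop("'tissue_values' must cover rows r1/r2s/mtsat/amp and columns gm/wm/csf")
  if (any(tissue_values < 0)) vbq_stop("tissue parameter means must be nonnegative")
  shape <- tissues$shape
  mix <- function(p) tissues$gm * tissue_values[p, "gm"] +
    tissues$wm * tissue_values[p, "wm"] + tissues$csf * tissue_values[p, "csf"]
  withr::with_seed(seed, {
    mod <- if (spatial_cv > 0)
      smooth_field(shape, c(1 - spatial_cv, 1 + spatial_cv)) else 1
    maps <- lapply(need, function(p) pmax(mix(p) * mod, 0))
    b1 <- smooth_field(shape, sort(b1_range))
  })
  names(maps) <- need
  for (m in need) dim(maps[[m]]) <- shape
  if (any(b1 <= 0)) vbq_stop("'b1_range' must be strictly positive")
  structure(c(maps, list(b1 = b1, voxel_size_mm = tissues$voxel_size_mm)),
            class = "ground_truth")
}

## ---- FLASH signal simulation -----------------------------------------------

## steady-state amplitude at TE = 0; `a` is the achieved flip angle in rad
flash_s0 <- function(amp, a, r1, tr_s, delta_frac, model) {
  if (model == "rational") {
    amp * a * (r1 * tr_s) / (a^2 / 2 + r1 * tr_s + delta_frac)
  } else {
    e1 <- exp(-tr_s * r1)
    amp * sin(a) * (1 - e1) / (1 - cos(a) * e1)
  }
}

#' Simulate a multi-echo FLASH acquisition from ground truth
#'
#' Per voxel the echo signal is `S(TE) = S0 * exp(-TE * R2*)` (TE in
#' seconds). Under `model = "rational"` the steady-state amplitude is the
#' small-angle rational approximation
#' `S0 = A * a * R1 * TR / (a^2/2 + R1 * TR + delta)` with `a = b1 * alpha`
#' in radians and, for MT-weighted acquisitions only,
#' `delta = (MTsat/100) * b1^2`: the off-resonance saturation pulse is played
#' out by the same transmit coil, so the achieved saturation scales with the
#' square of the local transmit factor. This is what makes the estimated MT
#' saturation insensitive to transmit bias (readout and saturation bias
#' cancel). Under `model = "ernst"` the full Ernst steady state is used;
#' the MT-weighted scan retains the rational saturation form (the package's
#' documented approximation, since a closed-form Ernst steady state with a
#' per-TR saturation pulse requires a two-pool model). Gaussian noise of
#' standard deviation `noise_sd` is added to every echo.
#'
#' @param gt A `ground_truth` object.
#' @param seq A [seq_params()] object.
#' @param model `"rational"` or `"ernst"`.
#' @param noise_sd Additive Gaussian noise SD (>= 0) in signal units.
#' @param seed Integer seed for the noise.
#' @return A [multiecho_series()].
#' @export
simulate_multiecho_flash <- function(gt, seq, model = c("rational", "ernst"),
                                     noise_sd = 0, seed = 1L) {
  if (!inherits(gt, "ground_truth")) vbq_stop("'gt' must be a ground_truth")
  if (!inherits(seq, "seq_params")) vbq_stop("'seq' must be a seq_params")
  model <- match.arg(model)
  if (noise_sd < 0) vbq_stop("'noise_sd' must be >= 0")
  a <- gt$b1 * seq$flip_deg * pi / 180
  tr_s <- seq$tr_ms / 1000
  delta <- if (seq$weighting == "MTw") gt$mtsat / 100 * gt$b1^2 else 0
  mdl <- if (seq$weighting == "MTw") "rational" else model
  s0 <- flash_s0(gt$amp, a, gt$r1, tr_s, delta, mdl)
  te_s <- seq$te_ms / 1000
  shape <- dim(gt$r1)
  echoes <- withr::with_seed(seed, {
    lapply(te_s, function(te) {
      s <- s0 * exp(-te * gt$r2s)
      if (noise_sd > 0) s <- s + array(rnorm(length(s), 0, noise_sd), shape)
      s
    })
  })
  multiecho_series(echoes, seq, gt$voxel_size_mm)
}

## ---- deformations ----------------------------------------------------------

#' Generate a smooth random deformation field
#'
#' A low-frequency random displacement (white noise smoothed with a kernel a
#' quarter of the field of view wide, rescaled to a maximum displacement of
#' `amplitude_mm`) is added to the identity map. If the Jacobian determinant
#' is not positive everywhere the displacement is attenuated (up to 20
#' times); an error is raised if positivity cannot be achieved.
#' `amplitude_mm = 0` returns the exact identity.
#'
#' @param shape Integer triple.
#' @param voxel_size_mm Voxel size triple in mm.
#' @param amplitude_mm Maximum displacement magnitude in mm (>= 0).
#' @param seed Integer seed.
#' @return An object of class `deformation_field` with a `shape x 3`
#'   displacement array in mm defined on the standard-space grid.
#' @export
make_deformation <- function(shape, voxel_size_mm = c(1, 1, 1),
                             amplitude_mm = 2, seed = 1L) {
  shape <- as.integer(shape)
  check_triple(shape, "shape")
  check_triple(voxel_size_mm, "voxel_size_mm")
  if (amplitude_mm < 0) vbq_stop("'amplitude_mm' must be >= 0")
  disp <- array(0, c(shape, 3L))
  if (amplitude_mm > 0) {
    fwhm <- 0.25 * min(shape * voxel_size_mm)
    disp <- withr::with_seed(seed, {
      d <- array(rnorm(prod(shape) * 3), c(shape, 3L))
      for (c_ in 1:3)
        d[, , , c_] <- gaussian_smooth(d[, , , c_], fwhm, voxel_size_mm)
      d
    })
    disp <- disp / max(abs(disp)) * amplitude_mm
    def <- structure(list(displacement = disp,
                          voxel_size_mm = as.numeric(voxel_size_mm)),
                     class = "deformation_field")
    for (try in seq_len(20L)) {
      if (min(jacobian_determinant(def)) > 0) return(def)
      def$displacement <- def$displacement * 0.7
    }
    vbq_stop("could not achieve a positive Jacobian determinant within 20 attenuation steps (amplitude %.3g mm)",
             amplitude_mm)
  }
  structure(list(displacement = disp,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  dm <- dim(x$displacement)
  cat(sprintf("<deformation_field> %dx%dx%d, max |u| %.3g mm\n",
              dm[1], dm[2], dm[3], max(abs(x$displacement))))
  invisible(x)
}

## ---- cohorts ---------------------------------------------------------------

#' Specification of a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param age_range_years Length-2 range from which ages are drawn uniformly.
#' @param gender_balance Fraction of male subjects.
#' @param effect_table Data frame with columns `parameter` (`r1`, `r2s`,
#'   `mtsat` or `amp`), `tissue` (`gm`/`wm`), `region` (`"all"` for the whole
#'   tissue class, or `"sphere:cx,cy,cz,r"` with centre fractions and radius
#'   fraction of the grid), `slope_per_year` and `units`. Age effects are
#'   applied as `(age - mean(age)) * slope` scaled by the local tissue
#'   probability inside the region.
#' @param noise_sd Named numeric vector of voxelwise truth-level noise SDs
#'   per parameter (in the parameter's units).
#' @param seed Integer seed; cohorts are bit-reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 26L,
                        age_range_years = c(18, 85),
                        gender_balance = 19 / 26,
                        effect_table = default_effect_table(),
                        noise_sd = c(r1 = 0.01, r2s = 0.3,
                                     mtsat = 0.05, amp = 4),
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 4L) vbq_stop("'n_subjects' must be >= 4")
  if (length(age_range_years) != 2L || diff(age_range_years) < 0)
    vbq_stop("'age_range_years' must be an increasing length-2 range")
  if (!is.null(effect_table) && nrow(effect_table) > 0) {
    need <- c("parameter", "tissue", "region", "slope_per_year")
    if (!all(need %in% names(effect_table)))
      vbq_stop("'effect_table' must have columns %s", paste(need, collapse = ", "))
    if (any(!is.finite(effect_table$slope_per_year)))
      vbq_stop("effect slopes must be finite")
  }
  structure(list(n_subjects = n_subjects,
                 age_range_years = as.numeric(age_range_years),
                 gender_balance = gender_balance,
                 effect_table = effect_table,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default age-effect table: MT saturation declining across white matter
#'
#' One effect: MT saturation loses 0.05 p.u. per year of age throughout the
#' white-matter class, emulating diffuse age-related myelin decline. The
#' other parameters carry no age effect (null parameters).
#'
#' @return A data frame usable as `effect_table` in [cohort_spec()].
#' @export
default_effect_table <- function() {
  data.frame(parameter = "mtsat", tissue = "wm", region = "all",
             slope_per_year = -0.05, units = "p.u./year",
             stringsAsFactors = FALSE)
}

## resolve a region spec to a binary indicator on the native grid: voxels
## where the tissue probability is >= 0.5, intersected with the geometric
## region; effects are injected uniformly inside the indicator
region_weight <- function(region, tissue, tissues) {
  ind <- (tissues[[tissue]] >= 0.5) * 1
  if (identical(region, "all")) {
    dim(ind) <- tissues$shape
    return(ind)
  }
  if (startsWith(region, "sphere:")) {
    p <- as.numeric(strsplit(sub("sphere:", "", region), ",")[[1]])
    if (length(p) != 4L || anyNA(p)) vbq_stop("bad sphere region spec: %s", region)
    shape <- tissues$shape
    ctr <- p[1:3] * shape
    rad <- p[4] * min(shape)
    g <- lapply(1:3, function(i) seq_len(shape[i]) - ctr[i])
    r2 <- outer(outer(g[[1]]^2, g[[2]]^2, `+`), g[[3]]^2, `+`)
    w <- ind * (r2 <= rad^2)
    dim(w) <- shape
    return(w)
  }
  vbq_stop("unknown region spec: %s", region)
}

#' Generate a synthetic ageing cohort
#'
#' Draws ages uniformly over the configured range, assigns genders, and
#' builds per-subject native data: a jittered tissue phantom, ground-truth
#' maps perturbed by the configured age effects (scaled by local tissue
#' probability inside each effect region) plus truth-level parameter noise,
#' a subject-specific transmit bias field and deformation, and simulated
#' multi-echo FLASH signals for the three weightings. Total intracranial
#' volume is the subject's summed tissue probability times the voxel volume
#' (in ml).
#'
#' @param spec A [cohort_spec()].
#' @param template A `tissue_probs` object defining grid and mean anatomy;
#'   per-subject anatomies are re-generated at the same shape with small
#'   jitter (set `vary_geometry = FALSE` for identical anatomy).
#' @param seqs Sequence set as [flash_sequences()].
#' @param deformation_amplitude_mm Maximum per-subject displacement.
#' @param b1_range Range of the per-subject transmit bias field.
#' @param echo_noise_sd Additive Gaussian noise SD on each echo volume.
#' @param model Signal model passed to [simulate_multiecho_flash()].
#' @param vary_geometry Logical; jitter per-subject anatomy.
#' @return An object of class `vbq_cohort`: list with `subjects` (each
#'   holding `tissues`, `truth`, `deformation`, `series` per weighting),
#'   `covariates` (tibble: subject_id, age, gender, tiv), `effects`
#'   (standard-grid effect-region weights per effect row) and `spec`.
#' @export
make_cohort <- function(spec, template, seqs = flash_sequences(),
                        deformation_amplitude_mm = 1,
                        b1_range = c(0.95, 1.05),
                        echo_noise_sd = 0.5,
                        model = "rational",
                        vary_geometry = TRUE) {
  if (!inherits(spec, "cohort_spec")) vbq_stop("'spec' must be a cohort_spec")
  if (!inherits(template, "tissue_probs")) vbq_stop("'template' must be tissue_probs")
  n <- spec$n_subjects
  eff <- spec$effect_table
  if (!is.null(eff) && nrow(eff) > 0) {
    for (i in seq_len(nrow(eff))) {
      w <- region_weight(eff$region[i], eff$tissue[i], template)
      if (!any(w > 0)) vbq_stop("effect region %d ('%s') is empty", i, eff$region[i])
    }
  }
  base_seed <- spec$seed
  demo <- withr::with_seed(base_seed, {
    ages <- runif(n, spec$age_range_years[1], spec$age_range_years[2])
    n_male <- round(n * spec$gender_balance)
    gender <- sample(c(rep("M", n_male), rep("F", n - n_male)))
    list(ages = ages, gender = gender)
  })
  ages <- demo$ages
  age_c <- ages - mean(ages)
  vox_ml <- prod(template$voxel_size_mm) / 1000
  effects_std <- NULL
  if (!is.null(eff) && nrow(eff) > 0) {
    effects_std <- lapply(seq_len(nrow(eff)), function(i)
      region_weight(eff$region[i], eff$tissue[i], template))
  }
  subjects <- vector("list", n)
  tiv <- numeric(n)
  for (s in seq_len(n)) {
    sseed <- base_seed + 1000L * s
    bw <- if (is.null(template$boundary_width_vox)) 0.4 else template$boundary_width_vox
    jt <- if (is.null(template$jitter)) 0.02 else template$jitter
    tis <- if (vary_geometry)
      make_tissue_phantom(template$shape, template$voxel_size_mm,
                          seed = sseed, boundary_width_vox = bw,
                          jitter = max(jt, 0.02)) else template
    gt <- make_true_maps(tis, b1_range = b1_range, seed = sseed + 1L)
    if (!is.null(eff) && nrow(eff) > 0) {
      for (i in seq_len(nrow(eff))) {
        w <- region_weight(eff$region[i], eff$tissue[i], tis)
        p <- eff$parameter[i]
        gt[[p]] <- pmax(gt[[p]] + age_c[s] * eff$slope_per_year[i] * w, 0)
        dim(gt[[p]]) <- tis$shape
      }
    }
    withr::with_seed(sseed + 2L, {
      for (p in names(spec$noise_sd)) {
        sdp <- spec$noise_sd[[p]]
        if (sdp > 0) {
          gt[[p]] <- pmax(gt[[p]] +
            array(rnorm(prod(tis$shape), 0, sdp), tis$shape), 0)
          dim(gt[[p]]) <- tis$shape
        }
      }
    })
    series <- list(
      t1w = simulate_multiecho_flash(gt, seqs$t1w, model, echo_noise_sd,
                                     seed = sseed + 3L),
      pdw = simulate_multiecho_flash(gt, seqs$pdw, model, echo_noise_sd,
                                     seed = sseed + 4L),
      mtw = simulate_multiecho_flash(gt, seqs$mtw, model, echo_noise_sd,
                                     seed = sseed + 5L)
    )
    def <- make_deformation(tis$shape, tis$voxel_size_mm,
                            deformation_amplitude_mm, seed = sseed + 6L)
    tiv[s] <- sum(tis$gm + tis$wm + tis$csf) * vox_ml
    subjects[[s]] <- list(id = sprintf("sub-%02d", s), tissues = tis,
                          truth = gt, deformation = def, series = series)
  }
  cov <- tibble::tibble(subject_id = vapply(subjects, `[[`, "", "id"),
                        age = ages, gender = demo$gender, tiv = tiv)
  structure(list(subjects = subjects, covariates = cov,
                 effects = effects_std, spec = spec,
                 seqs = seqs, template = template, model = model),
            class = "vbq_cohort")
}

#' @export
print.vbq_cohort <- function(x, ...) {
  cat(sprintf("<vbq_cohort> %d subjects, ages %.1f..%.1f, grid %s\n",
              nrow(x$covariates), min(x$covariates$age), max(x$covariates$age),
              paste(x$template$shape, collapse = "x")))
  invisible(x)
}

#' Write a cohort to disk as NIfTI volumes plus covariates and manifest
#'
#' Per subject: one file per echo per weighting, tissue probability maps, the
#' deformation as a 4-D displacement field in mm, and the B1 map. At the top
#' level: `covariates.tsv` (subject_id, age, gender, tiv) and
#' `manifest.json` recording ground-truth effect slopes and file layout;
#' effect-region weights are written as NIfTI.
#'
#' @param cohort A `vbq_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- cohort$template$voxel_size_mm
  manifest <- list(subjects = list(), seed = cohort$spec$seed,
                   effect_table = cohort$spec$effect_table,
                   sequences = lapply(cohort$seqs, unclass))
  for (sub in cohort$subjects) {
    sd_ <- file.path(dir, sub$id)
    files <- list()
    for (w in names(sub$series)) {
      ser <- sub$series[[w]]
      files[[w]] <- vapply(seq_along(ser$echoes), function(e) {
        p <- file.path(sd_, sprintf("%s_%s_echo-%d.nii.gz", sub$id, w, e))
        write_volume(ser$echoes[[e]], p, vox)
        basename(p)
      }, "")
    }
    for (t in c("gm", "wm", "csf"))
      write_volume(sub$tissues[[t]],
                   file.path(sd_, sprintf("%s_prob-%s.nii.gz", sub$id, t)), vox)
    write_volume(sub$truth$b1,
                 file.path(sd_, sprintf("%s_b1.nii.gz", sub$id)), vox)
    write_volume(sub$deformation$displacement,
                 file.path(sd_, sprintf("%s_deformation.nii.gz", sub$id)), vox)
    manifest$subjects[[sub$id]] <- files
  }
  if (!is.null(cohort$effects)) {
    for (i in seq_along(cohort$effects))
      write_volume(cohort$effects[[i]],
                   file.path(dir, sprintf("effect-region-%d.nii.gz", i)), vox)
  }
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
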