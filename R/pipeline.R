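## End-to-end pipeline: map fitting -> warping/weights -> tissue-weighted
## smoothing (+ VBM prep) -> block-diagonal GLM (+ MLM), in memory
## (analyze_cohort) and from/to disk with logging (run_pipeline).

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[vbq] ", fmt), ...))
}

#' Run the full voxel-based quantification analysis on a cohort in memory
#'
#' For every subject: fit the quantitative maps from the simulated FLASH
#' series (with analytic transmit-bias correction of R1 when `use_b1`),
#' compute the Jacobian determinant of the subject's deformation, warp
#' parameter and tissue maps to the standard grid, build tissue weights
#' `w = |Dphi| t(phi)`, apply tissue-weighted smoothing to each parameter
#' map and Jacobian modulation plus smoothing to the tissue map. Then build
#' the exclusive GM/WM masks, the block-diagonal design (age, gender, TIV),
#' fit the GLM, compute age T maps, apply FWE control, build the overlap
#' label map and (optionally) the multivariate eigenvariate analysis.
#'
#' @param cohort A [make_cohort()] bundle (or the equivalent structure read
#'   back by [read_cohort()]).
#' @param config A [run_config()]; `input_dir`/`output_dir` are ignored
#'   here.
#' @param verbose Log stage progress to stderr.
#' @return A list: `fit` (`vbq_glm`), `tmaps`, `fwe`, `labels`, `mlm`
#'   (or `NULL`), `masks`, `mask` (analysis mask actually used), `smoothed`
#'   (per parameter, n x V matrices), `vbm` (subject-level modulated maps),
#'   `qc`, `config`.
#' @export
analyze_cohort <- function(cohort, config = run_config(), verbose = FALSE) {
  pars <- config$parameters
  vox <- cohort$template$voxel_size_mm
  shape <- cohort$template$shape
  n <- length(cohort$subjects)
  tissue <- config$tissue
  qc <- list(min_jacobian = Inf, frac_negative_mtsat = 0, frac_masked = 0)

  warped <- list()   # per parameter: list of standard-space smoothed param_maps
  for (p in pars) warped[[p]] <- vector("list", n)
  gm_w <- wm_w <- vector("list", n)
  vbm <- vector("list", n)
  for (s in seq_len(n)) {
    sub <- cohort$subjects[[s]]
    maps <- fit_parameter_maps(sub$series$t1w, sub$series$pdw, sub$series$mtw,
                               b1 = if (config$use_b1) sub$truth$b1 else NULL,
                               tissues = if (config$use_b1) NULL else sub$tissues)
    qc$frac_negative_mtsat <- qc$frac_negative_mtsat + maps$qc$frac_negative_mtsat / n
    qc$frac_masked <- qc$frac_masked + maps$qc$frac_masked / n
    def <- sub$deformation
    jac <- jacobian_determinant(def)
    qc$min_jacobian <- min(qc$min_jacobian, min(jac))
    gm_w[[s]] <- warp_volume(sub$tissues$gm, def, config$warp_order)
    wm_w[[s]] <- warp_volume(sub$tissues$wm, def, config$warp_order)
    tw <- if (tissue == "wm") wm_w[[s]] else gm_w[[s]]
    wts <- compute_weights(jac, tw, toupper(tissue))
    for (p in pars) {
      pm <- maps[[p]]
      dat <- pm$data
      if (!is.null(pm$mask)) dat[!pm$mask] <- NA
      std <- warp_volume(dat, def, config$warp_order)
      warped[[p]][[s]] <- tissue_weighted_smooth(
        param_map(std, pm$kind, pm$units, vox, "standard"),
        wts, config$fwhm_mm)
    }
    vbm[[s]] <- modulate_and_smooth(gm_w[[s]], jac, config$fwhm_mm, vox, "GM")
    stage_log(verbose, "subject %s: maps + warp + smooth done", sub$id)
  }

  masks <- build_tissue_masks(gm_w, wm_w, config$mask_threshold)
  mask <- if (tissue == "wm") masks$wm_mask else masks$gm_mask
  ## restrict to voxels valid (weight support) in every subject
  for (p in pars) for (s in seq_len(n)) mask <- mask & warped[[p]][[s]]$mask
  stage_log(verbose, "analysis mask: %d voxels", sum(mask))

  data <- lapply(pars, function(p) {
    do.call(rbind, lapply(warped[[p]], function(m) m$data[mask]))
  })
  names(data) <- pars

  design <- build_design(cohort$covariates, pars)
  fit <- fit_glm(data, design, mask = mask, voxel_size_mm = vox)
  tmaps <- lapply(pars, function(p) t_map(fit, "age", p))
  names(tmaps) <- pars
  fwe <- lapply(pars, function(p)
    fwe_threshold(fit, tmaps[[p]], alpha = config$alpha,
                  method = config$fwe_method, n_perm = config$n_perm,
                  aux_unc = config$aux_unc, seed = config$seed))
  names(fwe) <- pars
  labels <- overlap_labels(tmaps, config$aux_unc)
  mlm <- NULL
  if (isTRUE(config$run_mlm) && length(pars) >= 2L)
    mlm <- mlm_age_eigen(data, design, seed = config$seed)
  stage_log(verbose, "statistics done (%s FWE at alpha=%.3g)",
            config$fwe_method, config$alpha)
  list(fit = fit, tmaps = tmaps, fwe = fwe, labels = labels, mlm = mlm,
       masks = masks, mask = mask, smoothed = data, warped = warped,
       vbm = vbm, qc = qc, config = config)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory containing `manifest.json`,
#'   `covariates.tsv` and per-subject NIfTI volumes.
#' @return A cohort bundle usable with [analyze_cohort()].
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) vbq_stop("manifest not found: %s", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  ids <- names(manifest$subjects)
  cov <- read_covariates(file.path(dir, "covariates.tsv"), subject_order = ids)
  seqs <- lapply(manifest$sequences, function(s)
    seq_params(s$tr_ms, s$flip_deg, s$te_ms, s$weighting, s$mt_pulse))
  subjects <- lapply(ids, function(id) {
    sd_ <- file.path(dir, id)
    rd <- function(f) {
      p <- file.path(sd_, f)
      if (!file.exists(p)) vbq_stop("missing volume for subject %s: %s", id, f)
      read_volume(p)
    }
    vox <- NULL
    series <- lapply(names(seqs), function(w) {
      files <- manifest$subjects[[id]][[w]]
      vols <- lapply(files, rd)
      vox <<- vols[[1]]$voxel_size_mm
      multiecho_series(lapply(vols, `[[`, "data"), seqs[[w]], vox)
    })
    names(series) <- names(seqs)
    tis <- list(gm = rd(sprintf("%s_prob-gm.nii.gz", id))$data,
                wm = rd(sprintf("%s_prob-wm.nii.gz", id))$data,
                csf = rd(sprintf("%s_prob-csf.nii.gz", id))$data,
                voxel_size_mm = vox)
    tis$shape <- dim(tis$gm)
    class(tis) <- "tissue_probs"
    disp <- rd(sprintf("%s_deformation.nii.gz", id))$data
    def <- structure(list(displacement = disp, voxel_size_mm = vox),
                     class = "deformation_field")
    b1 <- rd(sprintf("%s_b1.nii.gz", id))$data
    list(id = id, tissues = tis, truth = list(b1 = b1),
         deformation = def, series = series)
  })
  template <- subjects[[1]]$tissues
  structure(list(subjects = subjects, covariates = cov, effects = NULL,
                 spec = NULL, seqs = seqs, template = template),
            class = "vbq_cohort")
}

#' Run the pipeline from a configuration (disk to disk)
#'
#' Reads the cohort named by `config$input_dir`, runs [analyze_cohort()],
#' and writes: T/p/label volumes as NIfTI, peak tables as TSV, MLM loadings
#' and variance fractions as JSON, and a JSON run report (package version,
#' seed, per-stage QC: masked-voxel fraction, negative-MTsat fraction,
#' minimum Jacobian determinant, mask sizes). Any stage failure aborts with
#' the stage name (and subject, where applicable). Deterministic given the
#' config seed.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @param verbose Log progress to stderr.
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- "read-cohort"
  report <- list(package_version = as.character(utils::packageVersion("vbq")),
                 seed = config$seed, stages = list())
  res <- tryCatch({
    cohort <- read_cohort(config$input_dir)
    report$stages[["read-cohort"]] <- list(n_subjects = length(cohort$subjects))
    stage <- "analysis"
    res <- analyze_cohort(cohort, config, verbose = verbose)
    stage <- "write-outputs"
    vox <- cohort$template$voxel_size_mm
    msk <- res$mask
    unvec <- function(v) { a <- array(NA_real_, dim(msk)); a[msk] <- v; a }
    for (p in names(res$tmaps)) {
      write_volume(unvec(res$tmaps[[p]]$t),
                   file.path(out, sprintf("tmap_%s.nii.gz", p)), vox)
      write_volume(unvec(res$tmaps[[p]]$p),
                   file.path(out, sprintf("pmap_%s.nii.gz", p)), vox)
      write_volume(unvec(as.numeric(res$fwe[[p]]$fwe)),
                   file.path(out, sprintf("fwe_%s.nii.gz", p)), vox)
      utils::write.table(res$fwe[[p]]$peaks,
                         file.path(out, sprintf("peaks_%s.tsv", p)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_volume(unvec(res$labels$labels),
                 file.path(out, "overlap_labels.nii.gz"), vox)
    write_volume(array(as.numeric(msk), dim(msk)),
                 file.path(out, "analysis_mask.nii.gz"), vox)
    if (!is.null(res$mlm))
      jsonlite::write_json(
        list(parameters = res$mlm$parameters,
             loadings = res$mlm$loadings, var_frac = res$mlm$var_frac,
             p = res$mlm$p),
        file.path(out, "mlm.json"), auto_unbox = TRUE, digits = NA)
    res
  }, error = function(e) {
    vbq_stop("pipeline aborted at stage '%s': %s", stage, conditionMessage(e))
  })
  report$stages[["analysis"]] <- c(res$qc,
    list(mask_voxels = sum(res$mask),
         gm_mask_voxels = sum(res$masks$gm_mask),
         wm_mask_voxels = sum(res$masks$wm_mask)))
  report$completed <- TRUE
  jsonlite::write_json(report, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log(verbose, "run complete: %s", out)
  invisible(report)
}
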