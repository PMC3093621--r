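## Run configuration and covariate I/O.

#' Pipeline run configuration
#'
#' Collects all tunable parameters of the analysis pipeline with their
#' defaults: smoothing FWHM 6 mm, mask threshold 0.2, FWE level 0.05,
#' auxiliary uncorrected threshold 0.001. Configurations serialise to YAML
#' losslessly via [read_run_config()]/[write_run_config()].
#'
#' @param input_dir,output_dir Paths to a cohort directory (as written by
#'   [write_cohort()]) and the output directory.
#' @param fwhm_mm Gaussian smoothing FWHM in mm (>= 0).
#' @param mask_threshold Tissue probability threshold in (0, 1).
#' @param alpha FWE level in (0, 1).
#' @param aux_unc Auxiliary uncorrected threshold in (0, 1).
#' @param fwe_method `"bonferroni"` or `"permutation"`.
#' @param n_perm Permutations for `fwe_method = "permutation"`.
#' @param parameters Parameter maps to analyse.
#' @param tissue Tissue class for the statistics (`"wm"` or `"gm"`).
#' @param warp_order Interpolation order for warping (0, 1 or 3).
#' @param use_b1 Use the B1 map for analytic transmit-bias correction.
#' @param run_mlm Also run the multivariate eigenvariate analysis.
#' @param seed Integer seed controlling all randomness of the run.
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(input_dir = ".", output_dir = "vbq-out",
                       fwhm_mm = 6, mask_threshold = 0.2, alpha = 0.05,
                       aux_unc = 0.001, fwe_method = "bonferroni",
                       n_perm = 1000L, parameters = c("mtsat", "r1", "r2s"),
                       tissue = "wm", warp_order = 1L, use_b1 = TRUE,
                       run_mlm = TRUE, seed = 1L) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              fwhm_mm = fwhm_mm, mask_threshold = mask_threshold,
              alpha = alpha, aux_unc = aux_unc, fwe_method = fwe_method,
              n_perm = as.integer(n_perm), parameters = parameters,
              tissue = tissue, warp_order = as.integer(warp_order),
              use_b1 = isTRUE(use_b1), run_mlm = isTRUE(run_mlm),
              seed = as.integer(seed))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  with(cfg, {
    if (fwhm_mm < 0) vbq_stop("'fwhm_mm' must be >= 0")
    if (!(mask_threshold > 0 && mask_threshold < 1))
      vbq_stop("'mask_threshold' must be in (0,1)")
    for (nm in c("alpha", "aux_unc"))
      if (!(cfg[[nm]] > 0 && cfg[[nm]] < 1)) vbq_stop("'%s' must be in (0,1)", nm)
    if (!fwe_method %in% c("bonferroni", "permutation"))
      vbq_stop("unknown fwe_method '%s'", fwe_method)
    if (!tissue %in% c("gm", "wm")) vbq_stop("'tissue' must be gm or wm")
    if (!warp_order %in% c(0L, 1L, 3L)) vbq_stop("'warp_order' must be 0, 1 or 3")
  })
  structure(cfg, class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a validated `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) vbq_stop("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  base <- unclass(run_config())
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown)) vbq_stop("unknown config field(s): %s",
                                paste(unknown, collapse = ", "))
  base[names(raw)] <- raw
  base$n_perm <- as.integer(base$n_perm)
  base$warp_order <- as.integer(base$warp_order)
  base$seed <- as.integer(base$seed)
  validate_run_config(base)
}

#' @rdname read_run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a subject covariate table
#'
#' Reads a TSV/CSV with header `subject_id`, `age`, `gender`, `tiv`,
#' validates types and the gender coding (`M`/`F`), and (when a subject
#' order is supplied, e.g. from a manifest) reorders rows to it.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @param subject_order Optional character vector fixing the row order.
#' @return A tibble with typed columns.
#' @export
read_covariates <- function(path, subject_order = NULL) {
  if (!file.exists(path)) vbq_stop("covariate file not found: %s", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "gender", "tiv")
  miss <- setdiff(need, names(df))
  if (length(miss)) vbq_stop("covariate file lacks column(s): %s",
                             paste(miss, collapse = ", "))
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup)) vbq_stop("duplicated subject_id: %s",
                            paste(unique(dup), collapse = ", "))
  for (nm in c("age", "tiv")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v)) vbq_stop("non-numeric %s for subject(s): %s", nm,
                           paste(df$subject_id[is.na(v)], collapse = ", "))
    df[[nm]] <- v
  }
  bad <- !df$gender %in% c("M", "F")
  if (any(bad)) vbq_stop("gender must be coded M/F; offending subject(s): %s",
                         paste(df$subject_id[bad], collapse = ", "))
  if (!is.null(subject_order)) {
    miss <- setdiff(subject_order, df$subject_id)
    if (length(miss)) vbq_stop("covariates missing subject(s): %s",
                               paste(miss, collapse = ", "))
    df <- df[match(subject_order, df$subject_id), ]
  }
  tibble::as_tibble(df)
}
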