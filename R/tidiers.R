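## broom-style tidiers for fitted objects.

#' Tidy a voxelwise GLM fit
#'
#' One row per parameter block and regressor, summarising the voxelwise
#' beta estimates across the analysis mask.
#'
#' @param x A `vbq_glm`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `term`, `estimate` (mean
#'   voxelwise beta), `sd`, `min`, `max`.
#' @exportS3Method generics::tidy
tidy.vbq_glm <- function(x, ...) {
  rows <- lapply(names(x$blocks), function(p) {
    b <- x$blocks[[p]]$beta
    tibble::tibble(parameter = p, term = rownames(b),
                   estimate = rowMeans(b), sd = apply(b, 1, sd),
                   min = apply(b, 1, min), max = apply(b, 1, max))
  })
  do.call(rbind, rows)
}

#' @rdname tidy.vbq_glm
#' @exportS3Method generics::glance
glance.vbq_glm <- function(x, ...) {
  tibble::tibble(n_subjects = x$design$n, n_parameters = length(x$blocks),
                 n_voxels = x$n_voxels, dof = x$dof)
}

#' Tidy a multivariate eigenvariate result
#'
#' One row per component and parameter with the loading, the component's
#' variance-explained fraction and split-sample trace-test p-value.
#'
#' @param x A `vbq_mlm`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `parameter`, `loading`,
#'   `var_frac`, `p.value`.
#' @exportS3Method generics::tidy
tidy.vbq_mlm <- function(x, ...) {
  K <- length(x$d)
  tibble::tibble(
    component = rep(seq_len(K), each = length(x$parameters)),
    parameter = rep(x$parameters, K),
    loading = as.vector(x$loadings),
    var_frac = rep(x$var_frac, each = length(x$parameters)),
    p.value = rep(x$p, each = length(x$parameters)))
}

#' @rdname tidy.vbq_mlm
#' @exportS3Method generics::glance
glance.vbq_mlm <- function(x, ...) {
  tibble::tibble(n_subjects = x$n, n_parameters = length(x$parameters),
                 n_components = length(x$d),
                 var_frac_1 = x$var_frac[1], p_1 = x$p[1])
}
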