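# tidy() / glance() methods for the package's result objects.

#' @method tidy effect_size_report
#' @export
tidy.effect_size_report <- function(x, ...) {
  dplyr::mutate(x$report, selected = .data$voi == x$selected_reference)
}

#' @method glance effect_size_report
#' @export
glance.effect_size_report <- function(x, ...) {
  sel <- x$report[x$report$voi == x$selected_reference, ]
  tibble::tibble(
    selected_reference = x$selected_reference,
    d = sel$d,
    n_candidates = nrow(x$report),
    pooled_timepoints = is.null(x$timepoint)
  )
}

#' @method tidy connectivity_matrix
#' @export
tidy.connectivity_matrix <- function(x, ...) {
  p <- voi_pairs(x$vois)
  tibble::tibble(
    voi_i = p$voi_i, voi_j = p$voi_j,
    r = x$r[cbind(p$i, p$j)],
    z = x$z[cbind(p$i, p$j)]
  )
}

#' @method glance connectivity_matrix
#' @export
glance.connectivity_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  tibble::tibble(
    n_vois = length(x$vois), n_subjects = x$n_subjects,
    timepoint = x$timepoint, mean_r = mean(off), min_r = min(off),
    max_r = max(off)
  )
}

#' @method tidy pair_fit_ensemble
#' @export
tidy.pair_fit_ensemble <- function(x, ...) {
  x$pairs[c("voi_i", "voi_j", "slope", "intercept")]
}

#' @method glance pair_fit_ensemble
#' @export
glance.pair_fit_ensemble <- function(x, ...) {
  tibble::tibble(
    n_vois = length(x$vois), n_pairs = nrow(x$pairs), B = x$B,
    n_control = x$n_control, seed = x$seed, consensus = x$consensus,
    timepoint = x$timepoint
  )
}

#' @method tidy composite_pc1
#' @export
tidy.composite_pc1 <- function(x, ...) {
  dplyr::mutate(x$scores, composite = x$composite)
}

#' @method glance composite_pc1
#' @export
glance.composite_pc1 <- function(x, ...) {
  tibble::tibble(
    composite = x$composite,
    explained_variance = x$explained_variance,
    n_subjects = x$n_subjects,
    n_constituents = length(x$constituents),
    standardized = x$standardized
  )
}

#' @method tidy regression_result
#' @export
tidy.regression_result <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @method glance regression_result
#' @export
glance.regression_result <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    p_value = x$p_value, n = x$n, n_excluded = x$n_excluded,
    degenerate = x$degenerate,
    note = if (is.null(x$note)) NA_character_ else x$note
  )
}
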