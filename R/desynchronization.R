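# Desynchronization index (DI) / connectivity deviation score (CDS):
# per subject and VOI, the sum of perpendicular distances from the subject's
# pairwise uptake points to the control cohort's line fits, plus PC1
# composites over constituent VOIs.

#' Perpendicular distance from a point to a line
#'
#' Distance from `(x0, y0)` to the line `y = slope * x + intercept`:
#' `|slope * x0 - y0 + intercept| / sqrt(slope^2 + 1)`. Zero iff the point
#' lies on the line. All arguments are vectorized.
#'
#' @param x0,y0 Point coordinates.
#' @param slope,intercept Line coefficients.
#' @return Non-negative distances.
#' @export
perpendicular_distance <- function(x0, y0, slope, intercept) {
  if (any(!is.finite(x0) | !is.finite(y0) |
            !is.finite(slope) | !is.finite(intercept))) {
    abort("perpendicular_distance requires finite inputs")
  }
  abs(slope * x0 - y0 + intercept) / sqrt(slope^2 + 1)
}

#' Per-subject, per-VOI desynchronization index
#'
#' For each subject and each VOI pair `(i, j)` of the fit ensemble, the
#' perpendicular distance from the subject's `(value_i, value_j)` point to
#' the control cohort's line fit is computed; the DI of VOI `i` is the sum of
#' the distances of all pairs that include `i` (so each DI sums `V - 1` pair
#' terms). Distances are measured against the consensus fit by default, or
#' averaged over all `B` replicate fits with `method = "replicate"`.
#' Subjects with a missing VOI value are skipped and reported in the
#' `skipped_subjects` attribute.
#'
#' @param x Regional uptake table (typically unit `SUVR`).
#' @param fits A [bootstrap_pair_fits()] ensemble.
#' @param timepoint Scan age at which DI is computed; defaults to the latest
#'   in the table (the ensemble's timepoint convention).
#' @param method `"consensus"` (default) or `"replicate"`.
#' @return A tibble of class `desync_profile`: `subject_id`, `voi`, `di`
#'   (raw distance sum) and `di_norm` (`di / (V - 1)`, comparable across
#'   atlases).
#' @export
compute_di <- function(x, fits, timepoint = NULL,
                       method = c("consensus", "replicate")) {
  method <- match.arg(method)
  if (!inherits(fits, "pair_fit_ensemble")) {
    abort("`fits` must be a pair_fit_ensemble")
  }
  vois <- fits$vois
  m_all <- uptake_wide(x, tracer = fits$tracer, timepoint = timepoint,
                       vois = vois)
  complete <- complete.cases(m_all)
  skipped <- rownames(m_all)[!complete]
  m <- m_all[complete, , drop = FALSE]
  if (nrow(m) == 0L) abort("no subject has a complete VOI profile")
  pairs <- fits$pairs
  xi <- m[, pairs$i, drop = FALSE]
  xj <- m[, pairs$j, drop = FALSE]
  if (method == "consensus") {
    d <- perpendicular_distance(
      xi, xj,
      matrix(pairs$slope, nrow(m), nrow(pairs), byrow = TRUE),
      matrix(pairs$intercept, nrow(m), nrow(pairs), byrow = TRUE)
    )
  } else {
    d <- matrix(0, nrow(m), nrow(pairs))
    for (b in seq_len(fits$B)) {
      d <- d + perpendicular_distance(
        xi, xj,
        matrix(fits$slope_replicates[b, ], nrow(m), nrow(pairs), byrow = TRUE),
        matrix(fits$intercept_replicates[b, ], nrow(m), nrow(pairs),
               byrow = TRUE)
      )
    }
    d <- d / fits$B
  }
  # incidence: pair p contributes to both of its member VOIs
  inc <- matrix(0, nrow(pairs), length(vois))
  inc[cbind(seq_len(nrow(pairs)), pairs$i)] <- 1
  inc[cbind(seq_len(nrow(pairs)), pairs$j)] <- 1
  di <- d %*% inc
  out <- tibble::tibble(
    subject_id = rep(rownames(m), length(vois)),
    voi = rep(vois, each = nrow(m)),
    di = as.vector(di),
    di_norm = as.vector(di) / (length(vois) - 1L)
  )
  out <- dplyr::arrange(out, .data$subject_id, .data$voi)
  attr(out, "skipped_subjects") <- skipped
  attr(out, "method") <- method
  attr(out, "timepoint") <- attr(m_all, "timepoint")
  class(out) <- c("desync_profile", class(out))
  out
}

#' PC1 composite score over constituent VOIs
#'
#' Aggregates the DIs of a composite region's constituent VOIs into one score
#' per subject: the projection on the first principal component of the
#' subject-by-constituent DI matrix (per-VOI standardized by default). The
#' eigenvector sign is oriented so that the score correlates positively with
#' the mean constituent DI, making reported scores invariant to the
#' arbitrary sign of the raw eigenvector.
#'
#' @param di A `desync_profile` (or any tibble with `subject_id`, `voi`,
#'   `di`).
#' @param constituents VOI names forming the composite.
#' @param name Composite label (e.g. `"cortex"`, `"EHA"`).
#' @param standardize Standardize each constituent to mean 0 / SD 1 before
#'   the decomposition (correlation-matrix PCA); `FALSE` uses raw DIs.
#' @return A `composite_pc1`: per-subject scores plus the explained-variance
#'   fraction of PC1. [tidy()] returns the scores, [glance()] the summary.
#' @export
composite_pc1 <- function(di, constituents, name = "composite",
                          standardize = TRUE) {
  if (length(constituents) < 1L) abort("need at least one constituent VOI")
  absent <- setdiff(constituents, unique(di$voi))
  if (length(absent)) {
    abort(sprintf("constituent VOI absent from DI table: %s",
                  paste(absent, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(
    dplyr::filter(di, .data$voi %in% constituents)[
      c("subject_id", "voi", "di")],
    names_from = "voi", values_from = "di"
  )
  m <- as.matrix(wide[constituents])
  rownames(m) <- wide$subject_id
  if (nrow(m) < 3L) abort("need >= 3 subjects for a PC1 composite")
  v <- apply(m, 2, var)
  if (any(v <= 0)) {
    abort(sprintf("zero-variance constituent: %s",
                  paste(constituents[v <= 0], collapse = ", ")))
  }
  centered <- scale(m, center = TRUE, scale = standardize)
  p <- prcomp(centered, center = FALSE, scale. = FALSE)
  scores <- p$x[, 1L]
  if (cor(scores, rowMeans(m)) < 0) scores <- -scores
  ev <- p$sdev^2
  structure(
    list(
      scores = tibble::tibble(subject_id = rownames(m), score = unname(scores)),
      composite = name,
      constituents = constituents,
      explained_variance = ev[1L] / sum(ev),
      standardized = standardize,
      n_subjects = nrow(m)
    ),
    class = "composite_pc1"
  )
}

#' @export
print.composite_pc1 <- function(x, ...) {
  cat("<composite_pc1>", x$composite, "\n")
  cat(sprintf("  %d subjects, %d constituents, PC1 explains %.1f%% of variance\n",
              x$n_subjects, length(x$constituents),
              100 * x$explained_variance))
  invisible(x)
}
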