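# Interregional (molecular) connectivity: Pearson correlation across a
# cohort for every VOI pair, the Fisher r-to-z twin, and the bootstrap
# line-fit ensemble feeding the desynchronization index.

#' Fisher r-to-z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`. Correlations with
#' `|r| >= 1` are clipped to magnitude `1 - 1e-7` with a warning, so the
#' transform is always finite.
#'
#' @param r Numeric vector of correlation coefficients.
#' @return Transformed values; attribute `clipped` flags clipped inputs when
#'   any occurred.
#' @export
fisher_z <- function(r) {
  if (any(is.na(r))) abort("NaN/NA correlations cannot be transformed")
  clipped <- abs(r) >= 1
  if (any(clipped)) {
    warn("correlations with |r| >= 1 clipped to 1 - 1e-7 in magnitude")
    r[clipped] <- sign(r[clipped]) * (1 - 1e-7)
  }
  out <- atanh(r)
  if (any(clipped)) attr(out, "clipped") <- clipped
  out
}

#' Interregional correlation matrix
#'
#' Pearson correlation of uptake between every VOI pair, computed across the
#' subjects of a cohort at one timepoint. Subjects with any missing VOI value
#' are dropped listwise; at least three complete profiles are required and
#' every VOI must vary across subjects.
#'
#' @param x Regional uptake table (typically unit `SUVR`).
#' @param subjects Optional subject ids restricting the cohort.
#' @param tracer Tracer to correlate.
#' @param timepoint Scan age; defaults to the latest in the table.
#' @param vois Optional VOI order; defaults to the order of appearance.
#' @return A `connectivity_matrix`: VOI names, the symmetric `r` matrix
#'   (unit diagonal), its Fisher-z twin `z` (diagonal `NA`), and the number
#'   of complete subjects. [tidy()] returns the pairs in long form;
#'   [ggplot2::autoplot()] draws a heatmap.
#' @export
compute_icc_matrix <- function(x, subjects = NULL, tracer = "TSPO",
                               timepoint = NULL, vois = NULL) {
  if (!is.null(subjects)) {
    x <- dplyr::filter(x, .data$subject_id %in% subjects)
  }
  m <- uptake_wide(x, tracer = tracer, timepoint = timepoint, vois = vois)
  complete <- complete.cases(m)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 3L) {
    abort(sprintf("need >= 3 subjects with complete VOI profiles, got %d",
                  nrow(m)))
  }
  v <- apply(m, 2, var)
  if (any(v <= 0)) {
    abort(sprintf("zero-variance VOI: %s",
                  paste(colnames(m)[v <= 0], collapse = ", ")))
  }
  r <- cor(m)
  z <- suppressWarnings(fisher_z(pmin(pmax(r, -1), 1)))
  z <- matrix(z, nrow(r), ncol(r), dimnames = dimnames(r))
  diag(z) <- NA_real_
  structure(
    list(vois = colnames(m), r = r, z = z, n_subjects = nrow(m),
         tracer = tracer, timepoint = attr(m, "timepoint")),
    class = "connectivity_matrix"
  )
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat("<connectivity_matrix>\n")
  cat("  VOIs:", length(x$vois), " subjects:", x$n_subjects,
      " timepoint:", x$timepoint, "\n")
  cat(sprintf("  off-diagonal r: median %.3f, range [%.3f, %.3f]\n",
              median(off), min(off), max(off)))
  invisible(x)
}

# internal: unordered pairs in atlas order (lower index is the predictor)
voi_pairs <- function(vois) {
  idx <- utils::combn(length(vois), 2L)
  tibble::tibble(
    i = idx[1L, ], j = idx[2L, ],
    voi_i = vois[idx[1L, ]], voi_j = vois[idx[2L, ]]
  )
}

#' Bootstrap line-fit ensemble for every VOI pair of a control cohort
#'
#' For each of `B` bootstrap replicates, the control subjects are resampled
#' with replacement and an ordinary least-squares line of VOI_j on VOI_i
#' (lower atlas index predicts higher) is fit for every VOI pair. Replicates
#' in which a resample leaves a predictor without variance are redrawn
#' (bounded retries). The consensus fit of a pair is the mean (or median) of
#' its replicate coefficients.
#'
#' @param x Regional uptake table (typically unit `SUVR`).
#' @param control_subjects Subject ids of the control cohort (>= 3 complete
#'   profiles required).
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed making the ensemble reproducible.
#' @param tracer,timepoint,vois See [compute_icc_matrix()].
#' @param consensus `"mean"` (default) or `"median"` of replicate
#'   coefficients.
#' @param max_retries Redraw budget per replicate for degenerate resamples.
#' @return A `pair_fit_ensemble`: pair table with consensus slope/intercept,
#'   the `B x n_pairs` replicate coefficient matrices, and metadata.
#' @export
bootstrap_pair_fits <- function(x, control_subjects, B = 1000L, seed = 0L,
                                tracer = "TSPO", timepoint = NULL,
                                vois = NULL,
                                consensus = c("mean", "median"),
                                max_retries = 100L) {
  consensus <- match.arg(consensus)
  if (B < 1L) abort("B must be >= 1")
  x <- dplyr::filter(x, .data$subject_id %in% control_subjects)
  m <- uptake_wide(x, tracer = tracer, timepoint = timepoint, vois = vois)
  m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3L) {
    abort(sprintf("need >= 3 control subjects with complete profiles, got %d", n))
  }
  if (all(apply(m, 2, function(col) length(unique(col)) == 1L))) {
    abort("all control values are identical; bootstrap fits are degenerate")
  }
  pairs <- voi_pairs(colnames(m))
  P <- nrow(pairs)
  slope <- matrix(NA_real_, B, P)
  intercept <- matrix(NA_real_, B, P)
  set.seed(seed)
  for (b in seq_len(B)) {
    for (try in seq_len(max_retries + 1L)) {
      idx <- sample.int(n, n, replace = TRUE)
      mb <- m[idx, , drop = FALSE]
      mu <- colMeans(mb)
      cc <- crossprod(sweep(mb, 2, mu)) / (n - 1)
      pred_var <- diag(cc)[pairs$i]
      if (all(pred_var > 0)) break
      if (try > max_retries) {
        abort("degenerate resampling persists: a VOI has no variance in repeated bootstrap draws")
      }
    }
    s <- cc[cbind(pairs$i, pairs$j)] / diag(cc)[pairs$i]
    slope[b, ] <- s
    intercept[b, ] <- mu[pairs$j] - s * mu[pairs$i]
  }
  agg <- if (consensus == "mean") colMeans else
    function(m) apply(m, 2, median)
  pairs$slope <- agg(slope)
  pairs$intercept <- agg(intercept)
  structure(
    list(
      vois = colnames(m), pairs = pairs,
      slope_replicates = slope, intercept_replicates = intercept,
      B = as.integer(B), seed = as.integer(seed), n_control = n,
      consensus = consensus, tracer = tracer,
      timepoint = attr(m, "timepoint"),
      orientation = "lower atlas index predicts higher"
    ),
    class = "pair_fit_ensemble"
  )
}

#' @export
print.pair_fit_ensemble <- function(x, ...) {
  cat("<pair_fit_ensemble>\n")
  cat("  VOIs:", length(x$vois), " pairs:", nrow(x$pairs), "\n")
  cat("  B:", x$B, " controls:", x$n_control, " seed:", x$seed,
      " consensus:", x$consensus, "\n")
  invisible(x)
}
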