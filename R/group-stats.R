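# Group, coupling, and behavior statistics: Shapiro-Wilk gating,
# Mann-Whitney U and Kruskal-Wallis contrasts with Benjamini-Hochberg FDR,
# baseline-vs-percent-change regression, pooled regional tracer coupling,
# and per-arm behavior correlation.

#' Normality gate
#'
#' Shapiro-Wilk test at `alpha = 0.05`, used only to choose between
#' parametric and rank-based contrasts in reports. A constant vector (test
#' undefined) is returned as `"non_normal"` with attribute
#' `constant = TRUE`.
#'
#' @param x Numeric vector, `3 <= n <= 5000`.
#' @param alpha Significance level of the gate.
#' @return `"normal"` or `"non_normal"`.
#' @export
shapiro_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) abort("shapiro_gate needs n >= 3")
  if (length(unique(x)) == 1L) {
    return(structure("non_normal", constant = TRUE))
  }
  if (shapiro.test(x)$p.value >= alpha) "normal" else "non_normal"
}

#' Mann-Whitney U test
#'
#' Wraps [stats::wilcox.test()]: the exact permutation distribution is used
#' when the smaller group has at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie correction is used.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"less"`, or `"greater"`.
#' @param comparison Optional label carried into the result.
#' @return One-row tibble: `comparison`, `statistic_kind` (`"MWU_U"`),
#'   `statistic` (U of the first group), `p_value`, `method`, `n_a`, `n_b`.
#' @export
mwu_test <- function(a, b, alternative = "two.sided", comparison = "a vs b") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- min(length(a), length(b)) <= 8L && !ties
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = exact,
                correct = !exact)
  )
  tibble::tibble(
    comparison = comparison,
    statistic_kind = "MWU_U",
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = if (exact) "exact" else "normal approximation, tie-corrected",
    n_a = length(a),
    n_b = length(b)
  )
}

#' Kruskal-Wallis H test
#'
#' Wraps [stats::kruskal.test()] (H with tie correction, `df = k - 1`,
#' chi-square p-value).
#'
#' @param groups List of numeric vectors (>= 2 groups, each non-empty).
#' @param comparison Optional label.
#' @return One-row tibble: `comparison`, `statistic_kind` (`"KW_H"`),
#'   `statistic`, `df`, `p_value`, group sizes in `n`.
#' @export
kruskal_wallis <- function(groups, comparison = "omnibus") {
  if (!is.list(groups) || length(groups) < 2L) abort("need >= 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) == 0L)) abort("every group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    abort("all values identical: H is undefined (complete ties)")
  }
  ht <- kruskal.test(groups)
  tibble::tibble(
    comparison = comparison,
    statistic_kind = "KW_H",
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    n = list(lengths(groups))
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `p_(i) * m / i` with cumulative minima from the largest
#' rank, capped at 1 (wraps [stats::p.adjust()] with `method = "BH"`).
#' Input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
fdr_adjust <- function(p) {
  if (any(is.na(p) | p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' All pairwise Mann-Whitney contrasts within one family
#'
#' Runs [mwu_test()] for every pair of groups and adjusts the family of
#' p-values by Benjamini-Hochberg FDR.
#'
#' @param df Data frame.
#' @param value,group Columns (tidy-eval) holding the response and the group
#'   label.
#' @param alternative Passed to [mwu_test()].
#' @return Tibble with one row per contrast: `comparison`, `statistic`,
#'   `p_value`, `p_adjusted`, group sizes.
#' @export
pairwise_mwu <- function(df, value, group, alternative = "two.sided") {
  value <- enquo(value); group <- enquo(group)
  v <- dplyr::pull(df, !!value)
  g <- as.character(dplyr::pull(df, !!group))
  levels <- unique(g)
  if (length(levels) < 2L) abort("need >= 2 groups")
  pairs <- utils::combn(levels, 2L)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1L, k]; gb <- pairs[2L, k]
    mwu_test(v[g == ga], v[g == gb], alternative = alternative,
             comparison = paste(ga, "vs", gb))
  })
  res$p_adjusted <- fdr_adjust(res$p_value)
  res
}

# internal: OLS of y on x with degenerate-variance handling
ols_result <- function(x, y, n_excluded = 0L, note = NULL) {
  n <- length(x)
  if (n < 3L) abort("need >= 3 points for a regression")
  if (var(x) == 0 || var(y) == 0) {
    return(structure(
      list(slope = 0, intercept = mean(y), r_squared = NA_real_,
           p_value = NA_real_, n = n, n_excluded = n_excluded,
           degenerate = TRUE, note = note),
      class = "regression_result"
    ))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(
      slope = unname(coef(fit)[2L]),
      intercept = unname(coef(fit)[1L]),
      r_squared = sm$r.squared,
      p_value = unname(pf(sm$fstatistic[1L], sm$fstatistic[2L],
                          sm$fstatistic[3L], lower.tail = FALSE)),
      n = n, n_excluded = n_excluded, degenerate = FALSE, note = note
    ),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat("<regression_result>")
  if (!is.null(x$note)) cat(" [", x$note, "]", sep = "")
  cat("\n")
  if (x$degenerate) {
    cat("  degenerate: zero variance in predictor or response\n")
  } else {
    cat(sprintf("  slope %.4g, R^2 = %.3f, p = %.3g, n = %d\n",
                x$slope, x$r_squared, x$p_value, x$n))
  }
  invisible(x)
}

#' Baseline versus percent-change regression
#'
#' For paired baseline/follow-up values, regresses the percent change
#' `100 * (followup - baseline) / baseline` on the baseline value (OLS).
#' Subjects missing either value are excluded listwise and counted.
#'
#' @param df Data frame with one row per subject.
#' @param baseline,followup Columns (tidy-eval) with the paired values;
#'   baselines must be positive.
#' @return A `regression_result` (see [tidy()] / [glance()]); `degenerate`
#'   is set when the percent change does not vary.
#' @export
baseline_change_regression <- function(df, baseline, followup) {
  baseline <- enquo(baseline); followup <- enquo(followup)
  b <- dplyr::pull(df, !!baseline)
  f <- dplyr::pull(df, !!followup)
  keep <- !is.na(b) & !is.na(f)
  n_excluded <- sum(!keep)
  b <- b[keep]; f <- f[keep]
  if (any(b <= 0)) abort("baseline values must be > 0")
  change <- 100 * (f - b) / b
  ols_result(b, change, n_excluded = n_excluded,
             note = "percent change regressed on baseline")
}

#' Pooled regional coupling between two tracers' z-score profiles
#'
#' Pools the per-(subject, VOI) z-scores of two tracers at one timepoint and
#' fits one OLS line of the first tracer's z on the second's. Because each
#' subject contributes one point per region, the points are not independent;
#' the result is flagged descriptive.
#'
#' @param tspo_z,abeta_z Regional uptake tables in unit `ZSCORE` (response
#'   and predictor, respectively).
#' @param timepoint Scan age; defaults to the latest common age.
#' @return A `regression_result` with note
#'   `"descriptive (non-independent points)"`.
#' @export
regional_coupling <- function(tspo_z, abeta_z, timepoint = NULL) {
  assert_unit(tspo_z, "ZSCORE", "tspo_z")
  assert_unit(abeta_z, "ZSCORE", "abeta_z")
  if (is.null(timepoint)) {
    timepoint <- max(intersect(tspo_z$age_months, abeta_z$age_months))
  }
  a <- dplyr::filter(tspo_z, .data$age_months == !!timepoint)
  b <- dplyr::filter(abeta_z, .data$age_months == !!timepoint)
  joined <- dplyr::inner_join(
    a[c("subject_id", "voi", "value")],
    b[c("subject_id", "voi", "value")],
    by = c("subject_id", "voi"), suffix = c("_tspo", "_abeta")
  )
  if (nrow(joined) < 3L) abort("fewer than 3 matched (subject, VOI) points")
  ols_result(joined$value_abeta, joined$value_tspo,
             note = "descriptive (non-independent points)")
}

#' Per-arm correlation between a PET metric and behavior
#'
#' Regresses the behavior score (time in target quadrant) on a per-subject
#' PET metric (e.g. a composite DI PC1 score or a regional SUVR), separately
#' within each genotype/arm stratum. Strata with fewer than 3 subjects are
#' skipped and reported. No between-arm slope comparison is performed.
#'
#' @param metric Tibble with columns `subject_id` and `metric`.
#' @param behavior Behavior table with `subject_id`, `genotype`, `arm`,
#'   `quadrant_time`.
#' @return Tibble with one row per stratum: `genotype`, `arm`, `slope`,
#'   `r_squared`, `p_value`, `n`, `degenerate`; skipped strata in the
#'   `skipped_strata` attribute.
#' @export
behavior_correlation <- function(metric, behavior) {
  if (!all(c("subject_id", "metric") %in% names(metric))) {
    abort("`metric` needs columns subject_id and metric")
  }
  joined <- dplyr::inner_join(behavior, metric, by = "subject_id")
  strata <- dplyr::group_split(dplyr::group_by(joined, .data$genotype,
                                               .data$arm))
  skipped <- list()
  rows <- list()
  for (s in strata) {
    label <- c(genotype = s$genotype[1L], arm = s$arm[1L])
    if (nrow(s) < 3L) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(genotype = label[["genotype"]], arm = label[["arm"]],
                       n = nrow(s))
      next
    }
    if (var(s$metric) == 0 || var(s$quadrant_time) == 0) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        genotype = label[["genotype"]], arm = label[["arm"]],
        slope = NA_real_, r_squared = NA_real_, p_value = NA_real_,
        n = nrow(s), degenerate = TRUE
      )
      next
    }
    r <- ols_result(s$metric, s$quadrant_time)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      genotype = label[["genotype"]], arm = label[["arm"]],
      slope = r$slope, r_squared = r$r_squared, p_value = r$p_value,
      n = r$n, degenerate = FALSE
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped_strata") <- dplyr::bind_rows(skipped)
  out
}
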