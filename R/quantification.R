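# Quantification: %ID, effect-size screen for the pseudo-reference region,
# SUVR scaling, and control-referenced z-score profiles.

#' Convert regional concentrations to percent injected dose
#'
#' `value = 100 * concentration / injected_dose` per VOI. Concentration and
#' injected dose are assumed decay-corrected to a common time.
#'
#' @param x Tibble with the uptake-table key columns and a `concentration`
#'   column (activity per cc).
#' @param injected_dose Either a single positive number (same dose for every
#'   scan) or a tibble with columns `subject_id`, `tracer`, `age_months`,
#'   `injected_dose`.
#' @return A regional uptake table in unit `PCT_ID`.
#' @export
compute_percent_id <- function(x, injected_dose) {
  x <- tibble::as_tibble(x)
  if (!"concentration" %in% names(x)) abort("`x` needs a `concentration` column")
  if (any(!is.finite(x$concentration) | x$concentration < 0)) {
    abort("concentrations must be finite and >= 0")
  }
  if (is.numeric(injected_dose) && length(injected_dose) == 1L) {
    if (!is.finite(injected_dose) || injected_dose <= 0) {
      abort("injected dose must be > 0")
    }
    x$injected_dose <- injected_dose
  } else {
    dose <- tibble::as_tibble(injected_dose)
    need <- c("subject_id", "tracer", "age_months", "injected_dose")
    if (!all(need %in% names(dose))) {
      abort("dose table needs columns subject_id, tracer, age_months, injected_dose")
    }
    if (any(!is.finite(dose$injected_dose) | dose$injected_dose <= 0)) {
      abort("injected dose must be > 0")
    }
    x <- dplyr::left_join(x, dose[need],
                          by = c("subject_id", "tracer", "age_months"))
    if (anyNA(x$injected_dose)) abort("missing injected dose for some scans")
  }
  x$value <- 100 * x$concentration / x$injected_dose
  x$unit <- "PCT_ID"
  keep <- intersect(UPTAKE_COLUMNS, names(x))
  x[keep]
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(a) - mean(b)) / s_p` with
#' `s_p^2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)`,
#' sample variances with divisor `n - 1`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return The effect size (a relative to b).
#' @export
cohen_d <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a < 2L || n_b < 2L) abort("each group needs at least 2 values")
  s2 <- ((n_a - 1) * var(a) + (n_b - 1) * var(b)) / (n_a + n_b - 2)
  if (s2 <= 0) abort("zero pooled variance")
  (mean(a) - mean(b)) / sqrt(s2)
}

#' Select the pseudo-reference region by genotype effect size
#'
#' For every candidate VOI, the distribution of uptake (%ID) in pooled KI
#' subjects is compared to pooled WT subjects by Cohen's d; the VOI with the
#' smallest absolute effect size is selected as the pseudo-reference region
#' (i.e. the region least affected by genotype). Ties are broken
#' lexicographically by VOI name. By default all timepoints are pooled;
#' `timepoint` restricts the screen to a single scan age.
#'
#' @param x Regional uptake table in unit `PCT_ID`.
#' @param candidates Candidate VOI names; defaults to every VOI in the table.
#' @param tracer Tracer whose uptake is screened.
#' @param timepoint Optional single scan age to restrict the screen to.
#' @return An `effect_size_report`: per-candidate `d` (KI minus WT) and group
#'   sizes, with the selected reference VOI. Use [tidy()] for the
#'   per-VOI table and [glance()] for the selection summary.
#' @export
select_pseudo_reference <- function(x, candidates = NULL, tracer = "TSPO",
                                    timepoint = NULL) {
  assert_unit(x, "PCT_ID")
  x <- dplyr::filter(x, .data$tracer == !!tracer)
  if (!is.null(timepoint)) {
    x <- dplyr::filter(x, .data$age_months == !!timepoint)
  }
  if (is.null(candidates)) candidates <- sort(unique(x$voi))
  absent <- setdiff(candidates, unique(x$voi))
  if (length(absent)) {
    abort(sprintf("candidate VOI absent from table: %s",
                  paste(absent, collapse = ", ")))
  }
  for (g in GENOTYPES) {
    n_subj <- dplyr::n_distinct(x$subject_id[x$genotype == g])
    if (n_subj < 2L) {
      abort(sprintf("need >= 2 subjects of genotype %s, got %d", g, n_subj))
    }
  }
  report <- purrr::map_dfr(sort(candidates), function(v) {
    vx <- x[x$voi == v, ]
    wt <- vx$value[vx$genotype == "WT"]
    ki <- vx$value[vx$genotype == "KI"]
    tibble::tibble(
      voi = v,
      d = cohen_d(ki, wt),
      n_wt = dplyr::n_distinct(vx$subject_id[vx$genotype == "WT"]),
      n_ki = dplyr::n_distinct(vx$subject_id[vx$genotype == "KI"])
    )
  })
  ord <- order(abs(report$d), report$voi)
  structure(
    list(
      report = report,
      selected_reference = report$voi[ord[1L]],
      tracer = tracer,
      timepoint = timepoint
    ),
    class = "effect_size_report"
  )
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat("<effect_size_report>\n")
  cat("  candidates:", nrow(x$report), " tracer:", x$tracer, "\n")
  cat("  timepoints:", if (is.null(x$timepoint)) "pooled" else x$timepoint, "\n")
  sel <- x$report[x$report$voi == x$selected_reference, ]
  cat(sprintf("  selected:   %s (d = %.3f)\n", x$selected_reference, sel$d))
  invisible(x)
}

#' Scale a scan to its pseudo-reference region (SUVR)
#'
#' Divides every VOI value of a scan (one subject, tracer, timepoint) by the
#' scan's uptake in the reference VOI; the reference VOI itself maps to 1.
#' Scans whose reference value is missing or non-positive are excluded from
#' the output and reported via the `excluded_scans` attribute, never silently
#' dropped.
#'
#' @param x Regional uptake table in unit `PCT_ID`.
#' @param reference_voi Name of the pseudo-reference VOI.
#' @return The table in unit `SUVR`, with attribute `excluded_scans` (tibble
#'   of subject_id / tracer / age_months / reason).
#' @export
compute_suvr <- function(x, reference_voi) {
  assert_unit(x, "PCT_ID")
  ref <- x[x$voi == reference_voi,
           c("subject_id", "tracer", "age_months", "value")]
  names(ref)[4L] <- ".ref_value"
  out <- dplyr::left_join(x, ref, by = c("subject_id", "tracer", "age_months"))
  bad <- is.na(out$.ref_value) | out$.ref_value <= 0
  excluded <- dplyr::distinct(
    out[bad, c("subject_id", "tracer", "age_months", ".ref_value")]
  )
  excluded$reason <- ifelse(is.na(excluded$.ref_value),
                            "reference VOI missing",
                            "non-positive reference value")
  excluded$.ref_value <- NULL
  out <- out[!bad, ]
  out$value <- out$value / out$.ref_value
  out$unit <- "SUVR"
  out <- out[UPTAKE_COLUMNS]
  attr(out, "excluded_scans") <- excluded
  attr(out, "reference_voi") <- reference_voi
  out
}

#' Control-referenced z-score profiles
#'
#' Standardizes every VOI value against the mean and SD (divisor `n - 1`) of
#' a control cohort at a reference timepoint:
#' `z = (value - mean_control) / sd_control` per VOI. Scans at earlier
#' timepoints reuse the reference-timepoint control statistics, so that
#' z-scores are comparable across ages.
#'
#' @param x Regional uptake table (typically unit `SUVR`).
#' @param control_subjects Subject ids forming the control cohort (>= 3
#'   required at the reference timepoint).
#' @param tracer Tracer to standardize.
#' @param timepoint Reference timepoint; defaults to the latest age in the
#'   table.
#' @return The table restricted to `tracer`, in unit `ZSCORE`, with the
#'   control statistics in attribute `control_stats`.
#' @export
compute_zscores <- function(x, control_subjects, tracer = "TSPO",
                            timepoint = NULL) {
  assert_unit(x, c("PCT_ID", "SUVR"))
  x <- dplyr::filter(x, .data$tracer == !!tracer)
  if (nrow(x) == 0L) abort(sprintf("no rows for tracer %s", tracer))
  if (is.null(timepoint)) timepoint <- max(x$age_months)
  ctrl <- dplyr::filter(x, .data$subject_id %in% control_subjects,
                        .data$age_months == !!timepoint)
  absent <- setdiff(control_subjects, unique(ctrl$subject_id))
  if (length(absent)) {
    abort(sprintf("control subject absent at reference timepoint %s: %s",
                  timepoint, paste(absent, collapse = ", ")))
  }
  if (dplyr::n_distinct(ctrl$subject_id) < 3L) {
    abort("need >= 3 control subjects at the reference timepoint")
  }
  stats <- dplyr::summarise(
    dplyr::group_by(ctrl, .data$voi),
    mean_control = mean(.data$value),
    sd_control = sd(.data$value),
    n_control = dplyr::n(),
    .groups = "drop"
  )
  if (any(stats$sd_control <= 0)) {
    abort(sprintf("zero control SD in VOI: %s",
                  paste(stats$voi[stats$sd_control <= 0], collapse = ", ")))
  }
  out <- dplyr::left_join(x, stats, by = "voi")
  if (anyNA(out$mean_control)) {
    abort(sprintf("no control statistics for VOI: %s",
                  paste(unique(out$voi[is.na(out$mean_control)]),
                        collapse = ", ")))
  }
  out$value <- (out$value - out$mean_control) / out$sd_control
  out$unit <- "ZSCORE"
  out <- out[UPTAKE_COLUMNS]
  attr(out, "control_stats") <- stats
  attr(out, "reference_timepoint") <- timepoint
  out
}

#' Regional means from a labeled image volume
#'
#' Averages the voxels of a scalar 3D volume within each labeled VOI of an
#' integer label volume. Voxels labeled 0 are background and ignored.
#'
#' @param image 3D numeric array.
#' @param labels 3D integer array of the same shape.
#' @param label_map Named integer vector mapping VOI name to label id.
#' @return Tibble with `voi`, `value` (mean), `n_voxels`.
#' @export
extract_voi_means <- function(image, labels, label_map) {
  if (!identical(dim(image), dim(labels))) {
    abort("image and label volumes must share the same shape")
  }
  if (is.null(names(label_map)) || any(!nzchar(names(label_map)))) {
    abort("`label_map` must be a named vector (voi -> label id)")
  }
  purrr::imap_dfr(label_map, function(id, voi) {
    mask <- labels == id
    n_vox <- sum(mask)
    if (n_vox == 0L) {
      abort(sprintf("label for VOI '%s' (id %d) absent from volume", voi, id))
    }
    tibble::tibble(voi = voi, value = mean(image[mask]), n_voxels = n_vox)
  })
}

#' Regional means from NIfTI files
#'
#' Convenience wrapper around [extract_voi_means()] reading the image and
#' label volumes from NIfTI files (requires the RNifti package).
#'
#' @param image_path,labels_path Paths to `.nii`/`.nii.gz` files.
#' @param label_map Named integer vector mapping VOI name to label id.
#' @return See [extract_voi_means()].
#' @export
read_nifti_voi_means <- function(image_path, labels_path, label_map) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("the RNifti package is required to read NIfTI volumes")
  }
  img <- as.array(RNifti::readNifti(image_path))
  lab <- as.array(RNifti::readNifti(labels_path))
  storage.mode(lab) <- "integer"
  extract_voi_means(img, lab, label_map)
}
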