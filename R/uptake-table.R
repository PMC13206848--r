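# Long-format regional uptake tables: the interchange format shared by every
# pipeline stage. Columns (exactly):
#   subject_id, genotype, arm, age_months, tracer, voi, value, unit

UPTAKE_COLUMNS <- c("subject_id", "genotype", "arm", "age_months",
                    "tracer", "voi", "value", "unit")
GENOTYPES <- c("WT", "KI")
ARMS <- c("PL/PL", "Ab/PL", "PL/Pio", "Ab/Pio")
TRACERS <- c("TSPO", "ABETA")
UNITS <- c("PCT_ID", "SUVR", "ZSCORE")

#' Validate a regional uptake table
#'
#' Checks a long-format uptake table (or CSV file) against the interchange
#' schema: required columns, known genotype/arm/tracer/unit levels, a single
#' homogeneous unit, uniqueness of the (subject_id, tracer, age_months, voi)
#' key, and strict positivity of `PCT_ID` and `SUVR` values. Malformed rows
#' are enumerated in the error message.
#'
#' @param x A data frame or the path of a CSV file.
#' @return The validated table as a tibble.
#' @export
validate_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort(sprintf("file not found: %s", x))
    x <- readr::read_csv(x, show_col_types = FALSE, progress = FALSE)
  }
  x <- tibble::as_tibble(x)
  missing_cols <- setdiff(UPTAKE_COLUMNS, names(x))
  if (length(missing_cols)) {
    abort(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  x <- x[UPTAKE_COLUMNS]
  problems <- character()
  bad_rows <- function(mask, what) {
    idx <- which(mask)
    if (length(idx)) {
      sprintf("%s (rows %s)", what,
              paste(head(idx, 10L), collapse = ", "))
    } else {
      character()
    }
  }
  problems <- c(
    problems,
    bad_rows(!x$genotype %in% GENOTYPES, "unknown genotype"),
    bad_rows(!x$arm %in% ARMS, "unknown arm"),
    bad_rows(!x$tracer %in% TRACERS, "unknown tracer"),
    bad_rows(!x$unit %in% UNITS, "unknown unit"),
    bad_rows(!is.finite(x$value), "non-finite value"),
    bad_rows(!is.finite(x$age_months), "non-finite age_months")
  )
  units_present <- unique(x$unit)
  if (length(units_present) > 1L) {
    problems <- c(problems, sprintf(
      "mixed units in one table: %s", paste(units_present, collapse = ", ")
    ))
  }
  if (identical(units_present, "PCT_ID") || identical(units_present, "SUVR")) {
    problems <- c(problems, bad_rows(
      x$value <= 0, sprintf("non-positive %s value", units_present)
    ))
  }
  key <- paste(x$subject_id, x$tracer, x$age_months, x$voi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first_dup <- x[which(dup)[1L], ]
    problems <- c(problems, sprintf(
      "duplicate key (subject_id=%s, tracer=%s, age_months=%s, voi=%s)",
      first_dup$subject_id, first_dup$tracer,
      first_dup$age_months, first_dup$voi
    ))
  }
  if (length(problems)) {
    abort(paste0("invalid uptake table:\n", paste("-", problems, collapse = "\n")))
  }
  x
}

#' Read / write uptake tables
#'
#' Thin CSV wrappers around [validate_table()]. `write_uptake()` writes the
#' canonical column order so that write-read-write round trips are
#' byte-stable.
#'
#' @param path CSV file path.
#' @param x An uptake table.
#' @return `read_uptake()` returns a validated tibble; `write_uptake()`
#'   returns `x` invisibly.
#' @export
read_uptake <- function(path) validate_table(path)

#' @rdname read_uptake
#' @export
write_uptake <- function(x, path) {
  x <- validate_table(x)
  out <- x
  # 12 significant digits are a fixed point of write-parse-write, so round
  # trips are byte-stable while staying far below measurement precision
  out$value <- sprintf("%.12g", out$value)
  readr::write_csv(out, path, progress = FALSE)
  invisible(x)
}

# internal: assert homogeneous unit and return it
assert_unit <- function(x, expected = NULL, arg = "table") {
  u <- unique(x$unit)
  if (length(u) != 1L) {
    abort(sprintf("%s mixes units: %s", arg, paste(u, collapse = ", ")))
  }
  if (!is.null(expected) && !u %in% expected) {
    abort(sprintf("%s must be in unit %s, got %s",
                  arg, paste(expected, collapse = "/"), u))
  }
  u
}

# internal: subject x VOI wide matrix for one tracer/timepoint
uptake_wide <- function(x, tracer = "TSPO", timepoint = NULL, vois = NULL) {
  x <- dplyr::filter(x, .data$tracer == !!tracer)
  if (nrow(x) == 0L) abort(sprintf("no rows for tracer %s", tracer))
  if (is.null(timepoint)) timepoint <- max(x$age_months)
  x <- dplyr::filter(x, .data$age_months == !!timepoint)
  if (nrow(x) == 0L) {
    abort(sprintf("no rows at timepoint %s for tracer %s", timepoint, tracer))
  }
  if (is.null(vois)) vois <- unique(x$voi)
  x <- dplyr::filter(x, .data$voi %in% vois)
  wide <- tidyr::pivot_wider(
    x[c("subject_id", "voi", "value")],
    names_from = "voi", values_from = "value"
  )
  missing_vois <- setdiff(vois, names(wide))
  if (length(missing_vois)) {
    abort(sprintf("VOIs absent at timepoint %s: %s", timepoint,
                  paste(missing_vois, collapse = ", ")))
  }
  m <- as.matrix(wide[vois])
  rownames(m) <- wide$subject_id
  attr(m, "timepoint") <- timepoint
  m
}
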