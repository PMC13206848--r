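# End-to-end pipeline: simulate -> quantify -> connect -> desync -> stats,
# with CSV/JSON outputs and a digest manifest making runs reproducible and
# verifiable. Stage dependencies are computed in memory as needed; only the
# requested stages write outputs (so e.g. a stats-only run on a precomputed
# uptake table lists no simulation stage in its manifest).

PIPELINE_STAGES <- c("simulate", "quantify", "connect", "desync", "stats")

#' Configure a pipeline run
#'
#' @param stages Which stages to execute and write (subset of
#'   `simulate`, `quantify`, `connect`, `desync`, `stats`).
#' @param seed Integer seed governing every random draw of the run.
#' @param B Bootstrap replicate count for the pair-fit ensemble.
#' @param reference `"auto"` (data-driven pseudo-reference screen) or a VOI
#'   name.
#' @param abeta_reference Pseudo-reference VOI for the amyloid tracer.
#' @param di_method `"consensus"` or `"replicate"` distances for the DI.
#' @param pc1_standardize Standardize constituent DIs before PC1.
#' @param atlas A [voi_atlas()].
#' @param synth A [synth_config()]; defaults to the standard cohort with
#'   `seed`.
#' @param input_uptake Optional precomputed uptake table (tibble or CSV
#'   path, unit `PCT_ID`) used instead of simulation.
#' @param input_behavior Optional behavior table (tibble or CSV path).
#' @return A `run_config` list.
#' @export
run_config <- function(stages = PIPELINE_STAGES,
                       seed = 1L, B = 1000L,
                       reference = "auto",
                       abeta_reference = "periaqueductal_gray",
                       di_method = "consensus",
                       pc1_standardize = TRUE,
                       atlas = default_atlas(),
                       synth = NULL,
                       input_uptake = NULL,
                       input_behavior = NULL) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  if (is.null(synth)) synth <- synth_config(seed = seed)
  structure(
    list(stages = stages, seed = as.integer(seed), B = as.integer(B),
         reference = reference, abeta_reference = abeta_reference,
         di_method = di_method, pc1_standardize = pc1_standardize,
         atlas = atlas, synth = synth, input_uptake = input_uptake,
         input_behavior = input_behavior),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Recognized fields map onto the arguments of [run_config()]:
#' `stages`, `seed`, `B`, `reference`, `abeta_reference`, `di_method`,
#' `pc1_standardize`, `input_uptake`, `input_behavior`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("stages", "seed", "B", "reference", "abeta_reference",
             "di_method", "pc1_standardize", "input_uptake", "input_behavior")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw[intersect(names(raw), known)])
}

# internal: run one stage with failure attribution
run_stage <- function(stage, fn) {
  tryCatch(fn(), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

write_csv_out <- function(x, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  path
}

write_json_out <- function(x, dir, name) {
  path <- file.path(dir, name)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Execute the analysis pipeline
#'
#' Runs the requested stages on a synthetic or supplied cohort and writes
#' their outputs plus a `manifest.json` recording the configuration, the
#' stages run, and an MD5 digest of every output file. Re-running with an
#' identical configuration reproduces identical digests.
#'
#' @param config A [run_config()] (or path accepted by
#'   [read_run_config()]).
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) abort("`config` must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  atlas <- config$atlas
  files <- character()
  info <- list()

  # --- simulate (or load) ---------------------------------------------------
  behavior <- NULL
  if (!is.null(config$input_uptake)) {
    uptake <- run_stage("quantify", function() {
      validate_table(config$input_uptake)
    })
    if (!is.null(config$input_behavior)) {
      behavior <- config$input_behavior
      if (is.character(behavior)) {
        behavior <- readr::read_csv(behavior, show_col_types = FALSE,
                                    progress = FALSE)
      }
      behavior <- tibble::as_tibble(behavior)
    }
    cohort <- NULL
  } else {
    cohort <- run_stage("simulate", function() {
      apply_missingness(generate_cohort(config$synth), config$synth)
    })
    uptake <- cohort$uptake
    behavior <- cohort$behavior
  }
  if ("simulate" %in% config$stages) {
    if (is.null(cohort)) {
      abort("stage 'simulate' requested but an input uptake table was supplied")
    }
    files["uptake"] <- write_csv_out(uptake, out_dir, "uptake.csv")
    files["behavior"] <- write_csv_out(behavior, out_dir, "behavior.csv")
    files["truth"] <- write_csv_out(cohort$truth$subjects, out_dir,
                                    "truth_subjects.csv")
    removed <- attr(uptake, "removed_scans")
    if (!is.null(removed) && nrow(removed)) {
      files["removed_scans"] <- write_csv_out(removed, out_dir,
                                              "removed_scans.csv")
    }
  }

  # --- quantify -------------------------------------------------------------
  final_tp <- max(uptake$age_months)
  q <- run_stage("quantify", function() {
    if (identical(config$reference, "auto")) {
      screen <- select_pseudo_reference(uptake)
      reference <- screen$selected_reference
    } else {
      screen <- NULL
      reference <- config$reference
      if (!reference %in% uptake$voi) {
        abort(sprintf("reference VOI '%s' absent from table", reference))
      }
    }
    tspo_suvr <- compute_suvr(
      dplyr::filter(uptake, .data$tracer == "TSPO"), reference
    )
    wt_final <- unique(uptake$subject_id[
      uptake$genotype == "WT" & uptake$age_months == final_tp &
        uptake$tracer == "TSPO"
    ])
    tspo_z <- compute_zscores(
      dplyr::filter(tspo_suvr, .data$voi != reference),
      wt_final, tracer = "TSPO", timepoint = final_tp
    )
    abeta_suvr <- NULL
    abeta_z <- NULL
    if ("ABETA" %in% uptake$tracer &&
          config$abeta_reference %in% uptake$voi) {
      abeta_suvr <- compute_suvr(
        dplyr::filter(uptake, .data$tracer == "ABETA"),
        config$abeta_reference
      )
      wt_final_ab <- unique(abeta_suvr$subject_id[
        abeta_suvr$genotype == "WT" & abeta_suvr$age_months == final_tp
      ])
      if (length(wt_final_ab) >= 3L) {
        abeta_z <- compute_zscores(
          dplyr::filter(abeta_suvr, .data$voi != config$abeta_reference),
          wt_final_ab, tracer = "ABETA", timepoint = final_tp
        )
      }
    }
    list(screen = screen, reference = reference, tspo_suvr = tspo_suvr,
         tspo_z = tspo_z, abeta_suvr = abeta_suvr, abeta_z = abeta_z)
  })
  info$reference <- q$reference
  if ("quantify" %in% config$stages) {
    if (!is.null(q$screen)) {
      files["effect_sizes"] <- write_csv_out(tidy(q$screen), out_dir,
                                             "effect_sizes.csv")
    }
    suvr_all <- dplyr::bind_rows(q$tspo_suvr, q$abeta_suvr)
    files["uptake_suvr"] <- write_csv_out(suvr_all, out_dir,
                                          "uptake_suvr.csv")
    z_all <- dplyr::bind_rows(q$tspo_z, q$abeta_z)
    files["uptake_zscore"] <- write_csv_out(z_all, out_dir,
                                            "uptake_zscore.csv")
    excl <- dplyr::bind_rows(attr(q$tspo_suvr, "excluded_scans"),
                             attr(q$abeta_suvr, "excluded_scans"))
    if (nrow(excl)) {
      files["excluded_scans"] <- write_csv_out(excl, out_dir,
                                               "excluded_scans.csv")
    }
  }

  # --- connect --------------------------------------------------------------
  target_vois <- setdiff(intersect(atlas$target_vois, unique(q$tspo_suvr$voi)),
                         q$reference)
  controls <- unique(q$tspo_suvr$subject_id[
    q$tspo_suvr$genotype == "WT" & q$tspo_suvr$age_months == final_tp
  ])
  conn <- run_stage("connect", function() {
    icc <- compute_icc_matrix(q$tspo_suvr, timepoint = final_tp,
                              vois = target_vois)
    fits <- bootstrap_pair_fits(q$tspo_suvr, controls, B = config$B,
                                seed = config$seed, timepoint = final_tp,
                                vois = target_vois)
    list(icc = icc, fits = fits)
  })
  if ("connect" %in% config$stages) {
    r_wide <- tibble::as_tibble(conn$icc$r, rownames = "voi")
    z_wide <- tibble::as_tibble(conn$icc$z, rownames = "voi")
    files["connectivity_r"] <- write_csv_out(r_wide, out_dir,
                                             "connectivity_r.csv")
    files["connectivity_z"] <- write_csv_out(z_wide, out_dir,
                                             "connectivity_z.csv")
    files["pair_fits"] <- write_csv_out(tidy(conn$fits), out_dir,
                                        "pair_fits.csv")
    files["connectivity_meta"] <- write_json_out(
      c(as.list(glance(conn$icc)),
        list(B = conn$fits$B, seed = conn$fits$seed,
             orientation = conn$fits$orientation,
             control_subjects = sort(controls))),
      out_dir, "connectivity_meta.json"
    )
  }

  # --- desync ---------------------------------------------------------------
  des <- run_stage("desync", function() {
    di <- compute_di(q$tspo_suvr, conn$fits, timepoint = final_tp,
                     method = config$di_method)
    composites <- purrr::imap(atlas$composites, function(cvois, cname) {
      composite_pc1(di, intersect(cvois, target_vois), name = cname,
                    standardize = config$pc1_standardize)
    })
    list(di = di, composites = composites)
  })
  comp_scores <- purrr::map_dfr(des$composites, tidy)
  if ("desync" %in% config$stages) {
    files["desync"] <- write_csv_out(des$di, out_dir, "desync.csv")
    files["composites"] <- write_csv_out(comp_scores, out_dir,
                                         "composites.csv")
    files["desync_meta"] <- write_json_out(
      list(method = attr(des$di, "method"),
           timepoint = attr(des$di, "timepoint"),
           B = conn$fits$B, seed = conn$fits$seed,
           control_subjects = sort(controls),
           pc1 = purrr::map_dfr(des$composites, glance)),
      out_dir, "desync_meta.json"
    )
  }

  # --- stats ----------------------------------------------------------------
  if ("stats" %in% config$stages) {
    st <- run_stage("stats", function() {
      regions <- list(amygdala = "amygdala",
                      cortex = intersect(atlas$composites$cortex,
                                         target_vois))
      contrasts <- purrr::imap_dfr(regions, function(vois, rname) {
        df <- dplyr::filter(uptake, .data$tracer == "TSPO",
                            .data$age_months == final_tp,
                            .data$voi %in% vois)
        df <- dplyr::summarise(
          dplyr::group_by(df, .data$subject_id, .data$genotype, .data$arm),
          value = mean(.data$value), .groups = "drop"
        )
        df$cell <- paste(df$genotype, df$arm)
        kw <- kruskal_wallis(split(df$value, df$cell),
                             comparison = "omnibus")
        kw$p_adjusted <- NA_real_
        pw <- pairwise_mwu(df, value, cell)
        pw$df <- NA_real_
        pw$n <- list(NULL)
        dplyr::mutate(dplyr::bind_rows(kw, pw), region = rname,
                      .before = 1L)
      })
      coupling <- NULL
      if (!is.null(q$abeta_z)) {
        ki_arms <- sort(unique(q$tspo_z$arm[q$tspo_z$genotype == "KI"]))
        coupling <- purrr::map_dfr(ki_arms, function(a) {
          tz <- dplyr::filter(q$tspo_z, .data$genotype == "KI",
                              .data$arm == a, .data$voi %in% target_vois)
          az <- dplyr::filter(q$abeta_z, .data$genotype == "KI",
                              .data$arm == a, .data$voi %in% target_vois)
          res <- tryCatch(
            glance(regional_coupling(tz, az, timepoint = final_tp)),
            error = function(e) NULL
          )
          if (is.null(res)) return(NULL)
          dplyr::mutate(res, arm = a, .before = 1L)
        })
      }
      beh <- NULL
      if (!is.null(behavior) && "cortex" %in% comp_scores$composite) {
        metric <- dplyr::rename(
          dplyr::filter(comp_scores, .data$composite == "cortex"),
          metric = "score"
        )[c("subject_id", "metric")]
        beh <- behavior_correlation(metric, behavior)
      }
      bc <- purrr::map_dfr(
        dplyr::group_split(dplyr::group_by(q$tspo_suvr, .data$genotype,
                                           .data$arm)),
        function(g) {
          wide <- tidyr::pivot_wider(
            dplyr::summarise(
              dplyr::group_by(
                dplyr::filter(g, .data$voi %in% atlas$composites$cortex),
                .data$subject_id, .data$age_months
              ),
              value = mean(.data$value), .groups = "drop"
            ),
            names_from = "age_months", values_from = "value",
            names_prefix = "t"
          )
          t_first <- paste0("t", format(min(g$age_months)))
          t_last <- paste0("t", format(final_tp))
          if (!all(c(t_first, t_last) %in% names(wide)) ||
                t_first == t_last) {
            return(NULL)
          }
          paired <- wide[!is.na(wide[[t_first]]) & !is.na(wide[[t_last]]), ]
          if (nrow(paired) < 3L) return(NULL)
          paired$baseline <- paired[[t_first]]
          paired$followup <- paired[[t_last]]
          res <- glance(baseline_change_regression(paired, baseline, followup))
          dplyr::mutate(res, genotype = g$genotype[1L], arm = g$arm[1L],
                        .before = 1L)
        }
      )
      list(contrasts = contrasts, coupling = coupling, behavior = beh,
           baseline_change = bc)
    })
    files["stats_contrasts"] <- write_csv_out(
      dplyr::mutate(st$contrasts, n = purrr::map_chr(
        .data$n, ~ paste(unlist(.x), collapse = ";")
      )),
      out_dir, "stats_contrasts.csv"
    )
    if (!is.null(st$coupling) && nrow(st$coupling)) {
      files["coupling"] <- write_csv_out(st$coupling, out_dir,
                                         "coupling.csv")
    }
    if (!is.null(st$behavior) && nrow(st$behavior)) {
      files["behavior_correlation"] <- write_csv_out(
        st$behavior, out_dir, "behavior_correlation.csv"
      )
    }
    if (nrow(st$baseline_change)) {
      files["baseline_change"] <- write_csv_out(st$baseline_change, out_dir,
                                                "baseline_change.csv")
    }
  }

  digests <- vapply(files, function(f) unname(tools::md5sum(f)), character(1))
  manifest <- list(
    package = "petsync",
    version = as.character(utils::packageVersion("petsync")),
    stages = config$stages,
    seed = config$seed,
    B = config$B,
    reference_policy = config$reference,
    selected_reference = info$reference,
    di_method = config$di_method,
    outputs = as.list(setNames(
      sprintf("%s md5:%s", basename(files), digests), names(files)
    ))
  )
  write_json_out(manifest, out_dir, "manifest.json")
  invisible(manifest)
}
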