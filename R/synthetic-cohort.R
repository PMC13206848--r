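# Synthetic cohort generator.
#
# Generative model (per subject s, VOI v, timepoint t, TSPO tracer):
#
#   value = exp( loading[v] * ( sqrt(1 - delta_s) * F_s
#                               + sqrt(delta_s) * G_sv ) - loading[v]^2 / 2 )
#           * ( base_mean[v] + A_s * [s is KI]
#               * ( genotype_offset[v]
#                   + genotype_slope[v] * mult[arm_s] * (t - t0) ) )
#         + noise_sd[v] * eps
#
# F_s ~ N(0,1) is a shared per-subject activation factor that synchronizes
# regions multiplicatively (a log-normal scan scale, mean 1); G_sv ~ N(0,1)
# is idiosyncratic. The sqrt mixing weights preserve the log-scale variance
# of the latent term for every delta in [0,1], so increasing delta destroys
# interregional covariance without changing scale; the shared component
# cancels exactly in reference-region ratios (SUVR), while the replaced
# (idiosyncratic) component does not -- which is precisely what the
# desynchronization index detects. Reference VOIs are spared from the
# replacement (delta does not apply to them). A_s is a log-normal (mean 1)
# per-subject pathology amplitude shared between tracers. Amyloid-tracer
# values share the genotype-driven regional profile scaled by a per-arm,
# per-timepoint coupling kappa; wild-type amyloid signal is noise.

default_arms <- function() {
  tibble::tribble(
    ~genotype, ~arm,     ~n,  ~delta, ~behavior_intercept, ~behavior_beta,
    "WT",      "PL/PL",   8L,  0,     30,                   0,
    "WT",      "Ab/PL",   8L,  0,     30,                   0,
    "KI",      "PL/PL",  10L,  0.5,   21,                   0,
    "KI",      "Ab/PL",  14L,  0.5,   28,                  -4,
    "KI",      "PL/Pio", 11L,  0.4,   23,                   0,
    "KI",      "Ab/Pio", 21L,  0.4,   23,                   0
  )
}

default_voi_params <- function(atlas = default_atlas()) {
  base_of <- c(
    visual_cortex = 2.2, auditory_cortex = 2.2, somatosensory_cortex = 2.2,
    sensorimotor_cortex = 2.2, entorhinal_cortex = 2.2,
    amygdala = 2.0, hippocampus = 2.1, thalamus = 2.3, striatum = 2.2,
    hypothalamus = 2.0, midbrain = 2.1, olfactory_bulb = 1.8,
    cerebellum = 2.4, septum = 2.0, colliculi = 2.2,
    brainstem = 2.0, periaqueductal_gray = 1.9
  )
  slope_of <- c(
    visual_cortex = 0.095, auditory_cortex = 0.095,
    somatosensory_cortex = 0.095, sensorimotor_cortex = 0.095,
    entorhinal_cortex = 0.10,
    amygdala = 0.08, hippocampus = 0.085, thalamus = 0.06, striatum = 0.06,
    hypothalamus = 0.06, midbrain = 0.06, olfactory_bulb = 0.06,
    cerebellum = 0.06, septum = 0.06, colliculi = 0.06,
    brainstem = 0, periaqueductal_gray = 0
  )
  vois <- c(atlas$target_vois, atlas$reference_candidates)
  stem <- sub("_(l|r)$", "", vois)
  is_ref <- vois %in% atlas$reference_candidates
  base <- unname(base_of[stem])
  slope <- unname(slope_of[stem])
  tibble::tibble(
    voi = vois,
    base_mean = base,
    loading = 0.25,
    noise_sd = ifelse(is_ref, 0.10, 0.12) * base,
    genotype_slope = slope,
    genotype_offset = 15 * slope,
    ab_base_mean = ifelse(vois == "periaqueductal_gray", 1.8,
                          ifelse(vois == "brainstem", 1.9, 2.0)),
    is_reference = is_ref
  )
}

default_coupling <- function(arms, timepoints) {
  pattern <- list(
    c("PL/PL" = 0.15, "Ab/PL" = 0.15, "PL/Pio" = 0.15, "Ab/Pio" = 0.15),
    c("PL/PL" = 0.10, "Ab/PL" = 0.55, "PL/Pio" = 0.50, "Ab/Pio" = 0.40),
    c("PL/PL" = 0.10, "Ab/PL" = 0.40, "PL/Pio" = 0.35, "Ab/Pio" = 0.55)
  )
  arm_names <- unique(arms$arm)
  purrr::map_dfr(seq_along(timepoints), function(i) {
    kap <- pattern[[min(i, length(pattern))]]
    tibble::tibble(
      arm = arm_names,
      age_months = timepoints[i],
      kappa = unname(kap[arm_names])
    )
  })
}

#' Configure a synthetic cohort
#'
#' Builds and validates the full generative parameterization of a simulated
#' dual-tracer cohort. The defaults emulate the structure of a longitudinal
#' preclinical amyloidosis study: two genotypes (WT, KI), four treatment arms
#' (`PL/PL`, `Ab/PL`, `PL/Pio`, `Ab/Pio`), scans at 5, 7.5 and 10 months,
#' twenty target VOIs plus two reference VOIs, a genotype-driven regional
#' uptake increase attenuated by treatment, per-arm desynchronization
#' strength, arm- and age-dependent amyloid coupling, and a behavior score
#' linked to cortical desynchronization in one arm.
#'
#' @param arms Tibble with columns `genotype`, `arm`, `n`, `delta`,
#'   `behavior_intercept`, `behavior_beta`. `delta` in `[0,1]` is the fraction
#'   of the shared-factor variance replaced by independent noise
#'   (desynchronization strength).
#' @param voi_params Tibble of per-VOI generative parameters (see
#'   `petsync:::default_voi_params`): `base_mean` (> 0, percent injected dose
#'   scale), `loading` (log-scale SD of the multiplicative scan factor),
#'   `noise_sd`, `genotype_slope` (added uptake per month
#'   in KI animals; 0 for reference VOIs), `genotype_offset` (KI elevation
#'   already present at baseline), `ab_base_mean`, `is_reference`.
#' @param timepoints Strictly increasing scan ages in months.
#' @param treatment_multiplier Named vector scaling `genotype_slope` per arm.
#' @param coupling Tibble `arm`, `age_months`, `kappa`: strength linking the
#'   genotype-driven regional profile to the amyloid tracer.
#' @param missing_rate Per-timepoint probability that a scan is absent
#'   (each in `[0, 0.95)`).
#' @param behavior_sd Residual SD of the behavior score (seconds).
#' @param amp_sigma Log-scale SD of the per-subject pathology amplitude
#'   `A_s = exp(amp_sigma * Z - amp_sigma^2 / 2)` (mean 1) that scales the
#'   genotype-driven uptake of both tracers, modeling interindividual
#'   heterogeneity of disease burden.
#' @param ab_gain Scale of the coupled amyloid component.
#' @param ab_genotype_offset Regionally flat KI elevation of amyloid uptake.
#' @param ab_loading_frac,ab_noise_frac Log-scale SD of the amyloid scan
#'   factor, and amyloid noise SD as a fraction of `ab_base_mean`.
#' @param cortex_vois VOIs whose idiosyncratic components define the cortical
#'   desynchronization proxy used by the behavior model.
#' @param wt_abeta_final_only If `TRUE`, WT animals receive the amyloid
#'   tracer only at the final timepoint (as in split scan schedules).
#' @param seed Integer seed; identical configurations with identical seeds
#'   generate bit-identical cohorts.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(arms = default_arms(),
                         voi_params = default_voi_params(),
                         timepoints = c(5, 7.5, 10),
                         treatment_multiplier = c("PL/PL" = 1, "Ab/PL" = 0.45,
                                                  "PL/Pio" = 0.70,
                                                  "Ab/Pio" = 0.50),
                         coupling = NULL,
                         missing_rate = rep(0, length(timepoints)),
                         behavior_sd = 2.5,
                         amp_sigma = 0.8,
                         ab_gain = 4,
                         ab_genotype_offset = 0.6,
                         ab_loading_frac = 0.30,
                         ab_noise_frac = 0.22,
                         cortex_vois = default_atlas()$composites$cortex,
                         wt_abeta_final_only = TRUE,
                         seed = 1L) {
  arms <- tibble::as_tibble(arms)
  voi_params <- tibble::as_tibble(voi_params)
  if (is.null(coupling)) coupling <- default_coupling(arms, timepoints)

  bad_arm <- setdiff(arms$arm, ARMS)
  if (length(bad_arm)) {
    abort(sprintf("unknown arm: %s", paste(bad_arm, collapse = ", ")))
  }
  if (!all(arms$genotype %in% GENOTYPES)) abort("unknown genotype in arms")
  if (anyDuplicated(paste(arms$genotype, arms$arm))) {
    abort("duplicate genotype/arm combination")
  }
  if (any(arms$n < 1)) abort("each arm needs n >= 1")
  if (any(arms$delta < 0 | arms$delta > 1)) abort("delta must lie in [0, 1]")
  if (anyDuplicated(voi_params$voi)) abort("duplicate VOI names")
  if (any(voi_params$base_mean <= 0)) abort("all base_mean must be > 0")
  if (any(voi_params$noise_sd < 0)) abort("noise_sd must be >= 0")
  if (any(voi_params$genotype_slope[voi_params$is_reference] != 0)) {
    abort("reference VOIs must have genotype_slope = 0")
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly increasing")
  }
  if (length(missing_rate) == 1L) {
    missing_rate <- rep(missing_rate, length(timepoints))
  }
  if (length(missing_rate) != length(timepoints)) {
    abort("missing_rate must have one entry per timepoint")
  }
  if (any(missing_rate < 0 | missing_rate >= 0.95)) {
    abort(paste("missing_rate must lie in [0, 0.95):",
                "baseline protection unsatisfiable at higher rates"))
  }
  mult_missing <- setdiff(arms$arm, names(treatment_multiplier))
  if (length(mult_missing)) {
    abort(sprintf("treatment_multiplier missing for arm: %s",
                  paste(mult_missing, collapse = ", ")))
  }
  if (length(bad <- setdiff(cortex_vois, voi_params$voi))) {
    abort(sprintf("cortex_vois not in voi_params: %s",
                  paste(bad, collapse = ", ")))
  }
  structure(
    list(
      arms = arms, voi_params = voi_params, timepoints = timepoints,
      treatment_multiplier = treatment_multiplier, coupling = coupling,
      missing_rate = missing_rate, behavior_sd = behavior_sd,
      amp_sigma = amp_sigma, ab_gain = ab_gain, ab_genotype_offset = ab_genotype_offset,
      ab_loading_frac = ab_loading_frac, ab_noise_frac = ab_noise_frac,
      cortex_vois = cortex_vois, wt_abeta_final_only = wt_abeta_final_only,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat("  subjects:  ", sum(x$arms$n), "in", nrow(x$arms), "genotype/arm cells\n")
  cat("  VOIs:      ", nrow(x$voi_params),
      sprintf("(%d reference)\n", sum(x$voi_params$is_reference)))
  cat("  timepoints:", paste(x$timepoints, collapse = ", "), "months\n")
  cat("  seed:      ", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Draws a complete dual-tracer cohort (uptake table in percent injected
#' dose, behavior table, and a `truth` record sufficient to recompute the
#' generative expectations) from a [synth_config()]. Identical configuration
#' and seed reproduce the cohort exactly.
#'
#' @param config A `synth_config`.
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `uptake` (long tibble, unit `PCT_ID`), `behavior` (one row per subject,
#'   final timepoint), and `truth` (per-subject latent factors,
#'   desynchronization strength and cortical proxy, plus the configuration).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) abort("`config` must be a synth_config")
  vp <- config$voi_params
  arms <- config$arms
  tps <- config$timepoints
  t0 <- tps[1L]
  V <- nrow(vp)
  n_tp <- length(tps)

  subjects <- purrr::pmap_dfr(arms, function(genotype, arm, n, delta,
                                             behavior_intercept,
                                             behavior_beta) {
    tibble::tibble(
      subject_id = sprintf("%s_%s_%02d", genotype, gsub("/", "", arm),
                           seq_len(n)),
      genotype = genotype, arm = arm, delta = delta,
      behavior_intercept = behavior_intercept, behavior_beta = behavior_beta
    )
  })
  n <- nrow(subjects)

  set.seed(config$seed)
  f_shared <- rnorm(n)
  h_amyloid <- rnorm(n)
  a_amp <- exp(config$amp_sigma * rnorm(n) - config$amp_sigma^2 / 2)
  g_idio <- matrix(rnorm(n * V), n, V)
  eps_tspo <- array(rnorm(n * V * n_tp), c(n, V, n_tp))
  eps_ab <- array(rnorm(n * V * n_tp), c(n, V, n_tp))
  beh_noise <- rnorm(n)

  delta <- subjects$delta
  is_ki <- as.numeric(subjects$genotype == "KI")
  mult <- unname(config$treatment_multiplier[subjects$arm])

  # log-scale latent synchronized/idiosyncratic component, n x V,
  # variance-preserving on the log scale. Desynchronization only affects
  # target VOIs: reference regions are spared by definition (which is what
  # makes them usable as references). The -loading^2/2 correction keeps the
  # multiplicative scan scale mean-one.
  delta_sv <- outer(delta, as.numeric(!vp$is_reference))
  latent <- sweep(sqrt(1 - delta_sv) * f_shared, 2, vp$loading, `*`) +
    sweep(sqrt(delta_sv) * g_idio, 2, vp$loading, `*`)
  scan_scale <- exp(sweep(latent, 2, vp$loading^2 / 2))
  ab_scale <- exp(config$ab_loading_frac * h_amyloid -
                    config$ab_loading_frac^2 / 2)

  kappa_of <- function(arm, tp) {
    k <- config$coupling$kappa[config$coupling$arm == arm &
                                 config$coupling$age_months == tp]
    if (length(k) == 0L) 0 else k[1L]
  }

  rows <- vector("list", 2L * n_tp)
  idx <- 0L
  for (ti in seq_len(n_tp)) {
    tp <- tps[ti]
    geno_eff <- (is_ki * a_amp) %o% vp$genotype_offset +
      (is_ki * a_amp * mult * (tp - t0)) %o% vp$genotype_slope
    tspo <- scan_scale *
      (matrix(vp$base_mean, n, V, byrow = TRUE) + geno_eff) +
      sweep(eps_tspo[, , ti, drop = FALSE][, , 1L], 2, vp$noise_sd, `*`)
    tspo <- pmax(tspo, 0.01)

    kappa <- vapply(subjects$arm, kappa_of, numeric(1), tp = tp)
    ab_profile <- vp$genotype_offset + vp$genotype_slope * (tp - t0)
    ab <- ab_scale *
      (matrix(vp$ab_base_mean, n, V, byrow = TRUE) +
         (is_ki * config$ab_genotype_offset) +
         (is_ki * a_amp * kappa * config$ab_gain) %o% ab_profile) +
      sweep(eps_ab[, , ti, drop = FALSE][, , 1L], 2,
            config$ab_noise_frac * vp$ab_base_mean, `*`)
    ab <- pmax(ab, 0.01)

    idx <- idx + 1L
    rows[[idx]] <- tibble::tibble(
      subject_id = rep(subjects$subject_id, V),
      genotype = rep(subjects$genotype, V),
      arm = rep(subjects$arm, V),
      age_months = tp,
      tracer = "TSPO",
      voi = rep(vp$voi, each = n),
      value = as.vector(tspo),
      unit = "PCT_ID"
    )
    idx <- idx + 1L
    rows[[idx]] <- tibble::tibble(
      subject_id = rep(subjects$subject_id, V),
      genotype = rep(subjects$genotype, V),
      arm = rep(subjects$arm, V),
      age_months = tp,
      tracer = "ABETA",
      voi = rep(vp$voi, each = n),
      value = as.vector(ab),
      unit = "PCT_ID"
    )
  }
  uptake <- dplyr::bind_rows(rows)
  if (config$wt_abeta_final_only) {
    uptake <- dplyr::filter(
      uptake,
      !(.data$genotype == "WT" & .data$tracer == "ABETA" &
          .data$age_months != tps[n_tp])
    )
  }
  uptake <- dplyr::arrange(uptake, .data$tracer, .data$age_months,
                           .data$subject_id, .data$voi)

  # cortical desynchronization proxy: what the realized DI responds to is
  # the subject's displacement from the control connectivity pattern, which
  # scales with the pathology amplitude and with the idiosyncratic (replaced)
  # component over cortical VOIs
  cortex_idx <- match(config$cortex_vois, vp$voi)
  g_rms <- sqrt(delta) * sqrt(rowMeans(g_idio[, cortex_idx, drop = FALSE]^2))
  proxy <- ifelse(is_ki == 1, a_amp * (1 + g_rms), g_rms)
  quadrant <- subjects$behavior_intercept +
    subjects$behavior_beta * proxy + config$behavior_sd * beh_noise
  behavior <- tibble::tibble(
    subject_id = subjects$subject_id,
    genotype = subjects$genotype,
    arm = subjects$arm,
    quadrant_time = pmax(quadrant, 0)
  )

  truth <- list(
    subjects = tibble::tibble(
      subject_id = subjects$subject_id,
      genotype = subjects$genotype,
      arm = subjects$arm,
      delta = delta,
      amplitude = a_amp,
      shared_factor = f_shared,
      amyloid_factor = h_amyloid,
      di_proxy = proxy
    ),
    voi_params = vp,
    config = config
  )
  structure(list(uptake = uptake, behavior = behavior, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat("  uptake rows:", nrow(x$uptake), "\n")
  cat("  subjects:   ", nrow(x$truth$subjects), "\n")
  cat("  tracers:    ", paste(unique(x$uptake$tracer), collapse = ", "), "\n")
  invisible(x)
}

#' Remove scans at random to emulate interrupted acquisition
#'
#' Drops whole scans -- (subject, tracer, timepoint) cells -- independently
#' with the per-timepoint probability given in the configuration
#' (missing completely at random). A subject is never stripped of all scans
#' at the baseline timepoint: if every baseline scan of a subject is flagged
#' for removal, its TSPO scan is retained. Reproducible under the
#' configuration seed and independent of the draws used for cohort
#' generation.
#'
#' @param cohort A `synthetic_cohort`.
#' @param config The `synth_config` holding `missing_rate` and `seed`.
#' @return The cohort with rows removed from `uptake`; the set of removed
#'   scans is recorded in `attr(cohort$uptake, "removed_scans")`.
#' @export
apply_missingness <- function(cohort, config) {
  if (!inherits(cohort, "synthetic_cohort")) {
    abort("`cohort` must be a synthetic_cohort")
  }
  rate <- config$missing_rate
  if (any(rate < 0 | rate >= 0.95)) {
    abort(paste("missing_rate must lie in [0, 0.95):",
                "baseline protection unsatisfiable at higher rates"))
  }
  tps <- config$timepoints
  slots <- dplyr::distinct(cohort$uptake,
                           .data$subject_id, .data$tracer, .data$age_months)
  slots <- dplyr::arrange(slots, .data$subject_id, .data$tracer,
                          .data$age_months)
  slot_rate <- rate[match(slots$age_months, tps)]
  set.seed(config$seed + 1L)
  drop <- runif(nrow(slots)) < slot_rate

  # baseline protection
  t0 <- tps[1L]
  base_idx <- which(slots$age_months == t0)
  if (length(base_idx)) {
    by_subj <- split(base_idx, slots$subject_id[base_idx])
    for (idx in by_subj) {
      if (all(drop[idx])) {
        keep <- idx[slots$tracer[idx] == "TSPO"][1L]
        if (is.na(keep)) keep <- idx[1L]
        drop[keep] <- FALSE
      }
    }
  }
  removed <- slots[drop, ]
  kept <- dplyr::anti_join(
    cohort$uptake, removed,
    by = c("subject_id", "tracer", "age_months")
  )
  attr(kept, "removed_scans") <- removed
  cohort$uptake <- kept
  cohort
}
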