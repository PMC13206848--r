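# Fixtures shared across test files. All data is built in code.

UPTAKE_COLS <- function() {
  c("subject_id", "genotype", "arm", "age_months", "tracer", "voi",
    "value", "unit")
}

# minimal long uptake table from a subject x VOI matrix (one tracer/timepoint)
uptake_from_matrix <- function(m, tracer = "TSPO", age = 10, unit = "SUVR",
                               genotype = "WT", arm = "PL/PL") {
  tibble::tibble(
    subject_id = rep(rownames(m), ncol(m)),
    genotype = genotype,
    arm = arm,
    age_months = age,
    tracer = tracer,
    voi = rep(colnames(m), each = nrow(m)),
    value = as.vector(m),
    unit = unit
  )
}

# subjects lying exactly on y = slope * x + intercept for every pair:
# profiles proportional to a common direction give exact pairwise lines
collinear_matrix <- function(n_subj, vois, base = 1, step = 0.5) {
  x <- base + step * seq_len(n_subj)
  m <- outer(x, seq_along(vois), function(xx, k) k * xx)
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_subj)), vois)
  m
}

# two-arm WT cohort: control arm with delta 0, test arm with delta d
two_arm_config <- function(delta_test, n_per_arm, seed, ...) {
  arms <- tibble::tribble(
    ~genotype, ~arm,    ~n,         ~delta,     ~behavior_intercept, ~behavior_beta,
    "WT",      "PL/PL", n_per_arm,  0,          30,                  0,
    "WT",      "Ab/PL", n_per_arm,  delta_test, 30,                  0
  )
  synth_config(arms = arms, seed = seed, ...)
}

# mean cortical DI per subject for a cohort generated from two_arm_config
cortical_di_by_arm <- function(cfg, B = 200, timepoint = 10) {
  atlas <- default_atlas()
  cohort <- generate_cohort(cfg)
  suvr <- compute_suvr(
    dplyr::filter(cohort$uptake, tracer == "TSPO"), "brainstem"
  )
  controls <- unique(suvr$subject_id[suvr$arm == "PL/PL"])
  fits <- bootstrap_pair_fits(suvr, controls, B = B, seed = cfg$seed,
                              timepoint = timepoint,
                              vois = atlas$target_vois)
  di <- compute_di(suvr, fits, timepoint = timepoint)
  di <- dplyr::filter(di, voi %in% atlas$composites$cortex)
  out <- dplyr::summarise(dplyr::group_by(di, subject_id),
                          di = mean(di), .groups = "drop")
  out$test_arm <- grepl("AbPL", out$subject_id)
  out
}
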