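test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- synth_config(seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$uptake, b$uptake)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$truth$subjects, b$truth$subjects)
  # missingness is reproducible and independent of generation draws
  cfg_m <- synth_config(seed = 11L, missing_rate = c(0, 0.3, 0.1))
  expect_identical(apply_missingness(a, cfg_m)$uptake,
                   apply_missingness(b, cfg_m)$uptake)
})

test_that("a fully synchronized noise-free cohort is rank one", {
  vp <- default_voi_params()
  vp$noise_sd <- 0
  arms <- tibble::tibble(genotype = "WT", arm = "PL/PL", n = 12L,
                         delta = 0, behavior_intercept = 30,
                         behavior_beta = 0)
  cfg <- synth_config(arms = arms, voi_params = vp, seed = 5L)
  cohort <- generate_cohort(cfg)
  m <- tidyr::pivot_wider(
    dplyr::filter(cohort$uptake, tracer == "TSPO", age_months == 10)[
      c("subject_id", "voi", "value")],
    names_from = "voi", values_from = "value"
  )
  r <- cor(as.matrix(m[-1]))
  expect_true(all(r[upper.tri(r)] > 0.999))
})

test_that("empirical cell means recover the generative means", {
  arms <- tibble::tibble(
    genotype = c("WT", "KI"), arm = c("PL/PL", "PL/PL"), n = c(60L, 60L),
    delta = c(0, 0.5), behavior_intercept = c(30, 21), behavior_beta = c(0, 0)
  )
  cfg <- synth_config(arms = arms, seed = 42L)
  cohort <- generate_cohort(cfg)
  vp <- cfg$voi_params
  tspo <- dplyr::filter(cohort$uptake, tracer == "TSPO")
  cells <- dplyr::summarise(
    dplyr::group_by(tspo, genotype, age_months, voi),
    m = mean(value), s = sd(value), n = dplyr::n(), .groups = "drop"
  )
  i <- match(cells$voi, vp$voi)
  expected <- vp$base_mean[i] +
    (cells$genotype == "KI") *
      (vp$genotype_offset[i] + vp$genotype_slope[i] * (cells$age_months - 5))
  z <- abs(cells$m - expected) / (cells$s / sqrt(cells$n))
  expect_gte(mean(z <= 3), 0.97)
  expect_true(all(z <= 5))
})

test_that("missingness is MCAR at the configured rate with baseline protection", {
  arms <- tibble::tibble(genotype = "WT", arm = "PL/PL", n = 200L,
                         delta = 0, behavior_intercept = 30,
                         behavior_beta = 0)
  cfg0 <- synth_config(arms = arms, seed = 1L, missing_rate = c(0, 0, 0))
  cohort <- generate_cohort(cfg0)
  expect_equal(apply_missingness(cohort, cfg0)$uptake, cohort$uptake,
               ignore_attr = TRUE)

  # 200 subjects x 1 tracer x 2 later timepoints at rate 0.5 (WT amyloid is
  # final-only, giving 200 extra slots at 10 months): count retained scans
  cfg5 <- synth_config(arms = arms, seed = 1L, missing_rate = c(0, 0.5, 0.5))
  kept <- apply_missingness(cohort, cfg5)$uptake
  slots <- dplyr::distinct(kept, subject_id, tracer, age_months)
  n_late <- sum(slots$age_months > 5)
  n_total <- 200 * 2 + 200  # TSPO at 7.5 and 10 plus ABETA at 10
  # binomial 99% interval around 0.5
  expect_gt(n_late, qbinom(0.005, n_total, 0.5))
  expect_lt(n_late, qbinom(0.995, n_total, 0.5))

  # every subject keeps at least one baseline scan even at a high rate
  cfg9 <- synth_config(arms = arms, seed = 2L, missing_rate = c(0.9, 0.9, 0.9))
  kept9 <- apply_missingness(cohort, cfg9)$uptake
  base_subj <- unique(kept9$subject_id[kept9$age_months == 5])
  expect_setequal(base_subj, unique(cohort$uptake$subject_id))

  expect_error(synth_config(arms = arms, missing_rate = c(0, 0, 0.99)),
               "baseline protection")
})

test_that("configuration invariants are enforced", {
  vp <- default_voi_params()
  vp$base_mean[3] <- -1
  expect_error(synth_config(voi_params = vp), "base_mean")
  arms <- default_arms()
  arms$arm[1] <- "nope"
  expect_error(synth_config(arms = arms), "unknown arm")
  vp2 <- default_voi_params()
  vp2$voi[2] <- vp2$voi[1]
  expect_error(synth_config(voi_params = vp2), "duplicate VOI")
  expect_error(synth_config(timepoints = c(5, 5, 10)), "strictly increasing")
  arms3 <- default_arms()
  arms3$delta[1] <- 1.2
  expect_error(synth_config(arms = arms3), "delta")
})
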