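make_pctid <- function(values_by_subject, vois, genotype, arm = "PL/PL",
                       age = 10, tracer = "TSPO") {
  purrr::imap_dfr(values_by_subject, function(vals, sid) {
    tibble::tibble(
      subject_id = sid, genotype = genotype[[sid]], arm = arm,
      age_months = age, tracer = tracer, voi = vois, value = vals,
      unit = "PCT_ID"
    )
  })
}

test_that("percent injected dose is concentration over dose times 100", {
  x <- tibble::tibble(
    subject_id = "s1", genotype = "WT", arm = "PL/PL", age_months = 10,
    tracer = "TSPO", voi = c("a", "b"), concentration = c(0.8, 0)
  )
  out <- compute_percent_id(x, injected_dose = 80)
  expect_equal(out$value, c(1.0, 0))
  expect_equal(unique(out$unit), "PCT_ID")
  expect_error(compute_percent_id(x, injected_dose = 0), "> 0")
  expect_error(compute_percent_id(x, injected_dose = -5), "> 0")
  x$concentration[1] <- -1
  expect_error(compute_percent_id(x, 80), ">= 0")
  # per-scan dose table
  x$concentration[1] <- 0.8
  dose <- tibble::tibble(subject_id = "s1", tracer = "TSPO", age_months = 10,
                         injected_dose = 40)
  expect_equal(compute_percent_id(x, dose)$value, c(2.0, 0))
})

test_that("cohen_d matches its pooled-SD definition and invariances", {
  expect_equal(cohen_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohen_d(c(2, 4), c(0, 2)), sqrt(2), tolerance = 1e-10)
  expect_error(cohen_d(c(5, 5, 5), c(5, 5, 5)), "pooled variance")
  expect_error(cohen_d(1, c(1, 2)), "at least 2")
  set.seed(1)
  a <- rnorm(9); b <- rnorm(7, 1)
  expect_equal(cohen_d(a, b), -cohen_d(b, a))
  expect_equal(cohen_d(a + 5, b + 5), cohen_d(a, b))
  expect_equal(cohen_d(3 * a, 3 * b), cohen_d(a, b))
})

test_that("pseudo-reference selection minimizes |d| with lexicographic ties", {
  vois <- c("b_voi", "a_voi", "c_voi")
  geno <- c(w1 = "WT", w2 = "WT", w3 = "WT", k1 = "KI", k2 = "KI", k3 = "KI")
  # identical distributions in every VOI -> all d = 0 -> first name wins
  vals <- list(w1 = c(1, 4, 7), w2 = c(2, 5, 8), w3 = c(3, 6, 9),
               k1 = c(1, 4, 7), k2 = c(2, 5, 8), k3 = c(3, 6, 9))
  x <- make_pctid(vals, vois, geno)
  rep0 <- select_pseudo_reference(x)
  expect_equal(rep0$report$d, rep(0, 3))
  expect_equal(rep0$selected_reference, "a_voi")

  # singleton candidate list wins regardless of d
  rep1 <- select_pseudo_reference(x, candidates = "c_voi")
  expect_equal(rep1$selected_reference, "c_voi")

  expect_error(select_pseudo_reference(x, candidates = "missing_voi"),
               "absent")
  x_wt <- x[x$genotype == "WT", ]
  expect_error(select_pseudo_reference(x_wt), "genotype KI")
})

test_that("SUVR scaling is per scan, maps the reference to 1, and reports exclusions", {
  geno <- c(s1 = "WT", s2 = "WT")
  x <- make_pctid(list(s1 = c(2.0, 0.5, 0.5), s2 = c(3, 3, 3)),
                  c("a", "b", "ref"), geno)
  out <- compute_suvr(x, "ref")
  expect_equal(out$value[out$subject_id == "s1"], c(4, 1, 1))
  expect_equal(out$value[out$subject_id == "s2"], c(1, 1, 1))
  expect_equal(unique(out$unit), "SUVR")

  # scale invariance: scaling one scan leaves its SUVR unchanged
  x2 <- x
  x2$value[x2$subject_id == "s1"] <- x2$value[x2$subject_id == "s1"] * 7
  expect_equal(compute_suvr(x2, "ref")$value, out$value)

  # a scan without the reference row is excluded and reported
  x3 <- x[!(x$subject_id == "s2" & x$voi == "ref"), ]
  out3 <- compute_suvr(x3, "ref")
  excl <- attr(out3, "excluded_scans")
  expect_equal(excl$subject_id, "s2")
  expect_match(excl$reason, "missing")
  expect_equal(sort(unique(out3$subject_id)), "s1")
})

test_that("z-scores standardize against the control cohort at the reference timepoint", {
  geno <- c(c1 = "WT", c2 = "WT", c3 = "WT", c4 = "WT", p1 = "KI")
  vals <- list(c1 = c(1, 10), c2 = c(2, 20), c3 = c(3, 30), c4 = c(4, 40),
               p1 = c(4, 25))
  x <- make_pctid(vals, c("a", "b"), geno)
  x$unit <- "SUVR"
  z <- compute_zscores(x, control_subjects = c("c1", "c2", "c3", "c4"))
  # frozen from the closed-form (4 - 2.5) / sd(1:4)
  expect_equal(z$value[z$subject_id == "p1" & z$voi == "a"], 1.161895,
               tolerance = 1e-6)
  expect_equal(z$value[z$subject_id == "p1" & z$voi == "b"], 0)
  ctrl_z <- z[z$subject_id != "p1", ]
  stats <- dplyr::summarise(dplyr::group_by(ctrl_z, voi),
                            m = mean(value), s = sd(value))
  expect_equal(stats$m, c(0, 0), tolerance = 1e-12)
  expect_equal(stats$s, c(1, 1), tolerance = 1e-12)

  x_const <- x
  x_const$value[x_const$voi == "a" & x_const$genotype == "WT"] <- 2
  expect_error(compute_zscores(x_const, c("c1", "c2", "c3", "c4")),
               "zero control SD")
  expect_error(compute_zscores(x, c("c1", "c2", "c3", "ghost")), "absent")
  expect_error(compute_zscores(x, c("c1", "c2")), ">= 3 control")
})

test_that("VOI means are label-wise voxel averages", {
  img <- array(2, dim = c(2, 2, 2))
  lab <- array(0L, dim = c(2, 2, 2))
  lab[1, 1, 1] <- 1L
  lab[2, 1, 1] <- 1L
  lab[1, 2, 1] <- 2L
  out <- extract_voi_means(img, lab, c(roi_a = 1L, roi_b = 2L))
  expect_equal(out$value, c(2, 2))
  expect_equal(out$n_voxels, c(2L, 1L))

  img[1, 1, 1] <- 1; img[2, 1, 1] <- 3
  out2 <- extract_voi_means(img, lab, c(roi_a = 1L))
  expect_equal(out2$value, 2)

  expect_error(extract_voi_means(img, lab, c(ghost = 9L)), "ghost")
  expect_error(extract_voi_means(array(0, c(2, 2, 1)), lab, c(roi_a = 1L)),
               "shape")
})
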