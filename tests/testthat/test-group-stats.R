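test_that("shapiro gate flags gross non-normality and keeps nominal size", {
  set.seed(1)
  two_atoms <- sample(c(0, 1), 50, replace = TRUE) +
    rnorm(50, 0, 1e-6)  # two tight atoms
  expect_equal(shapiro_gate(two_atoms), "non_normal")
  const <- shapiro_gate(rep(3, 10))
  expect_equal(as.character(const), "non_normal")
  expect_true(attr(const, "constant"))
  expect_error(shapiro_gate(c(1, 2)), "n >= 3")
  # size: fraction gated "normal" for true normals stays in the binomial
  # 99% band around 1 - alpha
  set.seed(2024)
  gated <- replicate(100, shapiro_gate(rnorm(5000)) == "normal")
  expect_gte(sum(gated), qbinom(0.005, 100, 0.95))
})

test_that("Mann-Whitney U uses exact enumeration for small untied samples", {
  res <- mwu_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)  # 2 / C(6, 3) one-sided tails doubled
  expect_equal(res$method, "exact")
  res_sym <- mwu_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res_sym$p_value, 1)
  expect_error(mwu_test(1, numeric(0)), "non-empty")

  # exact and approximate branches agree closely at n = 8 per group
  set.seed(42)
  a <- round(rnorm(8), 3) * 10
  b <- round(rnorm(8), 3) * 10 + 2
  p_exact <- mwu_test(a, b)$p_value
  p_approx <- suppressWarnings(
    wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  )
  expect_lt(abs(p_exact - p_approx), 0.02)
})

test_that("Kruskal-Wallis equals the brute-force rank formula", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- kruskal_wallis(groups)
  # independent oracle: H = 12 / (N (N + 1)) * sum n_i (Rbar_i - Rbar)^2
  ranks <- rank(unlist(groups))
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(ranks, idx, mean)
  n_tot <- length(ranks)
  h_oracle <- 12 / (n_tot * (n_tot + 1)) *
    sum(lengths(groups) * (rbar - mean(ranks))^2)
  expect_equal(res$statistic, h_oracle, tolerance = 1e-12)
  expect_equal(res$df, 2)
  # permuting group order leaves H unchanged
  expect_equal(kruskal_wallis(groups[c(3, 1, 2)])$statistic, res$statistic)
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2))), "identical")
  expect_error(kruskal_wallis(list(c(1, 2))), ">= 2 groups")
})

test_that("Kruskal-Wallis at k = 2 equals the squared MWU normal deviate", {
  set.seed(9)
  x <- rnorm(7); y <- rnorm(9) + 0.5
  h <- kruskal_wallis(list(x, y))$statistic
  u <- unname(wilcox.test(x, y, exact = FALSE, correct = FALSE)$statistic)
  z <- (u - 7 * 9 / 2) / sqrt(7 * 9 * (7 + 9 + 1) / 12)
  expect_equal(h, z^2, tolerance = 1e-10)
})

test_that("BH adjustment is the step-up procedure and order-preserving", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  # independent oracle: literal step-up evaluation
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(fdr_adjust(p), rep(0.05, 5))
  expect_equal(fdr_adjust(p), bh_oracle(p))
  set.seed(3)
  q <- runif(20)
  expect_equal(fdr_adjust(q), bh_oracle(q))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 4)), rep(1, 4))
  expect_true(all(fdr_adjust(q) >= q))
  ord <- order(q)
  expect_true(!is.unsorted(fdr_adjust(q)[ord]))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("baseline-change regression matches closed-form OLS on percent change", {
  df <- tibble::tibble(baseline = c(1, 2, 4), followup = c(2, 3, 5))
  res <- baseline_change_regression(df, baseline, followup)
  # frozen from lm() on responses (100, 50, 25): slope -975/42
  expect_equal(res$slope, -975 / 42, tolerance = 1e-10)
  expect_equal(res$r_squared, 0.8622449, tolerance = 1e-6)
  expect_false(res$degenerate)

  # proportional follow-up: constant change, degenerate
  df2 <- tibble::tibble(baseline = c(1, 2, 4), followup = c(1.1, 2.2, 4.4))
  res2 <- baseline_change_regression(df2, baseline, followup)
  expect_true(res2$degenerate)
  expect_equal(res2$slope, 0)

  df3 <- tibble::tibble(baseline = c(1, 2, 4, 3), followup = c(2, 3, 5, NA))
  res3 <- baseline_change_regression(df3, baseline, followup)
  expect_equal(res3$n, 3)
  expect_equal(res3$n_excluded, 1)
  expect_error(baseline_change_regression(
    tibble::tibble(baseline = c(0, 1, 2), followup = c(1, 2, 3)),
    baseline, followup
  ), "> 0")
})

test_that("pooled regional coupling is OLS over matched subject-region points", {
  z <- tidyr::expand_grid(subject_id = c("s1", "s2", "s3"),
                          voi = c("a", "b", "c"))
  z$genotype <- "KI"; z$arm <- "PL/PL"; z$age_months <- 10
  z$tracer <- "TSPO"; z$unit <- "ZSCORE"
  set.seed(5)
  z$value <- rnorm(nrow(z))
  za <- z; za$tracer <- "ABETA"
  # exact-fit fixture: lm warns that the fit is perfect, which is the point
  res <- suppressWarnings(regional_coupling(z[UPTAKE_COLS()],
                                            za[UPTAKE_COLS()]))
  expect_equal(res$r_squared, 1)
  expect_equal(res$slope, 1)
  expect_match(res$note, "descriptive")

  za2 <- za; za2$value <- 0.5
  res2 <- regional_coupling(z[UPTAKE_COLS()], za2[UPTAKE_COLS()])
  expect_true(res2$degenerate)
})

test_that("behavior correlation is stratified with degenerate and skip handling", {
  beh <- tibble::tibble(
    subject_id = sprintf("s%d", 1:8),
    genotype = "KI",
    arm = rep(c("Ab/PL", "PL/Pio"), c(6, 2)),
    quadrant_time = 0
  )
  metric <- tibble::tibble(subject_id = sprintf("s%d", 1:8),
                           metric = c(1, 2, 3, 4, 5, 6, 1, 2))
  beh$quadrant_time <- ifelse(beh$arm == "Ab/PL", 10 - metric$metric, 5)
  res <- suppressWarnings(behavior_correlation(metric, beh))
  ab <- res[res$arm == "Ab/PL", ]
  expect_equal(ab$r_squared, 1)
  expect_lt(ab$slope, 0)
  skipped <- attr(res, "skipped_strata")
  expect_equal(skipped$arm, "PL/Pio")
  expect_equal(skipped$n, 2L)

  beh$arm <- "Ab/PL"
  metric$metric <- 1
  res2 <- behavior_correlation(metric, beh)
  expect_true(res2$degenerate)
})
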