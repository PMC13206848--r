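test_that("perpendicular distance satisfies its geometric identities", {
  expect_equal(perpendicular_distance(3, 3, 1, 0), 0)
  expect_equal(perpendicular_distance(0, 1, 1, 0), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(perpendicular_distance(2, 5, 0, 3), 2)
  expect_error(perpendicular_distance(Inf, 0, 1, 0), "finite")
  expect_error(perpendicular_distance(1, NA, 1, 0), "finite")
})

# exact-line ensemble over arbitrary profiles: pairwise fits of collinear
# control subjects are exact, so distances have closed form
exact_fit_setup <- function(n_vois = 4) {
  vois <- sprintf("v%d", seq_len(n_vois))
  m <- collinear_matrix(6, vois)
  ctrl <- uptake_from_matrix(m)
  fits <- bootstrap_pair_fits(ctrl, rownames(m), B = 20, seed = 1,
                              timepoint = 10)
  list(vois = vois, ctrl = ctrl, fits = fits)
}

test_that("a subject on every consensus line has DI zero in all VOIs", {
  s <- exact_fit_setup()
  probe <- matrix(seq_along(s$vois) * 2.7, nrow = 1,
                  dimnames = list("probe", s$vois))
  di <- compute_di(uptake_from_matrix(probe), s$fits, timepoint = 10)
  expect_equal(di$di, rep(0, length(s$vois)), tolerance = 1e-9)
  expect_equal(di$di_norm, di$di / (length(s$vois) - 1))
})

test_that("perturbing one VOI spreads single-pair distances per the summation rule", {
  s <- exact_fit_setup(5)
  base <- seq_along(s$vois) * 2
  probe <- matrix(base, nrow = 1, dimnames = list("probe", s$vois))
  k <- 3L
  probe[1, k] <- probe[1, k] + 1  # off-line only in pairs involving v3
  di <- compute_di(uptake_from_matrix(probe), s$fits, timepoint = 10)
  pairs <- s$fits$pairs
  d_pair <- perpendicular_distance(probe[1, pairs$i], probe[1, pairs$j],
                                   pairs$slope, pairs$intercept)
  involved <- pairs$i == k | pairs$j == k
  expect_true(all(d_pair[involved] > 0))
  expect_equal(max(d_pair[!involved]), 0, tolerance = 1e-9)
  # DI of a non-perturbed VOI equals its single pair distance to v3
  for (v in seq_along(s$vois)[-k]) {
    expect_equal(di$di[di$voi == s$vois[v]],
                 sum(d_pair[(pairs$i == v & pairs$j == k) |
                              (pairs$i == k & pairs$j == v)]),
                 tolerance = 1e-9)
  }
  expect_equal(di$di[di$voi == s$vois[k]], sum(d_pair[involved]),
               tolerance = 1e-9)
  expect_equal(sum(di$di), 2 * sum(d_pair), tolerance = 1e-9)
})

test_that("subjects with incomplete profiles are skipped and reported", {
  s <- exact_fit_setup()
  probe <- matrix(rep(1:2, each = length(s$vois)), nrow = 2, byrow = TRUE,
                  dimnames = list(c("ok", "gappy"), s$vois))
  x <- uptake_from_matrix(probe)
  x <- x[!(x$subject_id == "gappy" & x$voi == "v2"), ]
  di <- compute_di(x, s$fits, timepoint = 10)
  expect_equal(unique(di$subject_id), "ok")
  expect_equal(attr(di, "skipped_subjects"), "gappy")
})

test_that("PC1 composites standardize, orient, and report explained variance", {
  di <- tibble::tibble(
    subject_id = rep(c("s1", "s2", "s3"), each = 2),
    voi = rep(c("a", "b"), 3),
    di = c(0, 0, 1, 2, 2, 4)
  )
  pc <- composite_pc1(di, c("a", "b"), name = "toy")
  expect_equal(pc$explained_variance, 1)
  scores <- pc$scores$score
  expect_true(scores[1] < scores[2] && scores[2] < scores[3])
  expect_equal(scores[2], 0, tolerance = 1e-12)
  # orientation: positively correlated with the mean constituent DI
  expect_gt(cor(scores, c(0, 1.5, 3)), 0.99)

  # single constituent: standardized DI, explained variance 1
  pc1 <- composite_pc1(di, "b", name = "single")
  expect_equal(pc1$explained_variance, 1)
  expect_equal(pc1$scores$score, as.vector(scale(c(0, 2, 4))),
               tolerance = 1e-12)

  di_const <- di
  di_const$di[di_const$voi == "a"] <- 1
  expect_error(composite_pc1(di_const, c("a", "b")), "zero-variance")
  expect_error(composite_pc1(di[di$subject_id != "s3", ], c("a", "b")),
               ">= 3 subjects")
})

test_that("replicate-averaged distances match consensus on exact ensembles", {
  s <- exact_fit_setup()
  probe <- matrix(c(1, 3, 5, 9), nrow = 1,
                  dimnames = list("probe", s$vois))
  x <- uptake_from_matrix(probe)
  di_cons <- compute_di(x, s$fits, timepoint = 10, method = "consensus")
  di_repl <- compute_di(x, s$fits, timepoint = 10, method = "replicate")
  expect_equal(di_repl$di, di_cons$di, tolerance = 1e-9)
})
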