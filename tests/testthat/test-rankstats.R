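test_that("ranking distance matches hand evaluation and a brute-force oracle", {
  expect_equal(ranking_distance(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(ranking_distance(c(1, 2), c(2, 1)), 2 * log(2))
  # brute-force oracle builds f_Y by linear search
  rd_brute <- function(x, y) {
    d <- 0
    for (i in seq_along(x)) {
      fy <- which(y == x[i])
      d <- d + abs(log(i / fy))
    }
    d
  }
  set.seed(1)
  for (r in 1:50) {
    x <- sample(5); y <- sample(5)
    expect_equal(ranking_distance(x, y), rd_brute(x, y), tolerance = 1e-12)
  }
  expect_error(ranking_distance(c(1, 2, 2), c(1, 2, 3)), "duplicated: 2")
  expect_error(ranking_distance(c(1, 2, 4), c(1, 2, 3)), "missing: 3")
})

test_that("ranking distance satisfies the metric axioms exactly", {
  set.seed(2)
  n <- 9
  for (r in 1:1000) {
    x <- sample(n); y <- sample(n)
    d <- ranking_distance(x, y)
    expect_gte(d, 0)
    expect_identical(d == 0, identical(x, y))
    expect_equal(d, ranking_distance(y, x), tolerance = 1e-12)
  }
  for (r in 1:1000) {
    x <- sample(n); y <- sample(n); z <- sample(n)
    expect_lte(ranking_distance(x, z),
               ranking_distance(x, y) + ranking_distance(y, z) + 1e-12)
  }
})

test_that("the null of the permutation test matches one-sided sampling with fixed X", {
  # D(X, Y) for fixed X and uniform Y has the same law as for both uniform
  set.seed(3)
  n <- 10
  fixed_null <- replicate(5000, ranking_distance(seq_len(n), sample(n)))
  both <- rd_permutation_test(0, n, n_samples = 5000, seed = 4)
  withr::with_seed(4, {
    null2 <- texsparse:::rd_null_sample_cpp(n, 5000)
  })
  ks <- suppressWarnings(ks.test(fixed_null, null2))
  expect_gt(ks$p.value, 0.01)
})

test_that("the permutation test is exact at zero, monotone, and matches enumeration", {
  expect_equal(rd_permutation_test(0, 6, n_samples = 1e4, seed = 1)$p, 0)

  obs <- c(1, 2, 4, 8, 12)
  ps <- vapply(obs, function(o)
    rd_permutation_test(o, 8, n_samples = 2e4, seed = 9)$p, 0)
  expect_true(all(diff(ps) >= 0))

  # exhaustive enumeration oracle for n = 3, 4, 5, evaluated between the
  # atoms of the discrete distribution so strict comparisons are stable
  for (n in 3:5) {
    perms <- all_perms(n)
    dists <- c()
    for (x in perms) for (y in perms) {
      dists <- c(dists, ranking_distance(x, y))
    }
    us <- sort(unique(round(dists, 9)))
    mids <- (us[-length(us)] + us[-1]) / 2
    for (o in mids[unique(pmax(1, round(c(0.25, 0.6) * length(mids))))]) {
      exact <- mean(dists < o)
      mc <- rd_permutation_test(o, n, n_samples = 4e4, seed = 20 + n)
      expect_lt(abs(mc$p - exact),
                3 * sqrt(exact * (1 - exact) / 4e4) + 1e-9)
    }
  }
})

test_that("families are ranked by decreasing PMI with index tie-breaks", {
  expect_identical(rank_families_by_pmi(c(0.3, 0.5, 0.1)), c(2L, 1L, 3L))
  expect_identical(rank_families_by_pmi(rep(0.2, 4)), 1:4)
  expect_identical(rank_families_by_pmi(c(0.1, 0.2, 0.3)), 3:1)
  expect_error(rank_families_by_pmi(c(0.1, NA)), "undefined")
})

test_that("the random sampling t-test is calibrated and powered", {
  # A single RST call concentrates around the realized group difference, so
  # calibration is a statement about the null ensemble: average the RST
  # p-value over independent data draws.
  set.seed(5)
  null_p <- mean(vapply(1:200, function(r) {
    a <- rnorm(200); b <- rnorm(200)
    random_sampling_ttest(a, b, n_sample = 100, reps = 10, seed = r)$p
  }, 0))
  expect_lt(abs(null_p - 0.5), 0.05)
  a <- rnorm(400); b <- rnorm(400)

  shifted <- rnorm(400, mean = 2)
  pow_p <- random_sampling_ttest(shifted, b, n_sample = 100, reps = 100,
                                 seed = 7)$p
  expect_lt(pow_p, 0.01)

  # reps = 1 reproduces a single directly computed t-test
  one <- random_sampling_ttest(a, b, n_sample = 50, reps = 1, seed = 8)
  direct <- withr::with_seed(8, {
    aa <- sample(a, 50); bb <- sample(b, 50)
    t.test(aa, bb, alternative = "greater")$p.value
  })
  expect_equal(one$p, direct)

  expect_warning(random_sampling_ttest(rnorm(30), rnorm(300), n_sample = 100,
                                       reps = 5, seed = 1), "reduced")
  expect_error(random_sampling_ttest(numeric(0)), "empty")

  one_sample <- random_sampling_ttest(rnorm(300, 1), "zero", n_sample = 100,
                                      reps = 50, seed = 2)$p
  expect_lt(one_sample, 0.01)
})

test_that("the per-unit randomization test behaves at the extremes", {
  set.seed(9)
  # identical CM and SM responses: observed index 0. The within-pair swap
  # null is degenerate at 0 (every per-pair difference is zero), so the
  # symmetric-null behaviour (p near 1/2) is shown by the global-relabel
  # variant, which mixes different stimuli into the null pairs.
  v <- rexp(24)
  R <- response_matrix(cbind(matrix(v, 1), matrix(v, 1)),
                       data.frame(pair_id = 1:24, cm_col = 1:24,
                                  sm_col = 25:48, family_id = 1L))
  swap <- unit_randomization_test(R, n_perm = 500, seed = 1)
  expect_equal(swap$observed, 0)
  expect_equal(swap$p, 0)  # nothing in the degenerate null exceeds 0
  out <- unit_randomization_test(R, n_perm = 4000, seed = 1, global = TRUE)
  expect_equal(out$observed, 0)
  expect_lt(abs(out$p - 0.5), 0.05)

  # responds to CM only: observed 1, nothing in the null exceeds it
  cm <- matrix(rexp(20), 1); sm <- matrix(0, 1, 20)
  R2 <- response_matrix(cbind(cm, sm),
                        data.frame(pair_id = 1:20, cm_col = 1:20,
                                   sm_col = 21:40, family_id = 1L))
  out2 <- unit_randomization_test(R2, n_perm = 2000, seed = 2)
  expect_equal(out2$observed, 1)
  expect_lte(out2$p, 1 / 2000)
  expect_true(out2$significant)

  # unit with no valid pairs is skipped and counted
  R3 <- response_matrix(matrix(0, 2, 4),
                        data.frame(pair_id = 1:2, cm_col = 1:2,
                                   sm_col = 3:4, family_id = 1L))
  out3 <- unit_randomization_test(R3, n_perm = 100, seed = 3)
  expect_identical(attr(out3, "n_skipped"), 2L)
  expect_true(all(is.na(out3$p)))
})

test_that("the global-relabel variant agrees with the swap variant under exchangeability", {
  set.seed(10)
  cm <- matrix(rexp(6 * 12), 6, 12); sm <- matrix(rexp(6 * 12), 6, 12)
  R <- response_matrix(cbind(cm, sm),
                       data.frame(pair_id = 1:12, cm_col = 1:12,
                                  sm_col = 13:24, family_id = 1L))
  a <- unit_randomization_test(R, n_perm = 1500, seed = 4)
  b <- unit_randomization_test(R, n_perm = 1500, seed = 4, global = TRUE)
  expect_equal(a$observed, b$observed)
  expect_lt(max(abs(a$p - b$p)), 0.12)
})
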