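test_that("signed sqrt and z-scoring behave as specified", {
  # hand-evaluated: [4, -4] -> [2, -2] -> z-scores of +/- 1 (sd uses n-1)
  tr <- signed_sqrt_zscore(cbind(a = c(4, -4), b = c(1, 2)))
  expect_equal(unname(tr$x[, "a"]),
               c(2, -2) / sd(c(2, -2)), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(tr$x))), 1e-10)
  expect_lt(max(abs(apply(tr$x, 2, sd) - 1)), 1e-10)

  tr2 <- signed_sqrt_zscore(cbind(z = c(0, 0, 0), k = c(1, 2, 3)))
  expect_identical(unname(tr2$record$dropped), 1L)
  expect_identical(colnames(tr2$x), "k")

  # z-scoring an already standardized column leaves it standardized
  x <- rnorm(20); x <- (x - mean(x)) / sd(x)
  tr3 <- signed_sqrt_zscore(matrix(x^2 * sign(x), ncol = 1))  # sqrt undoes ^2
  expect_equal(unname(tr3$x[, 1]), x, tolerance = 1e-10)

  expect_error(signed_sqrt_zscore(matrix(1, 1, 3)), "2 rows")
})

test_that("groupwise PCA keeps the smallest component set past the threshold", {
  set.seed(5)
  # rank-1 group: all columns proportional
  base <- rnorm(30)
  z1 <- cbind(base, 2 * base, -base)
  z1 <- sweep(sweep(z1, 2, colMeans(z1)), 2, apply(z1, 2, sd), "/")
  d <- groupwise_pca(z1, rep("g1", 3), 0.9)
  expect_identical(unname(d$n_components["g1"]), 1L)
  expect_equal(unname(d$variance_retained["g1"]), 1, tolerance = 1e-10)

  # identity-covariance group of k columns: about ceil(0.9 k) components
  k <- 10
  counts <- vapply(1:20, function(s) {
    set.seed(s)
    z <- matrix(rnorm(200 * k), 200, k)
    z <- sweep(sweep(z, 2, colMeans(z)), 2, apply(z, 2, sd), "/")
    groupwise_pca(z, rep("g", k), 0.9)$n_components[["g"]]
  }, 1L)
  expect_true(all(abs(counts - ceiling(0.9 * k)) <= 1))

  expect_error(groupwise_pca(z1, rep("g", 3), 1.2), "var_threshold")
})

test_that("the modulation regression is exact where it must be", {
  set.seed(6)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- X[, 2]
  fit <- fit_pmi_regression(X, y)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # 2 points, 1 column: exact interpolation
  fit2 <- fit_pmi_regression(matrix(c(0, 1), 2, 1), c(3, 5))
  expect_equal(unname(fit2$fitted), c(3, 5), tolerance = 1e-10)
  expect_error(fit_pmi_regression(cbind(X, X[, 1]), y), "aliased|deficien")
})

test_that("null R-squared matches its expectation p/(n-1)", {
  set.seed(7)
  n <- 60; p <- 5
  r2 <- replicate(200, {
    fit_pmi_regression(matrix(rnorm(n * p), n, p), rnorm(n))$r_squared
  })
  expect_lt(abs(mean(r2) - p / (n - 1)), 0.01)
})

test_that("LMG contributions match the explicit all-orderings average", {
  set.seed(8)
  n <- 50
  X <- matrix(rnorm(n * 6), n, 6)
  y <- X %*% rnorm(6) + rnorm(n)
  spans <- list(g1 = 1:2, g2 = 3:4, g3 = 5:6)
  out <- lmg_contributions(X, y, group_spans = spans)

  # brute-force oracle: enumerate all 3! orderings explicitly
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  }
  G <- 3L
  oracle <- numeric(G)
  for (ord in all_perms(G)) {
    sofar <- integer(0)
    for (g in ord) {
      inc <- r2_of(unlist(spans[c(sofar, g)])) - r2_of(unlist(spans[sofar]))
      oracle[g] <- oracle[g] + inc / factorial(G)
      sofar <- c(sofar, g)
    }
  }
  expect_equal(out$contribution, oracle, tolerance = 1e-10)
  expect_equal(sum(out$contribution), r2_of(1:6), tolerance = 1e-8)
  expect_equal(sum(out$percent), 100, tolerance = 1e-6)
})

test_that("LMG is permutation-invariant in the group order and handles edge cases", {
  set.seed(9)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  spans <- list(a = 1:2, b = 3:4, c = 5:6)
  o1 <- lmg_contributions(X, y, group_spans = spans)
  o2 <- lmg_contributions(X, y, group_spans = spans[c(3, 1, 2)])
  expect_equal(o1$contribution[match(o2$group, o1$group)], o2$contribution,
               tolerance = 1e-8)

  # a single group owns 100 percent
  one <- lmg_contributions(X[, 1:2], y, group_spans = list(g = 1:2))
  expect_equal(one$percent, 100, tolerance = 1e-8)

  # orthogonal groups (also orthogonal to the intercept): contribution
  # equals each group's own marginal R^2
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 4), 40, 4))))[, 2:5]
  yy <- Q %*% c(2, 1, 0.5, 0.2) + rnorm(40, sd = 0.1)
  sp <- list(g1 = 1:2, g2 = 3:4)
  oo <- lmg_contributions(Q, yy, group_spans = sp)
  marg <- vapply(sp, function(ix)
    summary(lm(yy ~ Q[, ix]))$r.squared, 0)
  expect_equal(oo$contribution, unname(marg), tolerance = 1e-8)

  expect_error(lmg_contributions(X, y,
                                 group_spans = as.list(setNames(1:13, paste0("g", 1:13)))),
               "12")
})

test_that("CM-vs-SM group correlations are 1 on a self-paired corpus and small on noise", {
  corpus <- tiny_corpus()
  self <- corpus
  for (k in seq_along(self$pairs)) self$pairs[[k]]$sm <- self$pairs[[k]]$cm
  res <- group_correlation_cm_sm(self, tiny_bank())
  expect_true(all(abs(res$table$r) > 1 - 1e-8))

  noise <- noise_pair_corpus()
  resn <- group_correlation_cm_sm(noise, tiny_bank())
  expect_lt(mean(abs(resn$table$r)), 0.3)

  expect_error(group_correlation_cm_sm(build_corpus(2, 2, 64, 1), tiny_bank()),
               "10 pairs")
})

test_that("position statistics survive phase scrambling better than scale statistics", {
  res <- group_correlation_cm_sm(tiny_corpus(), tiny_bank())
  tab <- res$table
  pos <- mean(tab$r[tab$group %in% c("lin_position", "en_position")])
  scl <- mean(tab$r[tab$group %in% c("lin_scale", "en_scale")])
  expect_gt(pos, scl)
})
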