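test_that("the encoder satisfies the nonnegative-lasso optimality conditions", {
  set.seed(1)
  A <- matrix(rnorm(50 * 10), 50, 10)
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  x <- rnorm(50)
  # the zero-threshold condition: lambda >= 2 max a_i'x forces s = 0
  lam0 <- 2 * max(crossprod(A, x)) + 1e-6
  expect_identical(unname(encode(x, A, lam0)), rep(0, 10))
  # x = 0 -> s = 0
  expect_identical(unname(encode(rep(0, 50), A, 0.1)), rep(0, 10))
  # general KKT residuals
  s <- encode(x, A, 0.3)
  g <- 2 * (crossprod(A) %*% s - crossprod(A, x)) + 0.3
  expect_lt(max(abs(g[s > 0])), 1e-8)
  expect_gte(min(g[s == 0]), -1e-8)
  expect_error(encode(c(x[-1], NA), A, 0.1), "non-finite")
})

test_that("the encoder matches the closed form for an orthonormal dictionary", {
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(20 * 20), 20, 20)))[, 1:6]
  lam <- 0.1
  s <- encode(Q[, 4], Q, lam)
  want <- rep(0, 6); want[4] <- 1 - lam / 2  # soft threshold at lambda/2
  expect_equal(unname(s), want, tolerance = 1e-8)
})

test_that("the encoder agrees with an independent nonnegative-lasso solver", {
  skip_if_not_installed("glmnet")
  set.seed(3)
  A <- matrix(rnorm(60 * 12), 60, 12)
  A <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  x <- A %*% rexp(12) + rnorm(60, sd = 0.2)
  lam <- 0.5
  s <- encode(x, A, lam)
  # glmnet objective: 1/(2n)||y - Xb||^2 + lambda_g ||b||_1 with b >= 0
  g <- glmnet::glmnet(A, x, lambda = lam / (2 * nrow(A)), lower.limits = 0,
                      intercept = FALSE, standardize = FALSE, thresh = 1e-14)
  sg <- as.numeric(g$beta)
  obj <- function(b) sum((x - A %*% b)^2) + lam * sum(b)
  expect_lt(abs(obj(s) - obj(sg)), 1e-6 * max(1, obj(sg)))
})

test_that("dictionary learning is monotone, reproducible, and recovers planted atoms", {
  set.seed(4)
  B <- matrix(rnorm(25 * 3), 25, 3); B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  W <- matrix(rgamma(3 * 400, 2, 2) * (runif(3 * 400) < 0.5), 3, 400)
  X <- B %*% W + matrix(rnorm(25 * 400, sd = 0.01), 25, 400)

  d1 <- learn_dictionary(X, 3, lambda = 0.05, n_iters = 25, seed = 7)
  d2 <- learn_dictionary(X, 3, lambda = 0.05, n_iters = 25, seed = 7)
  expect_identical(d1$bases, d2$bases)
  expect_true(all(diff(d1$trace) <= 1e-6 * pmax(1, head(d1$trace, -1))))
  expect_true(all(colSums(d1$bases^2) <= 1 + 1e-9))
  cs <- apply(abs(crossprod(d1$bases, B)), 2, max)
  expect_true(all(cs >= 0.95))
  expect_error(learn_dictionary(X, 3, 0.05, n_iters = 0), "n_iters")
})

test_that("patch sampling is uniform, seeded, and validated", {
  set.seed(5)
  imgs <- lapply(1:10, function(i) matrix(rnorm(30 * 30), 30, 30))
  P <- sample_patches(imgs, n_per_image = 200, patch_size = 5, seed = 3)
  expect_identical(dim(P), c(25L, 2000L))
  P2 <- sample_patches(imgs, n_per_image = 200, patch_size = 5, seed = 3)
  expect_identical(attr(P, "coords"), attr(P2, "coords"))
  expect_identical(ncol(sample_patches(imgs, 0, 5)), 0L)
  expect_error(sample_patches(imgs, 10, 40), "larger than image")
})

test_that("the forward pass respects zero inputs, pooling, and shape contracts", {
  tt <- trained_tiny()
  out <- forward(tt$net, tt$dicts, matrix(0, 64, 64))
  expect_true(all(vapply(out$layers, function(m) all(m == 0), TRUE)))
  expect_true(all(vapply(out$big, function(m) all(m >= 0), TRUE)))

  # one positive pixel appears once per covering pooling window
  m <- array(0, c(6, 6, 1)); m[3, 3, 1] <- 2.5
  pooled <- forward(network_spec(list(layer_spec("max_pool", 2, 1)), 1L),
                    list(NULL), m[, , 1])$layers[[1]]
  expect_identical(sum(pooled == 2.5), 4L)  # 2x2 stride-1 windows over (3,3)

  bad <- tt$dicts
  bad[[1]]$bases <- bad[[1]]$bases[, -1]
  expect_error(forward(tt$net, bad, matrix(0, 64, 64)), "layer 1")
})

test_that("receptive fields and unit counts follow the strided geometry", {
  n1 <- network_spec(list(layer_spec("sparse_coding", 11, 4, M = 96,
                                     lambda = 0.1)), 1L)
  expect_identical(rf_size(n1, 1), 11L)
  n2 <- network_spec(list(layer_spec("sparse_coding", 11, 4, M = 96, lambda = 0.1),
                          layer_spec("max_pool", 3, 2)), c(1L, 1L))
  expect_identical(rf_size(n2, 2), 11L + 2L * 4L)

  alex <- alexnet_geometry()
  expect_identical(unit_count(alex, 1, 227), 55 * 55 * 96)
  expect_true(all(diff(vapply(seq_along(alex$layers),
                              function(l) rf_size(alex, l), 1L)) > 0))

  # a map collapsed to 1 x 1 with a single filter counts one unit
  none <- network_spec(list(layer_spec("sparse_coding", 8, 1, M = 1,
                                       lambda = 0.1)), 1L)
  expect_identical(unit_count(none, 1, 8), 1 * 1 * 1)
  expect_error(unit_count(none, 1, 6), "infeasible")
})

test_that("weight randomization keeps geometry and erases learned structure", {
  tt <- trained_tiny()
  rd <- randomize_weights(tt$dicts, seed = 5)
  rd2 <- randomize_weights(tt$dicts, seed = 5)
  for (l in seq_along(rd)) {
    if (is.null(rd[[l]])) next
    expect_lt(max(abs(colSums(rd[[l]]$bases^2) - 1)), 1e-12)
    expect_identical(rd[[l]]$bases, rd2[[l]]$bases)
  }
  cs <- colSums(rd[[1]]$bases * tt$dicts[[1]]$bases)
  expect_lt(abs(mean(cs)), 0.3)
})

test_that("the two-path construction equates the intended receptive fields", {
  net <- shmax_spec()
  for (pair in list(c(1, 2), c(2, 3))) {
    tp <- build_two_path(net, pair[1], pair[2])
    expect_identical(tp$rf[["a"]], tp$rf[["b"]])
    expect_gt(tp$rf[["b"]], tp$rf[["c"]])
  }
  tp <- build_two_path(alexnet_geometry(), 1, 2)
  expect_identical(tp$rf[["a"]], tp$rf[["b"]])
  expect_error(build_two_path(net, 1, 3), "consecutive")
})

test_that("the two paths emit same-size maps at the merge point", {
  tt <- trained_tiny()
  tp <- build_two_path(tt$net, 1, 2)
  td <- train_two_path(tp, lapply(tt$corpus$pairs[1:3], `[[`, "cm"),
                       seed = 2, n_per_image = 30, n_iters = 3)
  r <- forward_two_path(tp, td, tt$corpus$pairs[[1]]$cm)
  # b and c are same-size lower-layer maps up to their atom counts
  expect_identical(length(r$b) / tp$set_b$M, length(r$c) / tp$set_c$M)
  expect_true(all(r$a >= 0) && all(r$b >= 0) && all(r$c >= 0))
})
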