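test_that("phase randomization preserves the amplitude spectrum and the mean", {
  set.seed(1)
  for (i in 1:10) {
    img <- matrix(rnorm(32 * 48), 32, 48)
    out <- phase_randomize(img, seed = i)
    expect_true(is.numeric(out) && all(is.finite(out)))
    expect_identical(dim(out), dim(img))
    a_in <- Mod(fft(img)); a_out <- Mod(fft(out))
    big <- a_in > 1e-8
    expect_lt(max(abs(a_out[big] - a_in[big]) / a_in[big]), 1e-8)
    expect_lt(abs(mean(out) - mean(img)), 1e-8 * max(1, abs(mean(img))))
  }
})

test_that("a constant image is its own phase scramble", {
  img <- matrix(3.7, 16, 16)
  out <- phase_randomize(img, seed = 5)
  expect_equal(out, img, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a cosine grating keeps its frequency and amplitude under scrambling", {
  n <- 16
  xg <- matrix(rep(seq_len(n) - 1, each = n), n, n, byrow = TRUE)
  img <- cos(2 * pi * 3 * xg / n)
  out <- phase_randomize(img, seed = 2)
  # direct-DFT oracle, independent of the fft-based implementation
  expect_equal(Mod(direct_dft2(out)), Mod(direct_dft2(img)), tolerance = 1e-8)
  # energy still concentrated at the same single frequency pair
  a <- Mod(direct_dft2(out))
  expect_lt(sum(a > 1e-6 * max(a)), 3)
})

test_that("scrambling twice with independent seeds still matches the original spectrum", {
  set.seed(3)
  img <- matrix(rnorm(24 * 24), 24, 24)
  out <- phase_randomize(phase_randomize(img, seed = 11), seed = 12)
  a_in <- Mod(fft(img)); a_out <- Mod(fft(out))
  big <- a_in > 1e-8
  expect_lt(max(abs(a_out[big] - a_in[big]) / a_in[big]), 1e-8)
})

test_that("phase randomization validates its input", {
  img <- matrix(1, 16, 16); img[c(1, 5, 9)] <- NA
  expect_error(phase_randomize(img), "3 non-finite")
  expect_error(phase_randomize(matrix(0, 15, 16)), "even")
})

test_that("structured textures are deterministic and parameter-checked", {
  p <- list(density = 15, ori_conc = 10, curvature = 0.3, coupling = 0.8)
  a <- synth_texture(p, size = 32, seed = 9)
  b <- synth_texture(p, size = 32, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, synth_texture(p, size = 32, seed = 10)))
  expect_error(synth_texture(modifyList(p, list(density = 60)), 32, 1),
               "density")
  expect_error(synth_texture(modifyList(p, list(coupling = 2)), 32, 1),
               "coupling")
  expect_error(synth_texture(list(density = 1), 32, 1), "family_params")
})

test_that("scale coupling creates cross-scale structure that scrambling destroys", {
  bank <- tiny_bank()
  p <- list(density = 20, ori_conc = 12, curvature = 0.2, coupling = 1)
  wins <- 0L
  for (s in 1:8) {
    img <- synth_texture(p, size = 64, seed = 600 + s)
    scr <- phase_randomize(img, seed = 700 + s)
    d <- mean(compute_texture_stats(img, bank)$en_scale) -
      mean(compute_texture_stats(scr, bank)$en_scale)
    wins <- wins + (d > 0)
  }
  expect_gte(wins, 7L)
})

test_that("an unstructured field is statistically indistinguishable from its scramble", {
  bank <- tiny_bank()
  p <- list(density = 0, ori_conc = 0, curvature = 0, coupling = 0)
  diffs <- vapply(1:10, function(s) {
    img <- synth_texture(p, size = 64, seed = 800 + s)
    scr <- phase_randomize(img, seed = 900 + s)
    mean(compute_texture_stats(img, bank)$en_scale) -
      mean(compute_texture_stats(scr, bank)$en_scale)
  }, 0)
  expect_gt(t.test(diffs)$p.value, 0.01)
})

test_that("corpus construction yields n_families x n_per_family pairs with valid labels", {
  set.seed(20)
  for (r in 1:5) {
    nf <- sample(1:3, 1); np <- sample(1:3, 1)
    corpus <- build_corpus(nf, np, size = 16, seed = 100 + r)
    expect_length(corpus$pairs, nf * np)
    fams <- vapply(corpus$pairs, `[[`, 1L, "family_id")
    expect_true(all(fams %in% seq_len(nf)))
    expect_setequal(unique(fams), seq_len(nf))
  }
  expect_length(build_corpus(1, 1, size = 16, seed = 1)$pairs, 1L)
  expect_error(build_corpus(0, 5), ">= 1")
})

test_that("corpus construction is reproducible and pairs share spectra", {
  a <- build_corpus(2, 2, size = 16, seed = 77)
  b <- build_corpus(2, 2, size = 16, seed = 77)
  expect_identical(a$pairs, b$pairs)
  for (p in a$pairs) {
    am <- Mod(fft(p$cm)); as <- Mod(fft(p$sm))
    big <- am > 1e-8
    expect_lt(max(abs(as[big] - am[big]) / am[big]), 1e-8)
  }
})

test_that("preprocessing resizes, centers, and handles degenerate cases", {
  set.seed(4)
  img <- matrix(rnorm(64 * 64), 64, 64)
  # working == model == input: pure mean subtraction
  expect_equal(preprocess(img, 64, 64), img - mean(img), ignore_attr = TRUE)
  expect_equal(preprocess(matrix(5, 32, 32), 16, 24),
               matrix(0, 24, 24), ignore_attr = TRUE)
  out <- preprocess(img, 128, 224)
  expect_identical(dim(out), c(224L, 224L))
  expect_lt(abs(mean(out)), 1e-6 * max(sd(out), 1))
  expect_error(preprocess(img, 4, 64), ">= 8")
})

test_that("a corpus round-trips through PNG files and a JSON manifest", {
  corpus <- build_corpus(2, 2, size = 16, seed = 5)
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  back <- read_corpus(dir)
  expect_length(back$pairs, 4L)
  for (k in seq_along(corpus$pairs)) {
    # faithful up to 8-bit quantization of the per-image range
    q <- diff(range(corpus$pairs[[k]]$cm)) / 255
    expect_lt(max(abs(back$pairs[[k]]$cm - corpus$pairs[[k]]$cm)), q)
    expect_identical(back$pairs[[k]]$family_id, corpus$pairs[[k]]$family_id)
  }
})
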