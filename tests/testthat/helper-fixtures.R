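# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

tiny_bank <- function() fixture("tiny_bank", filter_bank(n_scales = 3L))

tiny_corpus <- function() {
  fixture("tiny_corpus", build_corpus(4L, 3L, size = 64L, seed = 42L))
}

# Corpus whose "pairs" are two independent white-noise images (no structure
# shared between the roles).
noise_pair_corpus <- function(n_pairs = 24L, size = 64L, seed = 7L) {
  fixture(sprintf("noise_corpus_%d_%d_%d", n_pairs, size, seed), {
    withr::with_seed(seed, {
      pairs <- lapply(seq_len(n_pairs), function(k) {
        list(cm = matrix(stats::rnorm(size^2), size, size),
             sm = matrix(stats::rnorm(size^2), size, size),
             family_id = 1L, image_id = k, pair_id = k)
      })
      structure(list(pairs = pairs, n_families = 1L, n_per_family = n_pairs,
                     size = size, family_params = NULL,
                     meta = list(seed = seed)),
                class = "stimulus_corpus")
    })
  })
}

# Small trained model shared by the forward/metrics/pipeline tests.
trained_tiny <- function() {
  fixture("trained_tiny", {
    corpus <- tiny_corpus()
    net <- shmax_spec()
    dicts <- train_shmax(net, lapply(corpus$pairs[1:6], `[[`, "cm"),
                         seed = 1L, n_per_image = 60L, n_iters = 6L)
    list(net = net, dicts = dicts, corpus = corpus)
  })
}

# Desk-scale experiment corpus and one trained model, shared by the
# pipeline and acceptance suites.
exp_corpus <- function() {
  fixture("exp_corpus", build_corpus(8L, 6L, size = 64L, seed = 99L))
}

trained_exp <- function() {
  fixture("trained_exp", {
    corpus <- exp_corpus()
    net <- shmax_spec()
    imgs <- withr::with_seed(1L, sample(lapply(corpus$pairs, `[[`, "cm"), 12L))
    list(net = net,
         dicts = train_shmax(net, imgs, seed = 1L, n_per_image = 80L,
                             n_iters = 8L),
         corpus = corpus)
  })
}

baseline_tiny <- function() {
  fixture("baseline_tiny", {
    run_baseline(tiny_corpus(), shmax_spec(), seed = 3L, n_train = 6L,
                 n_per_image = 40L, n_iters = 4L, n_perm = 300L,
                 rst_n = 50L, rst_reps = 50L)
  })
}

# All permutations of 1..n (n small), used by brute-force oracles.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# Direct 2-D DFT by explicit summation matrices (independent of stats::fft).
direct_dft2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  Wh <- exp(-2i * pi * outer(0:(h - 1), 0:(h - 1)) / h)
  Ww <- exp(-2i * pi * outer(0:(w - 1), 0:(w - 1)) / w)
  Wh %*% x %*% Ww
}
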