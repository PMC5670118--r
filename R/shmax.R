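#' Layer and network specifications
#'
#' A network is an ordered list of layers, each either a nonnegative
#' sparse-coding layer (with `M` dictionary atoms and sparseness penalty
#' `lambda`) or a max-pooling layer. Layers are grouped into "big layers"
#' (LAYER1..LAYERk), each starting with a coding layer; the response of a
#' big layer is the output of its final layer (after pooling where pooling
#' exists).
#'
#' @param kind `"sparse_coding"` or `"max_pool"`.
#' @param kernel,stride Positive integers; `pad` is symmetric zero padding.
#' @param M,lambda Required for coding layers: atom count and L1 penalty
#'   (`lambda > 0`).
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kind = c("sparse_coding", "max_pool"), kernel, stride,
                       M = NULL, lambda = NULL, pad = 0L) {
  kind <- match.arg(kind)
  if (kernel < 1L || stride < 1L || pad < 0L) stop("invalid layer geometry")
  if (kind == "sparse_coding") {
    if (is.null(M) || M < 1L) stop("coding layers need M >= 1")
    if (is.null(lambda) || lambda <= 0) stop("coding layers need lambda > 0")
  }
  structure(list(kind = kind, kernel = as.integer(kernel),
                 stride = as.integer(stride), M = M, lambda = lambda,
                 pad = as.integer(pad)),
            class = "layer_spec")
}

#' @param layers List of `layer_spec`s.
#' @param grouping Integer vector, one entry per layer, assigning each layer
#'   to a big layer (non-decreasing, starting at 1, covering all layers).
#' @rdname layer_spec
#' @export
network_spec <- function(layers, grouping) {
  grouping <- as.integer(grouping)
  if (length(grouping) != length(layers)) {
    stop("grouping must cover all layers exactly once")
  }
  if (grouping[1L] != 1L || any(diff(grouping) < 0L) || any(diff(grouping) > 1L)) {
    stop("grouping must be non-decreasing and contiguous from 1")
  }
  structure(list(layers = layers, grouping = grouping),
            class = "network_spec")
}

#' Desk-scale SHMAX architecture
#'
#' Three big layers, each a sparse-coding layer followed by 2x2 stride-2 max
#' pooling, sized for images up to ~96 pixels. The default sparseness
#' penalties follow the convention of 0.15 for the first two big layers and
#' 0.1 above.
#'
#' @param M Atoms per coding layer.
#' @param kernels,strides Coding-layer geometry (per big layer).
#' @param lambdas Per big layer sparseness penalty.
#' @param pool_kernel,pool_stride Pooling geometry.
#' @return A `network_spec`.
#' @export
shmax_spec <- function(M = c(32L, 48L, 64L), kernels = c(7L, 5L, 3L),
                       strides = c(2L, 1L, 1L),
                       lambdas = c(0.15, 0.15, 0.1),
                       pool_kernel = 2L, pool_stride = 2L) {
  nb <- length(M)
  stopifnot(length(kernels) == nb, length(strides) == nb, length(lambdas) == nb)
  layers <- list(); grouping <- integer(0)
  for (b in seq_len(nb)) {
    layers <- c(layers, list(
      layer_spec("sparse_coding", kernels[b], strides[b], M = M[b],
                 lambda = lambdas[b]),
      layer_spec("max_pool", pool_kernel, pool_stride)))
    grouping <- c(grouping, b, b)
  }
  network_spec(layers, grouping)
}

#' Five-big-layer geometry matching the classic AlexNet convolutional stack
#'
#' Provided for the receptive-field and unit-count calculators (geometry
#' only; this package does not train CNNs). With 227-pixel input the first
#' coding layer produces 55 x 55 maps of 96 filters.
#'
#' @return A `network_spec`.
#' @export
alexnet_geometry <- function() {
  L <- list(
    layer_spec("sparse_coding", 11L, 4L, M = 96L, lambda = 0.15),
    layer_spec("max_pool", 3L, 2L),
    layer_spec("sparse_coding", 5L, 1L, M = 256L, lambda = 0.15, pad = 2L),
    layer_spec("max_pool", 3L, 2L),
    layer_spec("sparse_coding", 3L, 1L, M = 384L, lambda = 0.1, pad = 1L),
    layer_spec("sparse_coding", 3L, 1L, M = 384L, lambda = 0.1, pad = 1L),
    layer_spec("sparse_coding", 3L, 1L, M = 256L, lambda = 0.1, pad = 1L),
    layer_spec("max_pool", 3L, 2L))
  network_spec(L, c(1L, 1L, 2L, 2L, 3L, 4L, 5L, 5L))
}

#' Receptive-field size of a layer
#'
#' Standard recursion: `rf_l = rf_{l-1} + (k_l - 1) * prod(strides below l)`,
#' with `rf_0 = 1`.
#'
#' @param net A `network_spec`.
#' @param layer Layer index (1-based).
#' @return Receptive-field side length in input pixels.
#' @export
rf_size <- function(net, layer) {
  if (layer < 1L || layer > length(net$layers)) stop("invalid layer index")
  rf <- 1L; jump <- 1L
  for (l in seq_len(layer)) {
    rf <- rf + (net$layers[[l]]$kernel - 1L) * jump
    jump <- jump * net$layers[[l]]$stride
  }
  rf
}

map_size_at <- function(net, layer, input_size) {
  n <- as.integer(input_size)
  for (l in seq_len(layer)) {
    sp <- net$layers[[l]]
    n <- (n + 2L * sp$pad - sp$kernel) %/% sp$stride + 1L
    if (n < 1L) {
      stop(sprintf("infeasible geometry: layer %d yields map size %d", l, n))
    }
  }
  n
}

#' Number of model units in a layer
#'
#' Every element of every feature map is one unit, so the count is
#' `height x width x filters` for the maps the layer produces at the given
#' input size (floor division for strided geometry, honouring paddings).
#'
#' @inheritParams rf_size
#' @param input_size Input image side in pixels.
#' @return Unit count.
#' @export
unit_count <- function(net, layer, input_size) {
  n <- map_size_at(net, layer, input_size)
  nf <- NA_integer_
  for (l in rev(seq_len(layer))) {  # channels carried through pooling
    if (net$layers[[l]]$kind == "sparse_coding") { nf <- net$layers[[l]]$M; break }
  }
  if (is.na(nf)) stop("no coding layer at or below the requested layer")
  as.numeric(n) * n * nf
}

#' Sparse-coding dictionary
#'
#' Columns are the bases `a_i`, constrained to `||a_i||^2 <= 1`.
#'
#' @param bases patch_dimension x M numeric matrix.
#' @param patch List with `k` (kernel side) and `channels`.
#' @return A `dictionary` object.
#' @export
new_dictionary <- function(bases, patch) {
  nrm2 <- colSums(bases^2)
  if (any(nrm2 > 1 + 1e-9)) stop("dictionary columns must satisfy ||a||^2 <= 1")
  if (nrow(bases) != patch$k^2 * patch$channels) {
    stop("bases dimension does not match patch geometry")
  }
  structure(list(bases = bases, patch = patch), class = "dictionary")
}

#' Nonnegative sparse code of one input
#'
#' Solves `min_s ||x - A s||^2 + lambda ||s||_1` subject to `s >= 0` by
#' cyclic coordinate descent. At the solution the KKT conditions of the
#' nonnegative lasso hold: `2 (A'A s)_i - 2 (A'x)_i + lambda = 0` where
#' `s_i > 0` and `>= 0` where `s_i = 0`; in particular `s = 0` whenever
#' `lambda >= 2 max_i a_i'x`.
#'
#' @param x Input vector (length = patch dimension).
#' @param dict A `dictionary` (or bare basis matrix).
#' @param lambda Positive sparseness penalty.
#' @param max_iter,tol Coordinate-descent budget and convergence tolerance.
#' @return Nonnegative coefficient vector of length M.
#' @export
encode <- function(x, dict, lambda, max_iter = 500L, tol = 1e-10) {
  A <- if (inherits(dict, "dictionary")) dict$bases else as.matrix(dict)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("non-finite input rejected")
  if (length(x) != nrow(A)) stop("input length does not match basis dimension")
  if (lambda <= 0) stop("lambda must be positive")
  drop(encode_batch_cpp(A, matrix(x, ncol = 1L), lambda, max_iter, tol))
}

sc_objective <- function(A, X, S, lambda) {
  sum((X - A %*% S)^2) + lambda * sum(S)
}

#' Learn a sparse-coding dictionary
#'
#' Alternates batch coordinate-descent coding with a block dictionary update
#' (each column minimized in closed form given the codes, then projected to
#' the unit ball), so the objective
#' `sum_j ||x_j - A s_j||^2 + lambda ||s_j||_1` is non-increasing across
#' outer iterations up to the coding tolerance. Deterministic given `seed`.
#'
#' @param patches patch_dimension x K matrix (columns are training patches).
#' @param M Number of atoms.
#' @param lambda Sparseness penalty.
#' @param n_iters Outer iterations (>= 1).
#' @param seed Integer seed for the random initialization.
#' @param tol Relative objective-change early-stopping threshold.
#' @param patch Optional patch geometry (list `k`, `channels`); inferred as
#'   a square single-channel patch when omitted.
#' @return A `dictionary` with the objective `trace` attached.
#' @export
learn_dictionary <- function(patches, M, lambda, n_iters = 30L, seed = 1L,
                             tol = 1e-6, patch = NULL) {
  X <- as.matrix(patches)
  if (n_iters < 1L) stop("n_iters must be >= 1")
  if (ncol(X) < M) warning("fewer patches than atoms; recovery may be poor")
  withr::local_seed(seed)
  p <- nrow(X)
  # Initialize atoms from random training patches (plus a tiny jitter so
  # duplicated patches do not yield identical atoms); the norm constraint
  # makes a pure-noise start waste the first iterations.
  pick <- sample.int(ncol(X), M, replace = ncol(X) < M)
  A <- X[, pick, drop = FALSE] + matrix(stats::rnorm(p * M, sd = 1e-3), p, M)
  nrm <- pmax(sqrt(colSums(A^2)), 1e-12)
  A <- sweep(A, 2L, nrm, "/")
  trace <- numeric(0)
  for (it in seq_len(n_iters)) {
    S <- encode_batch_cpp(A, X, lambda, 200L, 1e-9)
    obj <- sc_objective(A, X, S, lambda)
    trace <- c(trace, obj)
    if (it > 1L && abs(trace[it - 1L] - obj) <= tol * max(1, trace[it - 1L])) break
    A <- dict_update_cpp(A, X %*% t(S), S %*% t(S))
  }
  if (is.null(patch)) {
    k <- as.integer(round(sqrt(p)))
    patch <- if (k * k == p) list(k = k, channels = 1L) else list(k = 1L, channels = p)
  }
  d <- new_dictionary(A, patch)
  d$trace <- trace
  d$lambda <- lambda
  d
}

#' Sample patches uniformly from feature maps
#'
#' @param maps List of feature maps (h x w matrices or h x w x c arrays).
#' @param n_per_image Patches per map (default 200).
#' @param patch_size Patch side in pixels.
#' @param seed Integer seed.
#' @return patch_dimension x (maps * n_per_image) matrix; patch coordinates
#'   in attribute `coords`.
#' @export
sample_patches <- function(maps, n_per_image = 200L, patch_size, seed = 1L) {
  withr::local_seed(seed)
  cols <- list(); coords <- list()
  for (i in seq_along(maps)) {
    x <- maps[[i]]
    if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
    h <- dim(x)[1L]; w <- dim(x)[2L]
    if (patch_size > h || patch_size > w) stop("patch larger than image")
    if (n_per_image == 0L) next
    ys <- sample.int(h - patch_size + 1L, n_per_image, replace = TRUE)
    xs <- sample.int(w - patch_size + 1L, n_per_image, replace = TRUE)
    m <- vapply(seq_len(n_per_image), function(j) {
      as.vector(x[ys[j]:(ys[j] + patch_size - 1L),
                  xs[j]:(xs[j] + patch_size - 1L), , drop = FALSE])
    }, numeric(patch_size^2 * dim(x)[3L]))
    cols[[length(cols) + 1L]] <- m
    coords[[length(coords) + 1L]] <- cbind(image = i, y = ys, x = xs)
  }
  out <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(0), nrow = patch_size^2, ncol = 0L)
  attr(out, "coords") <- if (length(coords)) do.call(rbind, coords) else NULL
  out
}

layer_forward <- function(x, sp, dict = NULL, max_iter = 60L, tol = 1e-8) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (sp$kind == "max_pool") {
    return(maxpool_cpp(x, sp$kernel, sp$stride))
  }
  A <- dict$bases
  if (nrow(A) != sp$kernel^2 * dim(x)[3L] || ncol(A) != sp$M) {
    stop("dictionary does not match layer spec (kernel/channels/M)")
  }
  P <- im2col_cpp(x, sp$kernel, sp$stride, sp$pad, sp$pad, sp$pad, sp$pad)
  S <- encode_batch_cpp(A, P, sp$lambda, max_iter, tol)
  oh <- (dim(x)[1L] + 2L * sp$pad - sp$kernel) %/% sp$stride + 1L
  ow <- (dim(x)[2L] + 2L * sp$pad - sp$kernel) %/% sp$stride + 1L
  aperm(array(S, c(sp$M, oh, ow)), c(2L, 3L, 1L))
}

#' Forward pass through a SHMAX network
#'
#' Coding layers encode every patch at the layer stride; pooling layers take
#' the max over windows. All unit responses are nonnegative. Per-big-layer
#' outputs (the final maps of each big layer) are returned alongside the
#' per-layer maps.
#'
#' @param net A `network_spec`.
#' @param dicts List of `dictionary` objects indexed by layer (entries for
#'   pooling layers are ignored/NULL).
#' @param img Input image (matrix) or feature array.
#' @return List with `layers` (all feature arrays) and `big` (one array per
#'   big layer).
#' @export
forward <- function(net, dicts, img) {
  x <- as_pixels(img)
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  outs <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    sp <- net$layers[[l]]
    d <- if (sp$kind == "sparse_coding") {
      if (l > length(dicts) || is.null(dicts[[l]])) {
        stop(sprintf("missing dictionary for coding layer %d", l))
      }
      dicts[[l]]
    } else NULL
    x <- tryCatch(layer_forward(x, sp, d),
                  error = function(e) stop(sprintf("layer %d: %s", l,
                                                   conditionMessage(e))))
    outs[[l]] <- x
  }
  big <- lapply(split(seq_along(net$layers), net$grouping),
                function(ix) outs[[max(ix)]])
  list(layers = outs, big = big)
}

#' Train a SHMAX network layer-wise
#'
#' For each coding layer in turn: sample patches from the current feature
#' maps of the training images, learn the dictionary, then push all maps
#' through the layer (and any pooling) before training the next one.
#'
#' @param net A `network_spec`.
#' @param images List of training images (matrices).
#' @param seed Integer seed (patch sampling and initialization).
#' @param n_per_image Patches sampled per image per layer.
#' @param n_iters Dictionary-learning outer iterations.
#' @return List of dictionaries indexed by layer.
#' @export
train_shmax <- function(net, images, seed = 1L, n_per_image = 200L,
                        n_iters = 15L) {
  maps <- lapply(images, function(im) {
    x <- as_pixels(im); dim(x) <- c(dim(x), 1L); x
  })
  dicts <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    sp <- net$layers[[l]]
    if (sp$kind == "sparse_coding") {
      P <- sample_patches(maps, n_per_image, sp$kernel, seed = seed + l)
      dicts[[l]] <- learn_dictionary(
        P, sp$M, sp$lambda, n_iters = n_iters, seed = seed + 100L + l,
        patch = list(k = sp$kernel, channels = dim(maps[[1L]])[3L]))
    }
    maps <- lapply(maps, layer_forward, sp = sp, dict = dicts[[l]])
  }
  dicts
}

#' Replace every dictionary atom by a random unit-norm vector
#'
#' The random-weight control: i.i.d. Gaussian columns scaled to unit norm,
#' preserving all geometry.
#'
#' @param dicts List of dictionaries (as from [train_shmax()]).
#' @param seed Integer seed.
#' @return List of dictionaries of identical shapes.
#' @export
randomize_weights <- function(dicts, seed = 1L) {
  withr::local_seed(seed)
  lapply(dicts, function(d) {
    if (is.null(d)) return(NULL)
    A <- matrix(stats::rnorm(length(d$bases)), nrow(d$bases), ncol(d$bases))
    A <- sweep(A, 2L, sqrt(colSums(A^2)), "/")
    out <- new_dictionary(A, d$patch)
    out$lambda <- d$lambda
    out
  })
}
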