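#' Two-path receptive-field control architecture
#'
#' Splits the coding layer of `lower_big` into two sets with different
#' kernel sizes: set c keeps the baseline kernel, set b gets the enlarged
#' kernel `k_b = k_c + (kp - 1) s_c + (k_a - 1) s_c s_p` (pool kernel `kp`,
#' coding stride `s_c`, pool stride `s_p`, upper kernel `k_a`), chosen so
#' that the receptive field of the lower-layer set-b units equals that of
#' the upper-layer set-a units and strictly exceeds set c's. Asymmetric
#' zero-paddings on the set-b convolution keep both sets' feature maps the
#' same size, which is what later layers would require.
#'
#' @param net A `network_spec` whose big layers each consist of a coding
#'   layer followed by one pooling layer.
#' @param lower_big,upper_big Consecutive big-layer indices.
#' @param split Fraction of the lower layer's atoms assigned to set b.
#' @return A `two_path_spec`: the shared prefix, per-set layer specs, the
#'   engineered paddings, and the receptive-field sizes of sets a, b, c.
#' @export
build_two_path <- function(net, lower_big, upper_big, split = 0.5) {
  if (upper_big != lower_big + 1L) stop("big layers must be consecutive")
  idx_of_big <- split(seq_along(net$layers), net$grouping)
  lower_ix <- idx_of_big[[lower_big]]
  upper_ix <- idx_of_big[[upper_big]]
  lc <- net$layers[[lower_ix[1L]]]
  if (lc$kind != "sparse_coding") stop("big layer must start with a coding layer")
  if (length(lower_ix) != 2L || net$layers[[lower_ix[2L]]]$kind != "max_pool") {
    stop("two-path construction expects coding + pool big layers")
  }
  lp <- net$layers[[lower_ix[2L]]]
  uc <- net$layers[[upper_ix[1L]]]

  k_b <- lc$kernel + (lp$kernel - 1L) * lc$stride +
    (uc$kernel - 1L) * lc$stride * lp$stride
  pad_total <- k_b - lc$kernel
  pads <- c(left = pad_total %/% 2L, right = pad_total - pad_total %/% 2L)

  prefix_ix <- seq_len(lower_ix[1L] - 1L)
  jump0 <- prod(vapply(net$layers[prefix_ix],
                       function(l) l$stride, 1L)) %||one% 1L
  rf0 <- if (length(prefix_ix)) rf_size(net, max(prefix_ix)) else 1L
  rf_c <- rf0 + (lc$kernel - 1L) * jump0
  rf_b <- rf0 + (k_b - 1L) * jump0
  rf_a <- rf_c + (lp$kernel - 1L) * jump0 * lc$stride +
    (uc$kernel - 1L) * jump0 * lc$stride * lp$stride
  if (rf_a != rf_b || rf_b <= rf_c) {
    stop(sprintf("infeasible split: rf_a=%d rf_b=%d rf_c=%d (k_b=%d)",
                 rf_a, rf_b, rf_c, k_b))
  }

  M_b <- max(1L, round(split * lc$M))
  M_c <- lc$M - M_b
  if (M_c < 1L) stop("split leaves no atoms in set c")

  structure(list(
    base = net, lower_big = lower_big, upper_big = upper_big,
    prefix_layers = net$layers[prefix_ix],
    set_c = layer_spec("sparse_coding", lc$kernel, lc$stride, M = M_c,
                       lambda = lc$lambda),
    set_b = layer_spec("sparse_coding", k_b, lc$stride, M = M_b,
                       lambda = lc$lambda),
    set_b_pads = pads,
    pool = lp,
    set_a = layer_spec("sparse_coding", uc$kernel, uc$stride, M = uc$M,
                       lambda = uc$lambda, pad = uc$pad),
    rf = c(a = rf_a, b = rf_b, c = rf_c)),
    class = "two_path_spec")
}

`%||one%` <- function(a, b) if (length(a)) a else b

two_path_prefix <- function(tp, img, dicts_prefix) {
  x <- as_pixels(img); dim(x) <- c(dim(x), 1L)
  for (l in seq_along(tp$prefix_layers)) {
    x <- layer_forward(x, tp$prefix_layers[[l]], dicts_prefix[[l]])
  }
  x
}

conv_padded <- function(x, sp, dict, pads) {
  A <- dict$bases
  P <- im2col_cpp(x, sp$kernel, sp$stride, pads[["left"]], pads[["right"]],
                  pads[["left"]], pads[["right"]])
  S <- encode_batch_cpp(A, P, sp$lambda, 60L, 1e-8)
  oh <- (dim(x)[1L] + sum(pads) - sp$kernel) %/% sp$stride + 1L
  ow <- (dim(x)[2L] + sum(pads) - sp$kernel) %/% sp$stride + 1L
  aperm(array(S, c(sp$M, oh, ow)), c(2L, 3L, 1L))
}

#' Train the two-path control model
#'
#' Trains the shared prefix layer-wise as in [train_shmax()], then learns
#' separate dictionaries for set c, set b (enlarged kernel) and the upper
#' set a (on the pooled set-c maps).
#'
#' @param tp A `two_path_spec`.
#' @param images Training images.
#' @param seed Integer seed.
#' @param n_per_image,n_iters Training budget per dictionary.
#' @return List with `prefix`, `b`, `c`, `a` dictionaries.
#' @export
train_two_path <- function(tp, images, seed = 1L, n_per_image = 200L,
                           n_iters = 15L) {
  maps <- lapply(images, function(im) {
    x <- as_pixels(im); dim(x) <- c(dim(x), 1L); x
  })
  dp <- vector("list", length(tp$prefix_layers))
  for (l in seq_along(tp$prefix_layers)) {
    sp <- tp$prefix_layers[[l]]
    if (sp$kind == "sparse_coding") {
      P <- sample_patches(maps, n_per_image, sp$kernel, seed = seed + l)
      dp[[l]] <- learn_dictionary(P, sp$M, sp$lambda, n_iters = n_iters,
                                  seed = seed + 100L + l,
                                  patch = list(k = sp$kernel,
                                               channels = dim(maps[[1L]])[3L]))
    }
    maps <- lapply(maps, layer_forward, sp = sp, dict = dp[[l]])
  }
  ch <- dim(maps[[1L]])[3L]
  train_set <- function(sp, off) {
    P <- sample_patches(maps, n_per_image, sp$kernel, seed = seed + off)
    learn_dictionary(P, sp$M, sp$lambda, n_iters = n_iters,
                     seed = seed + 100L + off,
                     patch = list(k = sp$kernel, channels = ch))
  }
  d_c <- train_set(tp$set_c, 31L)
  d_b <- train_set(tp$set_b, 32L)
  pooled_c <- lapply(maps, function(x) {
    layer_forward(layer_forward(x, tp$set_c, d_c), tp$pool)
  })
  Pa <- sample_patches(pooled_c, n_per_image, tp$set_a$kernel, seed = seed + 33L)
  d_a <- learn_dictionary(Pa, tp$set_a$M, tp$set_a$lambda, n_iters = n_iters,
                          seed = seed + 133L,
                          patch = list(k = tp$set_a$kernel,
                                       channels = dim(pooled_c[[1L]])[3L]))
  list(prefix = dp, b = d_b, c = d_c, a = d_a)
}

#' Responses of the three unit sets of a two-path model
#'
#' Responses are taken at the coding layers themselves (the units whose
#' receptive fields the construction equates): set b and set c in the lower
#' stage, set a in the upper stage fed by the pooled set-c path.
#'
#' @param tp A `two_path_spec`.
#' @param dicts Dictionaries from [train_two_path()].
#' @param img Input image.
#' @return List of nonnegative response vectors `a`, `b`, `c`.
#' @export
forward_two_path <- function(tp, dicts, img) {
  x <- two_path_prefix(tp, img, dicts$prefix)
  resp_c <- layer_forward(x, tp$set_c, dicts$c)
  resp_b <- conv_padded(x, tp$set_b, dicts$b, tp$set_b_pads)
  if (!all(dim(resp_b)[1:2] == dim(resp_c)[1:2])) {
    stop(sprintf("path map sizes disagree at the merge point: %s vs %s",
                 paste(dim(resp_b)[1:2], collapse = "x"),
                 paste(dim(resp_c)[1:2], collapse = "x")))
  }
  pooled_c <- layer_forward(resp_c, tp$pool)
  resp_a <- layer_forward(pooled_c, tp$set_a, dicts$a)
  list(a = as.vector(resp_a), b = as.vector(resp_b), c = as.vector(resp_c))
}
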