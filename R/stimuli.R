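#' Grayscale stimulus image
#'
#' A `gray_image` is a plain numeric matrix (height x width, arbitrary
#' intensity units) carrying `family_id` and `image_id` attributes. All
#' stimulus operations accept and return bare matrices; the class exists so
#' corpus bookkeeping can travel with the pixels.
#'
#' @param pixels Numeric matrix, at least 8 x 8, all values finite.
#' @param family_id,image_id Integer labels.
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, family_id = 1L, image_id = 1L) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("pixels must be numeric")
  nbad <- sum(!is.finite(pixels))
  if (nbad > 0L) {
    stop(sprintf("image contains %d non-finite pixel(s)", nbad))
  }
  if (nrow(pixels) < 8L || ncol(pixels) < 8L) {
    stop("image must be at least 8 x 8 pixels")
  }
  structure(pixels, family_id = as.integer(family_id),
            image_id = as.integer(image_id), class = c("gray_image", "matrix"))
}

as_pixels <- function(img) {
  x <- unclass(img)
  attr(x, "family_id") <- NULL
  attr(x, "image_id") <- NULL
  x
}

#' Randomize the Fourier phases of an image
#'
#' Produces a spectrally matched (SM) image: the Fourier amplitude spectrum
#' of the input is preserved exactly while the phases are replaced by random
#' ones, destroying most higher-order statistical dependencies. Phases are
#' drawn over one half-plane of frequency space and mirrored with conjugate
#' symmetry so the output is real; the DC phase is left at 0 (the image mean
#' is untouched) and the self-conjugate Nyquist frequencies of even-sized
#' images only have their sign randomized. Odd image sizes are rejected to
#' avoid ambiguous Nyquist handling. No clipping is applied to the output.
#'
#' @param img Numeric matrix with even dimensions.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A real-valued matrix of the same size with identical amplitude
#'   spectrum (relative deviation below 1e-8).
#' @export
phase_randomize <- function(img, seed = NULL) {
  x <- as_pixels(img)
  nbad <- sum(!is.finite(x))
  if (nbad > 0L) stop(sprintf("image contains %d non-finite pixel(s)", nbad))
  h <- nrow(x); w <- ncol(x)
  if (h %% 2L != 0L || w %% 2L != 0L) {
    stop("phase_randomize requires even image dimensions")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  F <- stats::fft(x)
  # Antisymmetric random phase field: phi(u, v) = phi0(u, v) - phi0(-u, -v)
  # (indices mod size) is uniform at every non-self-conjugate frequency and
  # exactly zero at self-conjugate ones, which keeps the spectrum Hermitian.
  phi0 <- matrix(stats::runif(h * w, -pi, pi), h, w)
  iu <- c(1L, seq(h, 2L))  # index of -u mod h, 1-based
  iv <- c(1L, seq(w, 2L))
  phi <- phi0 - phi0[iu, iv]
  F <- F * exp(1i * phi)
  # Self-conjugate Nyquist bins (excluding DC): randomize only the sign.
  sc_u <- c(1L, h / 2L + 1L)
  sc_v <- c(1L, w / 2L + 1L)
  for (u in sc_u) for (v in sc_v) {
    if (u == 1L && v == 1L) next
    F[u, v] <- F[u, v] * sign(stats::runif(1) - 0.5)
  }
  out <- stats::fft(F, inverse = TRUE) / (h * w)
  resid <- max(abs(Im(out)))
  if (resid > 1e-9 * max(sqrt(mean(Re(out)^2)), .Machine$double.eps)) {
    stop("internal error: inverse transform is not real")
  }
  Re(out)
}

# Bilinear resize with box-average anti-aliasing when downscaling.
# Pixel centres are mapped with the half-pixel convention; edges clamp.
resize_bilinear <- function(x, out_h, out_w, antialias = TRUE) {
  h <- nrow(x); w <- ncol(x)
  if (out_h == h && out_w == w) return(x)
  if (antialias) {
    # Smooth with a separable box filter matched to the downscale factor
    # before resampling, so high frequencies do not alias.
    fy <- h / out_h; fx <- w / out_w
    if (fy > 1) x <- box_smooth(x, max(1L, floor(fy)), margin = 1L)
    if (fx > 1) x <- box_smooth(x, max(1L, floor(fx)), margin = 2L)
  }
  map_idx <- function(n_out, n_in) {
    pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) + 0.5  # source coordinate
    pos <- pmin(pmax(pos, 1), n_in)
    lo <- pmin(floor(pos), n_in - 1L)
    list(lo = as.integer(lo), frac = pos - lo)
  }
  my <- map_idx(out_h, h); mx <- map_idx(out_w, w)
  a <- x[my$lo, mx$lo, drop = FALSE]
  b <- x[my$lo + 1L, mx$lo, drop = FALSE]
  cc <- x[my$lo, mx$lo + 1L, drop = FALSE]
  d <- x[my$lo + 1L, mx$lo + 1L, drop = FALSE]
  wy <- matrix(my$frac, out_h, out_w)
  wx <- matrix(mx$frac, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * wy * (1 - wx) + cc * (1 - wy) * wx + d * wy * wx
}

box_smooth <- function(x, k, margin) {
  if (k <= 1L) return(x)
  kern <- rep(1 / k, k)
  sm <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1L], k), v, rep(v[n], k))
    out <- stats::filter(padded, kern, sides = 2L)
    out[(k + 1L):(k + n)]
  }
  if (margin == 1L) apply(x, 2L, sm) else t(apply(x, 1L, sm))
}

#' Preprocess a stimulus image for model presentation
#'
#' Resizes the image to `working_size`, subtracts its mean, then resizes to
#' `model_size` (the resolution the model expects). Defaults follow the
#' standard protocol of synthesizing at 128 x 128 and presenting at
#' 224 x 224. Resizing is bilinear with box-average anti-aliasing on
#' downscale.
#'
#' @param img Numeric matrix.
#' @param working_size,model_size Target sizes in pixels (square), >= 8.
#' @return Numeric matrix of size `model_size` x `model_size` with mean
#'   within interpolation error of zero.
#' @export
preprocess <- function(img, working_size = 128L, model_size = 224L) {
  if (working_size < 8L || model_size < 8L) stop("target sizes must be >= 8")
  x <- as_pixels(img)
  x <- resize_bilinear(x, working_size, working_size)
  x <- x - mean(x)
  resize_bilinear(x, model_size, model_size)
}

# Additive placement of an oriented even-phase Gabor element.
place_element <- function(canvas, cy, cx, theta, wavelength, sigma, amp = 1) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- ceiling(3 * sigma)
  ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(canvas)
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  g <- exp(-(u^2 + v^2) / (2 * sigma^2)) * cos(2 * pi * u / wavelength)
  canvas[ys, xs] <- canvas[ys, xs] + amp * g
  canvas
}

#' Synthesize a structured texture image
#'
#' Builds a texture from oriented quadrature (Gabor) elements placed along
#' smooth contours over a weak noise floor. The construction injects the
#' higher-order dependencies that phase randomization destroys:
#' cross-position correlations from contour alignment, and cross-scale
#' correlations from repeating an element at the same location at twice the
#' scale (with probability `coupling`). It is a stand-in for
#' correlation-matched (CM) textures when no externally synthesized corpus
#' is available.
#'
#' @param family_params List with entries `density` (expected elements per
#'   1000 pixels, in `[0, 50]`), `ori_conc` (orientation concentration about
#'   the contour tangent, `[0, 20]`; larger = tighter alignment), `curvature`
#'   (contour turning rate, `[0, 1]`) and `coupling` (probability of
#'   same-location two-scale repetition, `[0, 1]`).
#' @param size Image side in pixels (even, >= 16).
#' @param seed Integer seed; fixed seed and parameters give a bitwise
#'   identical image.
#' @return Numeric `size` x `size` matrix.
#' @export
synth_texture <- function(family_params, size = 64L, seed = NULL) {
  p <- family_params
  need <- c("density", "ori_conc", "curvature", "coupling")
  if (!all(need %in% names(p))) {
    stop("family_params must contain: ", paste(need, collapse = ", "))
  }
  if (p$density < 0 || p$density > 50) stop("density out of range [0, 50]")
  if (p$ori_conc < 0 || p$ori_conc > 20) stop("ori_conc out of range [0, 20]")
  if (p$curvature < 0 || p$curvature > 1) stop("curvature out of range [0, 1]")
  if (p$coupling < 0 || p$coupling > 1) stop("coupling out of range [0, 1]")
  if (size < 16L || size %% 2L != 0L) stop("size must be even and >= 16")
  if (!is.null(seed)) withr::local_seed(seed)

  canvas <- matrix(stats::rnorm(size * size, sd = 0.1), size, size)
  n_elements <- stats::rpois(1, p$density * size * size / 1000)
  if (n_elements == 0) return(canvas)
  wavelength <- 4; sigma <- 1.6; spacing <- 4
  contour_len <- 8L
  ori_sd <- 1 / sqrt(1 + p$ori_conc)  # tangent jitter, radians
  placed <- 0L
  while (placed < n_elements) {
    cy <- stats::runif(1, 1, size); cx <- stats::runif(1, 1, size)
    heading <- stats::runif(1, 0, 2 * pi)
    for (step in seq_len(min(contour_len, n_elements - placed))) {
      theta <- heading + stats::rnorm(1, sd = ori_sd)
      canvas <- place_element(canvas, cy, cx, theta, wavelength, sigma)
      if (stats::runif(1) < p$coupling) {
        canvas <- place_element(canvas, cy, cx, theta,
                                2 * wavelength, 2 * sigma, amp = 0.7)
      }
      placed <- placed + 1L
      heading <- heading + p$curvature * stats::rnorm(1, sd = 0.8)
      cy <- cy + spacing * sin(heading)
      cx <- cx + spacing * cos(heading)
      if (cy < 1 || cy > size || cx < 1 || cx > size) break
    }
  }
  canvas
}

#' Build a paired stimulus corpus
#'
#' Draws `n_families` parameter records from distinct regions of the
#' 4-dimensional family parameter space (Latin hypercube over density,
#' orientation concentration, curvature and scale coupling), synthesizes
#' `n_per_family` structured images per family, and pairs each with its own
#' phase-randomized counterpart. Family parameter ranges favour structured
#' textures (density 8-30, coupling 0.3-1) so that families are
#' distinguishable and carry the higher-order statistics the analysis needs.
#'
#' @param n_families,n_per_family Counts, >= 1.
#' @param size Image side in pixels (even).
#' @param seed Integer seed; the same seed reproduces the corpus exactly.
#' @return A `stimulus_corpus`: list with `pairs` (each a list holding `cm`,
#'   `sm`, `family_id`, `image_id`, `pair_id`, `seed`), `n_families`,
#'   `n_per_family`, `size`, `family_params` and `meta`.
#' @export
build_corpus <- function(n_families, n_per_family, size = 64L, seed = 1L) {
  if (n_families < 1L || n_per_family < 1L) stop("counts must be >= 1")
  withr::local_seed(seed)
  grid <- lhs::randomLHS(n_families, 4L)
  fams <- lapply(seq_len(n_families), function(i) {
    list(density = 8 + 22 * grid[i, 1L],
         ori_conc = 20 * grid[i, 2L],
         curvature = grid[i, 3L],
         coupling = 0.3 + 0.7 * grid[i, 4L])
  })
  # Per-image seeds drawn up front so corpus construction is reproducible
  # regardless of how much randomness each synthesis consumes.
  n_pairs <- n_families * n_per_family
  seeds <- sample.int(.Machine$integer.max, 2L * n_pairs)
  pairs <- vector("list", n_pairs)
  k <- 0L
  for (f in seq_len(n_families)) {
    for (im in seq_len(n_per_family)) {
      k <- k + 1L
      cm <- synth_texture(fams[[f]], size = size, seed = seeds[2L * k - 1L])
      sm <- phase_randomize(cm, seed = seeds[2L * k])
      pairs[[k]] <- list(cm = cm, sm = sm, family_id = f, image_id = im,
                         pair_id = k, seed = seeds[2L * k - 1L],
                         sm_seed = seeds[2L * k])
    }
  }
  structure(list(pairs = pairs, n_families = n_families,
                 n_per_family = n_per_family, size = size,
                 family_params = fams,
                 meta = list(seed = seed, interpolation = "bilinear")),
            class = "stimulus_corpus")
}

#' @export
print.stimulus_corpus <- function(x, ...) {
  cat(sprintf("stimulus corpus: %d families x %d images (%d pairs), %dx%d px\n",
              x$n_families, x$n_per_family, length(x$pairs), x$size, x$size))
  invisible(x)
}

#' Extract one role's images from a corpus
#'
#' @param corpus A `stimulus_corpus`.
#' @param role `"cm"` (structured) or `"sm"` (phase-scrambled).
#' @return List of image matrices in pair order.
#' @export
corpus_images <- function(corpus, role = c("cm", "sm")) {
  role <- match.arg(role)
  lapply(corpus$pairs, `[[`, role)
}

#' Write / read a stimulus corpus as PNG files and a JSON manifest
#'
#' Images are rescaled to [0, 1] per image and written as 8-bit grayscale
#' PNG (the scale and offset are recorded in the manifest, so intensities
#' round-trip up to 8-bit quantization).
#'
#' @param corpus A `stimulus_corpus`.
#' @param dir Output directory (created if needed).
#' @return `write_corpus` returns the manifest path invisibly; `read_corpus`
#'   returns a `stimulus_corpus`.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(n_families = corpus$n_families,
                   n_per_family = corpus$n_per_family,
                   size = corpus$size, meta = corpus$meta, pairs = list())
  for (p in corpus$pairs) {
    rec <- list(pair_id = p$pair_id, family_id = p$family_id,
                image_id = p$image_id, seed = p$seed, sm_seed = p$sm_seed)
    for (role in c("cm", "sm")) {
      img <- p[[role]]
      lo <- min(img); hi <- max(img)
      scl <- if (hi > lo) hi - lo else 1
      fn <- sprintf("%s_%04d.png", role, p$pair_id)
      png::writePNG((img - lo) / scl, file.path(dir, fn))
      rec[[paste0(role, "_file")]] <- fn
      rec[[paste0(role, "_offset")]] <- lo
      rec[[paste0(role, "_scale")]] <- scl
    }
    manifest$pairs[[length(manifest$pairs) + 1L]] <- rec
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  pairs <- lapply(manifest$pairs, function(rec) {
    out <- list(pair_id = rec$pair_id, family_id = rec$family_id,
                image_id = rec$image_id, seed = rec$seed,
                sm_seed = rec$sm_seed)
    for (role in c("cm", "sm")) {
      img <- png::readPNG(file.path(dir, rec[[paste0(role, "_file")]]))
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      out[[role]] <- img * rec[[paste0(role, "_scale")]] +
        rec[[paste0(role, "_offset")]]
    }
    out
  })
  structure(list(pairs = pairs, n_families = manifest$n_families,
                 n_per_family = manifest$n_per_family, size = manifest$size,
                 family_params = NULL, meta = manifest$meta),
            class = "stimulus_corpus")
}
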