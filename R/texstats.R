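#' Quadrature filter bank for texture statistics
#'
#' An undecimated analytic Gabor bank: at each scale and orientation a
#' quadrature pair of linear filters (even and odd, differing by 90 degrees
#' in phase) modelled as a log-Gabor transfer function occupying one
#' half-plane of frequency space. Scales are octave-spaced with the finest
#' centre wavelength at 4 pixels. The energy response (the modulus of the
#' analytic response, i.e. the L2-norm of the quadrature pair) models
#' complex cells. Because filtering is done in the frequency domain, all
#' response maps live on the full image grid and cross-scale correlations
#' need no resampling.
#'
#' @param n_scales,n_orientations Bank geometry (defaults 4 and 4).
#' @param max_offset Position-correlation neighborhood half-width; offsets
#'   are `{-max_offset..max_offset}^2` excluding the origin, de-duplicated
#'   by point symmetry.
#' @return A `filter_bank` configuration object.
#' @export
filter_bank <- function(n_scales = 4L, n_orientations = 4L, max_offset = 3L) {
  if (n_scales < 2L) stop("need at least 2 scales for cross-scale statistics")
  if (n_orientations < 2L) stop("need at least 2 orientations")
  offs <- expand.grid(dy = -max_offset:max_offset, dx = -max_offset:max_offset)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  offs <- offs[offs$dy > 0 | (offs$dy == 0 & offs$dx > 0), ]  # one per +/- pair
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 wavelengths = 4 * 2^(seq_len(n_scales) - 1),
                 orientations = pi * (seq_len(n_orientations) - 1) / n_orientations,
                 offsets = offs,
                 sigma_log = 0.55,  # radial bandwidth in log-frequency
                 row.names = NULL),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("filter bank: %d scales (wavelengths %s px) x %d orientations, %d position offsets\n",
              x$n_scales, paste(x$wavelengths, collapse = "/"),
              x$n_orientations, nrow(x$offsets)))
  invisible(x)
}

# Frequency-domain transfer functions for one image size, cached per call
# site. Returns list [[s]][[o]] of complex h x w matrices, normalized so the
# even (real) spatial kernel has unit L2 norm.
bank_transfer <- function(bank, h, w) {
  fu <- (seq_len(h) - 1) / h; fu[fu >= 0.5] <- fu[fu >= 0.5] - 1
  fv <- (seq_len(w) - 1) / w; fv[fv >= 0.5] <- fv[fv >= 0.5] - 1
  U <- matrix(fu, h, w); V <- matrix(fv, h, w, byrow = TRUE)
  rad <- sqrt(U^2 + V^2)
  ang <- atan2(V, U)
  rad[1, 1] <- 1  # avoid log(0); the DC gain is forced to zero below
  # Narrow angular lobes: with sd = spacing/2.5 the passbands of adjacent
  # orientations barely overlap, so orientation-energy correlations on white
  # noise are ~0 and measure genuine cross-orientation structure.
  sig_t <- (pi / bank$n_orientations) / 2.5
  lapply(seq_len(bank$n_scales), function(s) {
    f0 <- 1 / bank$wavelengths[s]
    Hr <- exp(-(log(rad / f0))^2 / (2 * bank$sigma_log^2))
    Hr[1, 1] <- 0
    lapply(seq_len(bank$n_orientations), function(o) {
      # single angular lobe => analytic (quadrature) filter
      d <- atan2(sin(ang - bank$orientations[o]), cos(ang - bank$orientations[o]))
      H <- Hr * exp(-d^2 / (2 * sig_t^2))
      # Parseval: ||even||^2 = sum(|H/2 + conj-mirror(H)/2|^2)/N; with
      # disjoint half-plane lobes this is sum(|H|^2)/(2N).
      nrm <- sqrt(sum(Mod(H)^2) / (2 * h * w))
      H / nrm
    })
  })
}

#' Spatial kernels of a filter bank
#'
#' Materializes the even/odd spatial kernels at a given grid size, mainly
#' for inspecting the bank and testing its quadrature/unit-norm invariants.
#'
#' @param bank A `filter_bank`.
#' @param size Grid side in pixels.
#' @return Nested list `[[scale]][[orientation]]` with `even` and `odd`
#'   matrices.
#' @export
bank_kernels <- function(bank, size = 64L) {
  tf <- bank_transfer(bank, size, size)
  lapply(tf, function(row) lapply(row, function(H) {
    k <- stats::fft(H, inverse = TRUE) / length(H)
    list(even = Re(k), odd = Im(k))
  }))
}

# Effective support (max centre wavelength) used for the image-size
# precondition: images must be at least 4x this.
bank_support <- function(bank) max(bank$wavelengths)

stat_group_names <- c("marginal", "spectral", "lin_position", "lin_scale",
                      "en_orientation", "en_position", "en_scale")

#' Per-group statistic counts of a bank
#'
#' Closed-form number of raw parameters per statistic group; depends only on
#' the bank configuration, never on image content.
#'
#' @param bank A `filter_bank`.
#' @return Named integer vector over the 7 groups.
#' @export
stat_counts <- function(bank) {
  S <- bank$n_scales; O <- bank$n_orientations; K <- nrow(bank$offsets)
  c(marginal = 2L, spectral = S * O,
    lin_position = S * O * K, lin_scale = (S - 1L) * O,
    en_orientation = as.integer(S * choose(O, 2L)),
    en_position = S * O * K, en_scale = (S - 1L) * O)
}

# Pearson correlation between a map and its (dy, dx)-shifted copy over the
# valid overlap region. Maps that are constant up to numerical noise (e.g.
# the energy response to a pure grating) are treated as zero-variance and
# give 0, rather than correlating round-off error.
near_constant <- function(a) {
  stats::sd(a) <= 1e-9 * (max(abs(a)) + .Machine$double.xmin)
}

shift_cor <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ys <- max(1, 1 - dy):min(h, h - dy)
  xs <- max(1, 1 - dx):min(w, w - dx)
  a <- m[ys, xs]; b <- m[ys + dy, xs + dx]
  if (near_constant(a) || near_constant(b)) return(0)
  stats::cor(as.vector(a), as.vector(b))
}

safe_cor <- function(a, b) {
  if (near_constant(a) || near_constant(b)) return(0)
  stats::cor(as.vector(a), as.vector(b))
}

#' Grouped higher-order texture statistics of an image
#'
#' Computes the seven classical statistic groups: (1) marginal statistics
#' (pixel skewness and kurtosis); (2) spectral statistics (mean energy per
#' scale x orientation sub-band); (3) correlations of linear (even) filter
#' responses at neighboring positions within each sub-band; (4) at adjacent
#' scales; and correlations of energy responses at (5) orientation pairs
#' within a scale, (6) neighboring positions, and (7) adjacent scales.
#' A constant (zero-variance) image is degenerate: every group is reported
#' as zeros and the result carries a `degenerate` attribute.
#'
#' @param img Numeric matrix, each side at least 4x the largest filter
#'   wavelength of the bank.
#' @param bank A `filter_bank`.
#' @return A named list of 7 numeric vectors (one per group, in the order
#'   above), with per-entry label names; attribute `degenerate` is TRUE for
#'   constant input.
#' @export
compute_texture_stats <- function(img, bank = filter_bank()) {
  x <- as_pixels(img)
  if (min(dim(x)) < 4L * bank_support(bank)) {
    stop(sprintf("image (%dx%d) smaller than 4x the largest filter wavelength (%d px)",
                 nrow(x), ncol(x), bank_support(bank)))
  }
  S <- bank$n_scales; O <- bank$n_orientations
  counts <- stat_counts(bank)
  if (stats::sd(x) == 0) {
    out <- lapply(counts, function(k) stats::setNames(numeric(k), NULL))
    names(out) <- stat_group_names
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  h <- nrow(x); w <- ncol(x)
  tf <- bank_transfer(bank, h, w)
  Fx <- stats::fft(x - mean(x))
  resp <- lapply(tf, function(row) lapply(row, function(H) {
    stats::fft(Fx * H, inverse = TRUE) / (h * w)
  }))
  lin <- lapply(resp, function(row) lapply(row, Re))
  en <- lapply(resp, function(row) lapply(row, Mod))
  # Sub-bands whose response carries a negligible fraction of the stimulus
  # RMS (e.g. orientations orthogonal to a grating) are numerically silent:
  # correlating them would only amplify round-off, so their correlation
  # statistics are reported as 0.
  img_rms <- sqrt(mean((x - mean(x))^2))
  silent <- lapply(seq_len(S), function(s) vapply(seq_len(O), function(o)
    sqrt(mean(en[[s]][[o]]^2)) < 1e-4 * img_rms, TRUE))

  mu <- mean(x); s2 <- mean((x - mu)^2)
  marginal <- c(skewness = mean((x - mu)^3) / s2^1.5,
                kurtosis = mean((x - mu)^4) / s2^2)

  lab_so <- as.vector(outer(seq_len(S), seq_len(O),
                            function(s, o) sprintf("s%d_o%d", s, o)))
  spectral <- stats::setNames(as.vector(
    vapply(seq_len(O), function(o) vapply(seq_len(S), function(s)
      mean(en[[s]][[o]]^2), 0), numeric(S))), lab_so)

  offs <- bank$offsets
  pos_block <- function(maps) {
    vals <- numeric(0)
    for (o in seq_len(O)) for (s in seq_len(S)) {
      m <- maps[[s]][[o]]
      v <- if (silent[[s]][o]) numeric(nrow(offs)) else
        vapply(seq_len(nrow(offs)), function(k)
          shift_cor(m, offs$dy[k], offs$dx[k]), 0)
      names(v) <- sprintf("s%d_o%d_dy%d_dx%d", s, o, offs$dy, offs$dx)
      vals <- c(vals, v)
    }
    vals
  }
  lin_position <- pos_block(lin)
  en_position <- pos_block(en)

  # Cross-scale linear correlations must compare the fine even response with
  # the PHASE-DOUBLED coarse response, Re(c^2 / |c|): a plain correlation of
  # two linearly filtered maps is a function of the amplitude spectrum only
  # (Parseval) and would be blind to phase scrambling. Doubling the coarse
  # phase aligns it with a fine component of half the wavelength, which is
  # exactly the cross-scale phase structure scrambling destroys.
  lin_scale <- numeric(0)
  for (o in seq_len(O)) for (s in seq_len(S - 1L)) {
    v <- if (silent[[s]][o] || silent[[s + 1L]][o]) 0 else {
      cmap <- resp[[s + 1L]][[o]]
      safe_cor(lin[[s]][[o]], Re(cmap^2 / (Mod(cmap) + 1e-12)))
    }
    names(v) <- sprintf("s%d_s%d_o%d", s, s + 1L, o)
    lin_scale <- c(lin_scale, v)
  }
  en_scale <- numeric(0)
  for (o in seq_len(O)) for (s in seq_len(S - 1L)) {
    v <- if (silent[[s]][o] || silent[[s + 1L]][o]) 0 else
      safe_cor(en[[s]][[o]], en[[s + 1L]][[o]])
    names(v) <- sprintf("s%d_s%d_o%d", s, s + 1L, o)
    en_scale <- c(en_scale, v)
  }

  en_orientation <- numeric(0)
  for (s in seq_len(S)) for (o1 in seq_len(O - 1L)) for (o2 in (o1 + 1L):O) {
    v <- if (silent[[s]][o1] || silent[[s]][o2]) 0 else
      safe_cor(en[[s]][[o1]], en[[s]][[o2]])
    names(v) <- sprintf("s%d_o%d_o%d", s, o1, o2)
    en_orientation <- c(en_orientation, v)
  }

  out <- list(marginal = marginal, spectral = spectral,
              lin_position = lin_position, lin_scale = lin_scale,
              en_orientation = en_orientation, en_position = en_position,
              en_scale = en_scale)
  stopifnot(lengths(out) == counts)
  attr(out, "degenerate") <- FALSE
  out
}

#' Stack per-image statistics into a raw design matrix
#'
#' @param images List of numeric matrices.
#' @param bank A `filter_bank`.
#' @return List with `x` (images x parameters matrix, columns labelled
#'   `group:descriptor`) and `groups` (per-column group factor).
#' @export
stats_matrix <- function(images, bank = filter_bank()) {
  rows <- lapply(images, compute_texture_stats, bank = bank)
  counts <- stat_counts(bank)
  groups <- factor(rep(stat_group_names, counts), levels = stat_group_names)
  x <- do.call(rbind, lapply(rows, function(r) unlist(r, use.names = FALSE)))
  labels <- unlist(lapply(rows[[1]], names), use.names = FALSE)
  colnames(x) <- paste(groups, labels, sep = ":")
  list(x = x, groups = groups)
}
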