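#' Signed square root followed by z-score normalization
#'
#' Each raw statistic x is transformed to sign(x) * sqrt(|x|) and then
#' standardized to mean 0, standard deviation 1 over the fitted set.
#' Constant columns carry no information and are dropped (recorded in the
#' transform record).
#'
#' @param raw Numeric matrix, images x parameters, at least 2 rows.
#' @return List with `x` (transformed matrix over kept columns) and `record`
#'   (kept/dropped column indices, means, sds).
#' @export
signed_sqrt_zscore <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) < 2L) stop("need at least 2 rows to standardize")
  y <- sign(raw) * sqrt(abs(raw))
  sds <- apply(y, 2L, stats::sd)
  keep <- which(sds > 0)
  dropped <- which(sds == 0)
  y <- y[, keep, drop = FALSE]
  mus <- colMeans(y)
  sds <- sds[keep]
  z <- sweep(sweep(y, 2L, mus), 2L, sds, "/")
  list(x = z, record = list(kept = keep, dropped = dropped,
                            means = mus, sds = sds))
}

#' Groupwise principal component analysis
#'
#' Runs PCA separately on each group of (already standardized) parameters
#' and keeps, per group, the smallest number of leading components whose
#' cumulative explained variance exceeds `var_threshold`. The concatenated
#' scores form the design matrix for the modulation regression.
#'
#' @param z Standardized matrix (output of [signed_sqrt_zscore()]).
#' @param groups Factor or vector of length `ncol(z)` assigning each column
#'   to a group.
#' @param var_threshold Fraction of variance to retain per group, in (0, 1).
#' @return A `stat_design` object: list with `design` (scores matrix),
#'   `group_spans` (named list of column index vectors), `variance_retained`
#'   and `n_components` per group, and the `rotations` needed to project new
#'   data.
#' @export
groupwise_pca <- function(z, groups, var_threshold = 0.9) {
  if (var_threshold <= 0 || var_threshold >= 1) {
    stop("var_threshold must be in (0, 1)")
  }
  groups <- as.factor(groups)
  if (length(groups) != ncol(z)) stop("groups must label every column of z")
  design <- NULL
  spans <- list(); vr <- c(); nc <- c(); rot <- list(); centers <- list()
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (!length(idx)) next
    xg <- z[, idx, drop = FALSE]
    pc <- stats::prcomp(xg, center = TRUE, scale. = FALSE)
    ev <- pc$sdev^2
    if (sum(ev) == 0) {
      k <- 1L
      vr[g] <- 1
    } else {
      cum <- cumsum(ev) / sum(ev)
      k <- which(cum > var_threshold)[1L]
      if (is.na(k)) k <- length(ev)
      vr[g] <- cum[k]
    }
    sc <- pc$x[, seq_len(k), drop = FALSE]
    colnames(sc) <- paste0(g, "_pc", seq_len(k))
    spans[[g]] <- ncol(design %||% matrix(nrow = nrow(z), ncol = 0)) + seq_len(k)
    design <- cbind(design, sc)
    nc[g] <- k
    rot[[g]] <- pc$rotation[, seq_len(k), drop = FALSE]
    centers[[g]] <- pc$center
  }
  structure(list(design = design, group_spans = spans,
                 variance_retained = vr, n_components = nc,
                 rotations = rot, centers = centers,
                 var_threshold = var_threshold),
            class = "stat_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.stat_design <- function(x, ...) {
  cat(sprintf("stat design: %d rows x %d components (%s)\n",
              nrow(x$design), ncol(x$design),
              paste(sprintf("%s=%d", names(x$n_components), x$n_components),
                    collapse = ", ")))
  invisible(x)
}

#' Build a regression design from raw texture statistics
#'
#' Convenience composition of [signed_sqrt_zscore()] and [groupwise_pca()].
#'
#' @param raw Raw statistics matrix (e.g. from [stats_matrix()]).
#' @param groups Per-column group labels.
#' @param var_threshold Passed to [groupwise_pca()].
#' @return A `stat_design`; the transform record is attached as `transform`.
#' @export
make_design <- function(raw, groups, var_threshold = 0.9) {
  tr <- signed_sqrt_zscore(raw)
  d <- groupwise_pca(tr$x, droplevels(as.factor(groups)[tr$record$kept]),
                     var_threshold)
  d$transform <- tr$record
  d
}

#' Ordinary least-squares fit of per-pair modulation on image statistics
#'
#' @param design A `stat_design` (or plain matrix).
#' @param pmi_per_pair Response vector, one value per image pair.
#' @return List with the fitted `lm` model, `coefficients`, `fitted` values
#'   and `r_squared`.
#' @export
fit_pmi_regression <- function(design, pmi_per_pair) {
  X <- if (inherits(design, "stat_design")) design$design else as.matrix(design)
  y <- as.numeric(pmi_per_pair)
  if (nrow(X) != length(y)) stop("design rows must match the response length")
  if (nrow(X) <= ncol(X)) stop("need more rows than columns for OLS")
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  tss <- sum((y - mean(y))^2)
  list(model = fit, coefficients = cf, fitted = fitted(fit),
       r_squared = 1 - sum(stats::residuals(fit)^2) / tss)
}

r2_subset <- function(X, y, cols, tss) {
  if (!length(cols)) return(0)
  fit <- stats::lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / tss
}

#' Relative importance by averaging over orderings (LMG)
#'
#' Decomposes the full-model R^2 over predictor groups: the contribution of
#' a group is the average, over all orderings in which groups can enter the
#' model, of the R^2 increment when that group is added. Computed exactly
#' via the subset identity (weights |S|! (G-|S|-1)! / G!) rather than by
#' enumerating orderings, at cost 2^G, so the number of groups is capped at
#' 12. Contributions sum to the full-model R^2; percentages sum to 100.
#'
#' @param design A `stat_design` (groups taken from its `group_spans`) or a
#'   plain matrix with a `group_spans` list supplied.
#' @param target Response vector.
#' @param group_spans Optional named list of column index vectors.
#' @return Data frame with `group`, `contribution` (R^2 units) and `percent`
#'   (of full-model R^2).
#' @export
lmg_contributions <- function(design, target, group_spans = NULL) {
  if (inherits(design, "stat_design")) {
    X <- design$design
    group_spans <- group_spans %||% design$group_spans
  } else {
    X <- as.matrix(design)
    if (is.null(group_spans)) stop("group_spans required for a plain matrix")
  }
  y <- as.numeric(target)
  G <- length(group_spans)
  if (G > 12L) stop("more than 12 groups: exact enumeration (2^G subsets) refused")
  tss <- sum((y - mean(y))^2)
  r2 <- numeric(2^G)  # indexed by bitmask + 1
  for (m in 0:(2^G - 1L)) {
    inset <- which(bitwAnd(m, bitwShiftL(1L, 0:(G - 1L))) != 0L)
    cols <- unlist(group_spans[inset], use.names = FALSE)
    r2[m + 1L] <- r2_subset(X, y, cols, tss)
  }
  lfact <- lgamma(seq_len(G + 1L))  # log factorials 0!..G!
  wt <- function(k) exp(lfact[k + 1L] + lfact[G - k] - lfact[G + 1L])
  contrib <- numeric(G)
  for (g in seq_len(G)) {
    bit_g <- bitwShiftL(1L, g - 1L)
    for (m in 0:(2^G - 1L)) {
      if (bitwAnd(m, bit_g) != 0L) next
      k <- sum(bitwAnd(m, bitwShiftL(1L, 0:(G - 1L))) != 0L)
      contrib[g] <- contrib[g] + wt(k) * (r2[m + bit_g + 1L] - r2[m + 1L])
    }
  }
  full <- r2[2^G]
  data.frame(group = names(group_spans), contribution = contrib,
             percent = 100 * contrib / full, row.names = NULL)
}

#' Per-group correlation of statistics between CM and SM images
#'
#' For each statistic group, computes the raw statistics of every CM and SM
#' image, fits the signed-sqrt/z-score transform and the group PCA on the
#' pooled set, projects both roles onto the leading principal component, and
#' reports the Pearson correlation between paired CM and SM projections.
#' On phase-scramble corpora the position groups are expected to correlate
#' far more strongly than the scale groups, because position correlations
#' within a sub-band are insensitive to phase shuffling while cross-scale
#' alignment is destroyed by it.
#'
#' @param corpus A `stimulus_corpus` with at least 10 pairs.
#' @param bank A `filter_bank`.
#' @return List with `table` (data frame: group, r, degenerate flag) and
#'   `scatter` (per group, a data frame of paired CM/SM PC1 scores).
#' @export
group_correlation_cm_sm <- function(corpus, bank = filter_bank()) {
  n <- length(corpus$pairs)
  if (n < 10L) stop("need at least 10 pairs")
  cm_raw <- stats_matrix(corpus_images(corpus, "cm"), bank)
  sm_raw <- stats_matrix(corpus_images(corpus, "sm"), bank)
  pooled <- rbind(cm_raw$x, sm_raw$x)
  tr <- signed_sqrt_zscore(pooled)
  groups <- droplevels(as.factor(cm_raw$groups)[tr$record$kept])
  z_cm <- tr$x[seq_len(n), , drop = FALSE]
  z_sm <- tr$x[n + seq_len(n), , drop = FALSE]
  out <- data.frame(group = levels(groups), r = NA_real_, degenerate = FALSE)
  scatter <- list()
  for (i in seq_along(out$group)) {
    g <- out$group[i]
    idx <- which(groups == g)
    pc <- stats::prcomp(tr$x[, idx, drop = FALSE], center = TRUE)
    proj <- function(m) {
      sweep(m[, idx, drop = FALSE], 2L, pc$center) %*% pc$rotation[, 1L]
    }
    a <- drop(proj(z_cm)); b <- drop(proj(z_sm))
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      out$degenerate[i] <- TRUE
      out$r[i] <- 0
    } else {
      out$r[i] <- stats::cor(a, b)
    }
    scatter[[g]] <- data.frame(cm = a, sm = b)
  }
  list(table = out, scatter = scatter)
}
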