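check_permutation <- function(x, n) {
  x <- as.integer(x)
  tab <- tabulate(x[x >= 1L & x <= n], n)
  if (any(tab != 1L) || length(x) != n) {
    dup <- which(tab > 1L); mis <- which(tab == 0L)
    stop(sprintf("not a permutation of 1..%d (duplicated: %s; missing: %s)", n,
                 paste(dup, collapse = ","), paste(mis, collapse = ",")))
  }
  x
}

#' Ranking distance between two orderings
#'
#' For permutations X and Y of 1..n, `D = sum_i |log(i / f_Y(x_i))|` where
#' `f_Y(x_i)` is the position of `x_i` within Y (natural logarithm). D is a
#' proper metric on permutations: zero iff X = Y, symmetric, and satisfying
#' the triangle inequality. Small values indicate consistent orderings.
#'
#' @param x,y Integer permutations of 1..n.
#' @return Nonnegative distance.
#' @export
ranking_distance <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("permutations must have the same length")
  x <- check_permutation(x, n)
  y <- check_permutation(y, n)
  fy <- match(x, y)
  sum(abs(log(seq_len(n) / fy)))
}

#' Permutation test for consistency of two orderings
#'
#' The null distribution is the ranking distance between two independent
#' uniformly random permutations of 1..n; the p-value is the fraction of
#' null distances strictly smaller than the observed one (small distances =
#' consistent orderings, so small p rejects inconsistency). No continuity
#' correction is applied unless `corrected = TRUE` (which uses
#' `(count + 1) / (n_samples + 1)`).
#'
#' @param observed Observed ranking distance.
#' @param n Permutation length (>= 2).
#' @param n_samples Monte-Carlo sample count (>= 1).
#' @param seed Integer seed.
#' @param corrected Apply the +1 continuity correction.
#' @return List with `p`, its Monte-Carlo standard error `se`, `n_samples`
#'   and `seed`.
#' @export
rd_permutation_test <- function(observed, n, n_samples = 1e6, seed = 1L,
                                corrected = FALSE) {
  if (n < 2L) stop("n must be >= 2")
  if (n_samples < 1) stop("n_samples must be >= 1")
  withr::local_seed(seed)
  null <- rd_null_sample_cpp(as.integer(n), as.integer(n_samples))
  k <- sum(null < observed)
  p <- if (corrected) (k + 1) / (n_samples + 1) else k / n_samples
  list(p = p, se = sqrt(p * (1 - p) / n_samples),
       n_samples = as.integer(n_samples), seed = seed)
}

#' Rank texture families by PMI
#'
#' Decreasing order of per-family PMI; ties broken by ascending family
#' index.
#'
#' @param pmi_per_family Numeric vector (no NAs).
#' @return Integer permutation: family indices from highest to lowest PMI.
#' @export
rank_families_by_pmi <- function(pmi_per_family) {
  if (anyNA(pmi_per_family)) stop("undefined PMIs cannot be ranked")
  order(-pmi_per_family, seq_along(pmi_per_family))
}

#' Random sampling t-test (RST)
#'
#' Emulates finite electrode sampling: per repetition, `n_sample` units are
#' drawn without replacement from each group independently (or from one
#' group, tested against zero), a standard t-test is run, and the final
#' p-value is the mean over repetitions. Tests are one-tailed by default
#' with the alternative that group A's mean exceeds group B's (or zero).
#'
#' @param group_a Numeric vector of unit values.
#' @param group_b Numeric vector, or `"zero"` for a one-sample test against
#'   0.
#' @param n_sample Units drawn per group per repetition (reduced to the
#'   group size with a warning when a group is smaller).
#' @param reps Number of repetitions.
#' @param tail `"one"` or `"two"`.
#' @param paired Paired t-test (groups must align).
#' @param seed Integer seed.
#' @return List with `p` (averaged), `p_values` (per repetition), `n_sample`
#'   and `reps`.
#' @export
random_sampling_ttest <- function(group_a, group_b = "zero", n_sample = 100L,
                                  reps = 500L, tail = c("one", "two"),
                                  paired = FALSE, seed = 1L) {
  tail <- match.arg(tail)
  one_sample <- identical(group_b, "zero")
  if (!length(group_a) || (!one_sample && !length(group_b))) {
    stop("empty group")
  }
  sizes <- c(length(group_a), if (!one_sample) length(group_b))
  if (any(sizes < n_sample)) {
    n_sample <- min(sizes)
    warning(sprintf("group smaller than n_sample; reduced to %d", n_sample))
  }
  alt <- if (tail == "one") "greater" else "two.sided"
  withr::local_seed(seed)
  ps <- vapply(seq_len(reps), function(r) {
    a <- sample(group_a, n_sample)
    if (one_sample) {
      stats::t.test(a, mu = 0, alternative = alt)$p.value
    } else if (paired) {
      ix <- sample.int(length(group_a), n_sample)
      stats::t.test(group_a[ix], group_b[ix], paired = TRUE,
                    alternative = alt)$p.value
    } else {
      b <- sample(group_b, n_sample)
      stats::t.test(a, b, alternative = alt)$p.value
    }
  }, 0)
  list(p = mean(ps), p_values = ps, n_sample = n_sample, reps = reps)
}

#' Per-unit randomization test for positive modulation
#'
#' For each unit, the CM/SM roles of its stimulus pairs are shuffled (by
#' default an independent within-pair role swap with probability 1/2, which
#' preserves the pair structure; `global = TRUE` instead permutes all labels
#' jointly and re-pairs in order), the modulation index is recomputed per
#' shuffle, and the p-value is the fraction of the null strictly larger
#' than the observed index. A unit is significantly positively modulated
#' when this fraction is below `alpha`.
#'
#' @param R A `response_matrix`.
#' @param n_perm Number of shuffles (default 10000).
#' @param alpha Significance threshold (default 0.05).
#' @param seed Integer seed.
#' @param global Use the global-relabel variant.
#' @return Data frame: `unit`, `observed`, `p`, `significant`, `n_valid`.
#'   Units with no valid pairs carry `NA` and are counted in attribute
#'   `n_skipped`.
#' @export
unit_randomization_test <- function(R, n_perm = 10000L, alpha = 0.05,
                                    seed = 1L, global = FALSE) {
  cm <- cm_block(R); sm <- sm_block(R)
  withr::local_seed(seed)
  if (!global) {
    res <- unit_randomization_cpp(cm, sm, as.integer(n_perm))
  } else {
    res <- global_relabel_test(cm, sm, as.integer(n_perm))
  }
  out <- data.frame(unit = seq_len(nrow(cm)), observed = res$observed,
                    p = res$p,
                    significant = !is.na(res$p) & res$p < alpha,
                    n_valid = res$n_valid)
  attr(out, "n_skipped") <- sum(res$n_valid == 0L)
  out
}

# Global relabeling: permute the 2P stimuli jointly, re-pair consecutive
# columns, recompute each unit's index. Interpreted-R fallback variant kept
# simple; the within-pair swap is the default and the fast path.
global_relabel_test <- function(cm, sm, n_perm) {
  U <- nrow(cm); P <- ncol(cm)
  all_resp <- cbind(cm, sm)
  obs <- numeric(U); nv <- integer(U)
  for (u in seq_len(U)) {
    r <- modulation_index(cm[u, ], sm[u, ])
    obs[u] <- r$index; nv[u] <- r$n_valid
  }
  larger <- numeric(U)
  for (b in seq_len(n_perm)) {
    ix <- sample.int(2L * P)
    a <- all_resp[, ix[seq_len(P)], drop = FALSE]
    bb <- all_resp[, ix[P + seq_len(P)], drop = FALSE]
    tot <- a + bb
    d <- (a - bb) / tot
    d[tot == 0] <- NA
    nullv <- rowMeans(d, na.rm = TRUE)
    larger <- larger + (!is.na(nullv) & !is.na(obs) & nullv > obs)
  }
  list(observed = obs, p = ifelse(nv > 0L, larger / n_perm, NA_real_),
       n_valid = nv)
}
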