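#' Response matrix of model units to a paired stimulus set
#'
#' Units x stimuli nonnegative responses, with the CM/SM pairing recorded:
#' `pairing` has one row per pair holding the column indices of its CM and
#' SM stimuli and the pair's texture family.
#'
#' @param responses Nonnegative finite numeric matrix (units x stimuli).
#' @param pairing Data frame with columns `pair_id`, `cm_col`, `sm_col`,
#'   `family_id`.
#' @param layer Optional layer label.
#' @param provenance Optional list (model, seed, ...).
#' @return A `response_matrix` object.
#' @export
response_matrix <- function(responses, pairing, layer = NA_character_,
                            provenance = list()) {
  responses <- as.matrix(responses)
  if (any(!is.finite(responses)) || any(responses < 0)) {
    stop("responses must be finite and nonnegative")
  }
  cols <- c(pairing$cm_col, pairing$sm_col)
  if (anyDuplicated(cols) || !setequal(cols, seq_len(ncol(responses)))) {
    stop("every stimulus column must belong to exactly one pair and one role")
  }
  structure(list(responses = responses, pairing = pairing, layer = layer,
                 provenance = provenance),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response matrix: %d units x %d stimuli (%d pairs), layer %s\n",
              nrow(x$responses), ncol(x$responses), nrow(x$pairing), x$layer))
  invisible(x)
}

cm_block <- function(R) R$responses[, R$pairing$cm_col, drop = FALSE]
sm_block <- function(R) R$responses[, R$pairing$sm_col, drop = FALSE]

#' Record unit responses of a big layer to a stimulus corpus
#'
#' Runs the forward pass on every preprocessed stimulus and flattens the
#' requested big layer's maps into unit rows. Columns are all CM stimuli
#' followed by all SM stimuli, with the pairing recorded.
#'
#' @param net,dicts Trained network (see [train_shmax()]).
#' @param corpus A `stimulus_corpus`.
#' @param big_layer Big-layer index.
#' @param preprocess_fn Applied to each image before the forward pass;
#'   defaults to identity (use [preprocess()] for the full protocol).
#' @return A `response_matrix`, or (for a vector `big_layer`) a named list
#'   of them computed from a single forward pass per stimulus.
#' @export
extract_responses <- function(net, dicts, corpus, big_layer,
                              preprocess_fn = identity) {
  n <- length(corpus$pairs)
  n_big <- max(net$grouping)
  if (any(big_layer > n_big)) stop("big layer without outputs")
  one <- function(img) {
    out <- forward(net, dicts, preprocess_fn(img))
    lapply(out$big[big_layer], as.vector)
  }
  cm <- lapply(corpus$pairs, function(p) one(p$cm))
  sm <- lapply(corpus$pairs, function(p) one(p$sm))
  pairing <- data.frame(pair_id = vapply(corpus$pairs, `[[`, 1L, "pair_id"),
                        cm_col = seq_len(n), sm_col = n + seq_len(n),
                        family_id = vapply(corpus$pairs, `[[`, 1L, "family_id"))
  res <- lapply(seq_along(big_layer), function(i) {
    resp <- cbind(vapply(cm, `[[`, cm[[1L]][[i]], i),
                  vapply(sm, `[[`, cm[[1L]][[i]], i))
    response_matrix(resp, pairing,
                    layer = sprintf("LAYER%d", big_layer[i]),
                    provenance = list(model = "shmax"))
  })
  if (length(big_layer) == 1L) res[[1L]] else
    stats::setNames(res, sprintf("LAYER%d", big_layer))
}

#' Modulation index of one unit
#'
#' Per pair, `(r_cm - r_sm) / (r_cm + r_sm)`; pairs where both responses are
#' exactly zero are excluded, and the index is the mean over the remaining
#' pairs. A unit with no valid pair is excluded (returns `NA` with
#' `n_valid = 0`).
#'
#' @param unit_cm,unit_sm Nonnegative response vectors over pairs (equal
#'   length).
#' @return List with `index` (in `[-1, 1]` or `NA`) and `n_valid`.
#' @export
modulation_index <- function(unit_cm, unit_sm) {
  if (length(unit_cm) != length(unit_sm)) stop("pair vectors differ in length")
  tot <- unit_cm + unit_sm
  valid <- tot > 0
  if (!any(valid)) return(list(index = NA_real_, n_valid = 0L))
  d <- (unit_cm[valid] - unit_sm[valid]) / tot[valid]
  list(index = mean(d), n_valid = sum(valid))
}

#' Modulation indices and PMI of a response matrix
#'
#' Vectorized over units; optionally restricted to the pairs of one texture
#' family (all non-excluded units are always used).
#'
#' @param R A `response_matrix`.
#' @param family Optional family id.
#' @return A `modulation_result`: data frame `units` (index, n_valid,
#'   excluded), `pmi` (mean index over non-excluded units, `NA` if all are
#'   excluded), and `pmi_by_family`.
#' @export
modulation_result <- function(R, family = NULL) {
  cm <- cm_block(R); sm <- sm_block(R)
  if (!is.null(family)) {
    keep <- R$pairing$family_id == family
    cm <- cm[, keep, drop = FALSE]; sm <- sm[, keep, drop = FALSE]
  }
  tot <- cm + sm
  d <- (cm - sm) / tot
  d[tot == 0] <- NA
  n_valid <- rowSums(!is.na(d))
  idx <- rowMeans(d, na.rm = TRUE)
  idx[n_valid == 0L] <- NA_real_
  units <- data.frame(index = idx, n_valid = n_valid,
                      excluded = n_valid == 0L)
  fams <- sort(unique(R$pairing$family_id))
  pbf <- if (is.null(family)) {
    vapply(fams, function(f) modulation_result(R, family = f)$pmi, 0)
  } else NULL
  structure(list(units = units,
                 pmi = if (all(units$excluded)) NA_real_ else
                   mean(idx[!units$excluded]),
                 pmi_by_family = if (!is.null(pbf))
                   stats::setNames(pbf, fams) else NULL),
            class = "modulation_result")
}

#' Population modulation index
#'
#' Mean modulation index over the non-excluded units of a set.
#'
#' @param mod A `modulation_result` (or a `response_matrix`, which is
#'   converted first).
#' @param family Optional family id: PMI restricted to that family's pairs.
#' @return Scalar PMI (`NA` if every unit is excluded).
#' @export
pmi <- function(mod, family = NULL) {
  if (inherits(mod, "response_matrix")) {
    return(modulation_result(mod, family = family)$pmi)
  }
  if (!is.null(family)) return(mod$pmi_by_family[[as.character(family)]])
  mod$pmi
}

#' Lifetime sparseness of a unit
#'
#' `S = 1 - (E[r])^2 / E[r^2]`, the expectation across stimuli: 0 for a
#' constant response, approaching 1 for a highly selective unit. An all-zero
#' unit is undefined (`NA`).
#'
#' @param r Nonnegative response vector over at least 2 stimuli.
#' @return Sparseness in `[0, 1)`, or `NA` for an all-zero unit.
#' @export
lifetime_sparseness <- function(r) {
  if (length(r) < 2L) stop("need at least 2 stimuli")
  m2 <- mean(r^2)
  if (m2 == 0) return(NA_real_)
  1 - mean(r)^2 / m2
}

#' Non-firing sparseness: fraction of stimuli with exactly zero response
#'
#' "Did not respond" means exactly zero by default (rectified/nonnegative
#' coding yields hard zeros); `eps` allows a threshold.
#'
#' @param r Response vector.
#' @param eps Zero threshold (default 0).
#' @return Fraction in `[0, 1]`.
#' @export
nonfiring_sparseness <- function(r, eps = 0) mean(r <= eps)

#' Lifetime kurtosis of a unit
#'
#' The fourth standardized moment `E[(r - mu)^4] / sigma^4` (not excess
#' kurtosis). Undefined (`NA`) for zero-variance responses.
#'
#' @param r Response vector.
#' @return Kurtosis, or `NA`.
#' @export
lifetime_kurtosis <- function(r) {
  mu <- mean(r); s2 <- mean((r - mu)^2)
  if (s2 == 0) return(NA_real_)
  mean((r - mu)^4) / s2^2
}

#' Population sparseness
#'
#' The same functional as [lifetime_sparseness()] with the expectation taken
#' across units for one stimulus; the corpus summary is the mean over
#' stimuli. Invariant to positive rescaling of a stimulus column.
#'
#' @param R A `response_matrix` (at least 2 units).
#' @param stimulus Optional stimulus column index; when omitted, returns the
#'   per-stimulus vector with the summary mean as attribute `mean`.
#' @return Sparseness value(s).
#' @export
population_sparseness <- function(R, stimulus = NULL) {
  X <- R$responses
  if (nrow(X) < 2L) stop("need at least 2 units")
  one <- function(col) {
    m2 <- mean(col^2)
    if (m2 == 0) return(NA_real_)
    1 - mean(col)^2 / m2
  }
  if (!is.null(stimulus)) return(one(X[, stimulus]))
  v <- apply(X, 2L, one)
  attr(v, "mean") <- mean(v, na.rm = TRUE)
  v
}

#' Normalize each unit's responses by its maximum
#'
#' Rows are scaled so the maximum response over all CM and SM stimuli is 1;
#' all-zero rows are passed through unchanged and flagged.
#'
#' @param R A `response_matrix`.
#' @return A `response_matrix` with attribute `zero_rows` (indices).
#' @export
normalize_per_unit <- function(R) {
  mx <- apply(R$responses, 1L, max)
  zero <- which(mx == 0)
  scl <- ifelse(mx > 0, mx, 1)
  out <- response_matrix(R$responses / scl, R$pairing, R$layer, R$provenance)
  attr(out, "zero_rows") <- zero
  out
}

#' Lifetime sparseness of every unit over a seeded stimulus draw
#'
#' Emulates evaluating sparseness on a fixed-size random draw of stimuli:
#' samples `n_stimuli` columns without replacement (capped at the number of
#' columns) and applies the chosen measure per unit.
#'
#' @param R A `response_matrix`.
#' @param n_stimuli Draw size (default 2000).
#' @param measure One of `"lifetime"`, `"nonfiring"`, `"kurtosis"`.
#' @param seed Integer seed.
#' @return Numeric vector over units.
#' @export
unit_sparseness <- function(R, n_stimuli = 2000L,
                            measure = c("lifetime", "nonfiring", "kurtosis"),
                            seed = 1L) {
  measure <- match.arg(measure)
  withr::local_seed(seed)
  n <- min(n_stimuli, ncol(R$responses))
  cols <- sample.int(ncol(R$responses), n)
  f <- switch(measure, lifetime = lifetime_sparseness,
              nonfiring = nonfiring_sparseness, kurtosis = lifetime_kurtosis)
  apply(R$responses[, cols, drop = FALSE], 1L, f)
}
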