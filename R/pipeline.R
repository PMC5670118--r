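#' Per-pair population modulation
#'
#' For each CM-SM pair, the mean over units of the per-pair index
#' `(r_cm - r_sm) / (r_cm + r_sm)` (both-zero unit/pair entries excluded) --
#' the response variable of the statistics regression.
#'
#' @param R A `response_matrix`.
#' @return Numeric vector, one value per pair.
#' @export
pair_modulation <- function(R) {
  cm <- cm_block(R); sm <- sm_block(R)
  tot <- cm + sm
  d <- (cm - sm) / tot
  d[tot == 0] <- NA
  colMeans(d, na.rm = TRUE)
}

report_header <- function(name, config, seed) {
  config_plain <- rapply(config, function(x) x, how = "replace")
  list(experiment = name, seed = seed,
       hash = rlang::hash(list(name = name, config = config_plain)),
       timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
}

check_corpus <- function(corpus) {
  if (!inherits(corpus, "stimulus_corpus") || !length(corpus$pairs)) {
    stop("empty or invalid stimulus corpus")
  }
  invisible(corpus)
}

training_images <- function(corpus, role, n_train, seed) {
  imgs <- corpus_images(corpus, role)
  withr::local_seed(seed)
  imgs[sample.int(length(imgs), min(n_train, length(imgs)))]
}

#' Baseline experiment: layerwise preference for structured textures
#'
#' Trains a SHMAX network on structured (CM-role) images of the corpus,
#' records every big layer's responses to all CM-SM pairs, and reports per
#' layer: the PMI, the percentage of units with a significant positive
#' modulation index (per-unit randomization test), random-sampling t-tests
#' of each layer against zero and against the layer below, the per-family
#' PMI table, and sparseness-modulation scatter data.
#'
#' @param corpus A `stimulus_corpus`.
#' @param net A `network_spec` (default [shmax_spec()]).
#' @param seed Integer seed for training and tests.
#' @param random_weights Replace trained dictionaries by random unit-norm
#'   atoms (the random-weight control).
#' @param n_train Training images drawn from the corpus.
#' @param n_per_image,n_iters Training budget.
#' @param n_perm Shuffles for the per-unit randomization test.
#' @param rst_n,rst_reps Random-sampling t-test draw size and repetitions.
#' @return A report list (tables are data frames); see Details.
#' @export
run_baseline <- function(corpus, net = shmax_spec(), seed = 1L,
                         random_weights = FALSE, n_train = 20L,
                         n_per_image = 100L, n_iters = 10L, n_perm = 2000L,
                         rst_n = 100L, rst_reps = 500L) {
  check_corpus(corpus)
  cfg <- list(net = net, random_weights = random_weights, n_train = n_train,
              n_per_image = n_per_image, n_iters = n_iters, n_perm = n_perm,
              rst_n = rst_n, rst_reps = rst_reps)
  dicts <- train_shmax(net, training_images(corpus, "cm", n_train, seed),
                       seed = seed, n_per_image = n_per_image,
                       n_iters = n_iters)
  if (random_weights) dicts <- randomize_weights(dicts, seed = seed + 7L)
  n_big <- max(net$grouping)
  layers <- data.frame(big_layer = seq_len(n_big), pmi = NA_real_,
                       pct_significant = NA_real_, rst_p_vs_zero = NA_real_,
                       rst_p_vs_below = NA_real_, n_units = NA_integer_,
                       mean_lifetime_sparseness = NA_real_)
  fam_tab <- NULL; scatter <- list(); idx_by_layer <- list()
  Rs <- extract_responses(net, dicts, corpus, seq_len(n_big))
  for (b in seq_len(n_big)) {
    R <- Rs[[b]]
    mod <- modulation_result(R)
    keep <- !mod$units$excluded
    idx <- mod$units$index[keep]
    idx_by_layer[[b]] <- idx
    rt <- unit_randomization_test(R, n_perm = n_perm, seed = seed + 50L + b)
    ls <- unit_sparseness(R, measure = "lifetime", seed = seed + 70L + b)
    layers$pmi[b] <- mod$pmi
    layers$n_units[b] <- sum(keep)
    layers$pct_significant[b] <- 100 * mean(rt$significant[keep])
    layers$mean_lifetime_sparseness[b] <- mean(ls[keep], na.rm = TRUE)
    layers$rst_p_vs_zero[b] <- random_sampling_ttest(
      idx, "zero", n_sample = rst_n, reps = rst_reps, seed = seed + 90L + b)$p
    if (b > 1L) {
      layers$rst_p_vs_below[b] <- random_sampling_ttest(
        idx, idx_by_layer[[b - 1L]], n_sample = rst_n, reps = rst_reps,
        seed = seed + 110L + b)$p
    }
    fam_tab <- rbind(fam_tab, data.frame(
      big_layer = b, family_id = as.integer(names(mod$pmi_by_family)),
      pmi = unname(mod$pmi_by_family)))
    scatter[[b]] <- data.frame(big_layer = b, unit = which(keep),
                               sparseness = ls[keep], index = idx)
  }
  list(header = report_header("baseline", cfg, seed), layers = layers,
       pmi_by_family = fam_tab, scatter = do.call(rbind, scatter),
       dicts = dicts, net = net)
}

set_big_lambda <- function(net, big_layer, lambda) {
  for (l in seq_along(net$layers)) {
    if (net$grouping[l] == big_layer &&
        net$layers[[l]]$kind == "sparse_coding") {
      net$layers[[l]]$lambda <- lambda
    }
  }
  net
}

#' Sparseness sweep: vary the coding penalty of one big layer
#'
#' For each lambda in the sweep, trains `n_models` networks differing only
#' in the swept layer's penalty, and reports that layer's mean lifetime
#' sparseness, mean non-firing sparseness and PMI, together with a
#' quadratic fit of PMI on sparseness across the sweep.
#'
#' @param corpus A `stimulus_corpus`.
#' @param net Baseline `network_spec`.
#' @param big_layer Big layer whose penalty is swept.
#' @param lambdas Sweep values (default the conventional
#'   `{0.01, 0.02, 0.05, 0.1, 0.25, 0.35, 0.45}`).
#' @param n_models Models per setting (paper protocol: 10).
#' @param seed Integer seed.
#' @param ... Passed to [run_baseline()]'s training arguments.
#' @inheritParams run_baseline
#' @return Report list with `sweep` (per lambda x model), `summary` (per
#'   lambda means) and `quadratic_fit` coefficients (or a note when the
#'   sweep has a single point).
#' @export
run_lambda_sweep <- function(corpus, net = shmax_spec(), big_layer = NULL,
                             lambdas = c(0.01, 0.02, 0.05, 0.1, 0.25, 0.35, 0.45),
                             n_models = 10L, seed = 1L, n_train = 20L,
                             n_per_image = 100L, n_iters = 10L) {
  check_corpus(corpus)
  if (is.null(big_layer)) stop("the swept big layer must be named")
  cfg <- list(net = net, big_layer = big_layer, lambdas = lambdas,
              n_models = n_models)
  rows <- NULL
  for (li in seq_along(lambdas)) {
    net_l <- set_big_lambda(net, big_layer, lambdas[li])
    for (m in seq_len(n_models)) {
      s <- seed + 1000L * li + m
      dicts <- train_shmax(net_l, training_images(corpus, "cm", n_train, s),
                           seed = s, n_per_image = n_per_image,
                           n_iters = n_iters)
      R <- extract_responses(net_l, dicts, corpus, big_layer)
      ls <- unit_sparseness(R, measure = "lifetime", seed = s)
      nf <- unit_sparseness(R, measure = "nonfiring", seed = s)
      rows <- rbind(rows, data.frame(
        lambda = lambdas[li], model = m, pmi = pmi(R),
        lifetime_sparseness = mean(ls, na.rm = TRUE),
        nonfiring_sparseness = mean(nf, na.rm = TRUE)))
    }
  }
  summary <- do.call(rbind, lapply(split(rows, rows$lambda), function(d) {
    data.frame(lambda = d$lambda[1L], pmi = mean(d$pmi, na.rm = TRUE),
               lifetime_sparseness = mean(d$lifetime_sparseness),
               nonfiring_sparseness = mean(d$nonfiring_sparseness))
  }))
  fit <- if (length(unique(rows$lambda)) >= 3L) {
    stats::coef(stats::lm(pmi ~ lifetime_sparseness + I(lifetime_sparseness^2),
                          data = summary))
  } else {
    "sweep has fewer than 3 distinct penalties; quadratic fit skipped"
  }
  list(header = report_header("lambda_sweep", cfg, seed), sweep = rows,
       summary = summary, quadratic_fit = fit)
}

#' Receptive-field control experiment
#'
#' Builds the two-path model (see [build_two_path()]), trains `n_models`
#' instances, and compares the PMIs of set a (upper layer) against set b
#' (lower layer, same receptive-field size) with a one-tailed paired t-test
#' over models, and set b against set c (same layer, smaller receptive
#' field) with a two-tailed paired t-test.
#'
#' @param corpus A `stimulus_corpus`.
#' @param net Baseline `network_spec`.
#' @param lower_big,upper_big Consecutive big layers to split.
#' @param n_models Models trained (paper protocol: 10).
#' @inheritParams run_baseline
#' @return Report list with per-model PMIs, the receptive-field sizes, and
#'   the two paired tests.
#' @export
run_rf_control <- function(corpus, net = shmax_spec(), lower_big = 1L,
                           upper_big = 2L, n_models = 10L, seed = 1L,
                           n_train = 20L, n_per_image = 100L, n_iters = 10L) {
  check_corpus(corpus)
  tp <- build_two_path(net, lower_big, upper_big)
  stopifnot(tp$rf[["a"]] == tp$rf[["b"]], tp$rf[["b"]] > tp$rf[["c"]])
  cfg <- list(net = net, lower_big = lower_big, upper_big = upper_big,
              n_models = n_models)
  rows <- NULL
  for (m in seq_len(n_models)) {
    s <- seed + 31L * m
    dicts <- train_two_path(tp, training_images(corpus, "cm", n_train, s),
                            seed = s, n_per_image = n_per_image,
                            n_iters = n_iters)
    n <- length(corpus$pairs)
    fwd_cm <- lapply(corpus$pairs, function(p) forward_two_path(tp, dicts, p$cm))
    fwd_sm <- lapply(corpus$pairs, function(p) forward_two_path(tp, dicts, p$sm))
    pairing <- data.frame(pair_id = seq_len(n), cm_col = seq_len(n),
                          sm_col = n + seq_len(n),
                          family_id = vapply(corpus$pairs, `[[`, 1L,
                                             "family_id"))
    resp <- lapply(c(a = "a", b = "b", c = "c"), function(set) {
      cmm <- vapply(fwd_cm, `[[`, fwd_cm[[1L]][[set]], set)
      smm <- vapply(fwd_sm, `[[`, fwd_cm[[1L]][[set]], set)
      response_matrix(cbind(cmm, smm), pairing)
    })
    rows <- rbind(rows, data.frame(model = m, pmi_a = pmi(resp$a),
                                   pmi_b = pmi(resp$b), pmi_c = pmi(resp$c)))
  }
  t_ab <- stats::t.test(rows$pmi_a, rows$pmi_b, paired = TRUE,
                        alternative = "greater")
  t_bc <- stats::t.test(rows$pmi_b, rows$pmi_c, paired = TRUE,
                        alternative = "two.sided")
  list(header = report_header("rf_control", cfg, seed),
       rf_sizes = tp$rf, models = rows,
       test_a_vs_b = list(p = t_ab$p.value, tail = "one", paired = TRUE),
       test_b_vs_c = list(p = t_bc$p.value, tail = "two", paired = TRUE))
}

#' Regress per-pair modulation on grouped image statistics
#'
#' Computes the per-pair population modulation of the top big layer,
#' builds the signed-sqrt/z-score + groupwise-PCA design from the
#' structured (CM-role) images, fits the OLS regression, and decomposes the
#' full-model R^2 over statistic groups by averaging over orderings.
#'
#' @param corpus A `stimulus_corpus` (>= 50 pairs recommended).
#' @param net,dicts A trained network (e.g. from [run_baseline()]).
#' @param big_layer Layer whose modulation is regressed (default: top).
#' @param bank A `filter_bank` sized for the corpus images.
#' @param var_threshold Per-group PCA variance threshold.
#' @return Report list with the fit, per-group LMG percentages (summing to
#'   100), and measured-vs-predicted scatter data.
#' @export
run_stat_regression <- function(corpus, net, dicts, big_layer = NULL,
                                bank = NULL, var_threshold = 0.9) {
  check_corpus(corpus)
  if (length(corpus$pairs) < 50L) {
    warning("fewer than 50 pairs; the regression may be unstable")
  }
  if (is.null(big_layer)) big_layer <- max(net$grouping)
  if (is.null(bank)) {
    ns <- max(2L, min(4L, floor(log2(corpus$size / 16))))
    bank <- filter_bank(n_scales = ns)
  }
  R <- extract_responses(net, dicts, corpus, big_layer)
  y <- pair_modulation(R)
  raw <- stats_matrix(corpus_images(corpus, "cm"), bank)
  design <- make_design(raw$x, raw$groups, var_threshold)
  fit <- fit_pmi_regression(design, y)
  contrib <- lmg_contributions(design, y)
  list(header = report_header("stat_regression",
                              list(big_layer = big_layer,
                                   var_threshold = var_threshold), NA),
       r_squared = fit$r_squared, contributions = contrib,
       scatter = data.frame(measured = y, predicted = unname(fit$fitted)),
       design_components = design$n_components)
}

#' CM-vs-SM statistic correlation experiment
#'
#' Per statistic group, the correlation between the leading-component
#' projections of CM and SM image statistics (see
#' [group_correlation_cm_sm()]). On phase-scramble corpora the position
#' groups are expected to exceed the scale groups; the report flags a
#' violation of that direction.
#'
#' @param corpus A `stimulus_corpus`.
#' @param bank A `filter_bank` (sized automatically when omitted).
#' @return Report list with the per-group correlation table, scatter data,
#'   and the qualitative position-vs-scale check.
#' @export
run_cm_sm_stat_correlation <- function(corpus, bank = NULL) {
  check_corpus(corpus)
  if (is.null(bank)) {
    ns <- max(2L, min(4L, floor(log2(corpus$size / 16))))
    bank <- filter_bank(n_scales = ns)
  }
  res <- group_correlation_cm_sm(corpus, bank)
  tab <- res$table
  pos <- mean(tab$r[tab$group %in% c("lin_position", "en_position")])
  scl <- mean(tab$r[tab$group %in% c("lin_scale", "en_scale")])
  list(header = report_header("cm_sm_stat_correlation",
                              list(bank = unclass(bank)["n_scales"]), NA),
       table = tab, scatter = res$scatter,
       position_exceeds_scale = pos > scl,
       note = if (pos <= scl) "position-group correlation does NOT exceed scale-group correlation" else NULL)
}

#' Train-on-SM control experiment
#'
#' Re-runs the baseline protocol with the phase-scrambled (SM-role) images
#' as the training set and compares per-layer PMIs against a supplied
#' baseline report (trained on structured images).
#'
#' @param corpus A `stimulus_corpus`.
#' @param baseline Report from [run_baseline()] on the same corpus.
#' @inheritParams run_baseline
#' @return Report list; `comparison` has one row per big layer with both
#'   PMIs.
#' @export
run_train_on_sm <- function(corpus, baseline, net = shmax_spec(), seed = 1L,
                            n_train = 20L, n_per_image = 100L, n_iters = 10L,
                            n_perm = 2000L, rst_n = 100L, rst_reps = 500L) {
  check_corpus(corpus)
  if (missing(baseline) || is.null(baseline$layers)) {
    stop("a baseline report (trained on structured images) is required")
  }
  cfg <- list(net = net, n_train = n_train)
  dicts <- train_shmax(net, training_images(corpus, "sm", n_train, seed),
                       seed = seed, n_per_image = n_per_image,
                       n_iters = n_iters)
  n_big <- max(net$grouping)
  rows <- data.frame(big_layer = seq_len(n_big), pmi_sm_trained = NA_real_,
                     pmi_baseline = baseline$layers$pmi[seq_len(n_big)])
  Rs <- extract_responses(net, dicts, corpus, seq_len(n_big))
  for (b in seq_len(n_big)) rows$pmi_sm_trained[b] <- pmi(Rs[[b]])
  list(header = report_header("train_on_sm", cfg, seed),
       comparison = rows, dicts = dicts)
}

#' Write a report's tables to disk
#'
#' Data-frame members become CSV files; everything else is summarized into
#' one JSON document (including the config hash and seeds).
#'
#' @param report A report list from one of the `run_*` functions.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keep <- list()
  for (nm in names(report)) {
    x <- report[[nm]]
    if (is.data.frame(x)) {
      utils::write.csv(x, file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    } else if (!nm %in% c("dicts", "net", "scatter")) {
      keep[[nm]] <- x
    }
  }
  jsonlite::write_json(keep, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
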