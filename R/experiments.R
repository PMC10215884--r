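#' k-fold cross-validation split over a scenario dataset
#'
#' Partitions the manifest's pair indices into `folds` disjoint test folds
#' covering every pair; per fold, the remaining pairs form the training
#' portion, from which a validation fraction is carved. Because the split is
#' over pair indices and the pairing is fixed across SNR levels, a clean
#' segment never straddles train and test in any fold.
#'
#' @param manifest a `denoise_manifest` (see [build_scenario_dataset()]).
#' @param folds number of folds (>= 2).
#' @param val_fraction validation fraction of each fold's training portion.
#' @param seed permutation seed.
#' @return List of `folds` elements, each `list(train, val, test)` of pair
#'   indices.
#' @export
kfold_split <- function(manifest, folds = 5L, val_fraction = 0.1,
                        seed = manifest$seed) {
  n <- manifest$n_pairs
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < folds) stop("fewer pairs (", n, ") than folds (", folds, ")")
  perm <- withr::with_seed(seed, sample.int(n))
  fold_id <- rep(seq_len(folds), length.out = n)   # sizes differ by at most 1
  lapply(seq_len(folds), function(f) {
    test <- perm[fold_id == f]
    rest <- perm[fold_id != f]
    n_val <- floor(val_fraction * length(rest))
    list(train = rest[setdiff(seq_along(rest), seq_len(n_val))],
         val = rest[seq_len(n_val)], test = test)
  })
}

#' Evaluate a fitted model on held-out contaminated pairs
#'
#' Runs the forward pass on the normalized contaminated segments and computes
#' the full metric suite (see [denoise_metrics()]) of the predictions against
#' the normalized ground truth.
#'
#' @param fit a fitted `mrunet3p` model, any object with a `predict` method
#'   returning a prediction matrix for a `contaminated_pairs` input, or a
#'   plain function `pairs -> matrix` (useful for reference predictors such
#'   as the identity `function(p) p$y_hat`).
#' @param pairs a `contaminated_pairs` batch.
#' @param fs sampling rate; taken from `pairs` when available.
#' @return A `metric_report`.
#' @export
evaluate_model <- function(fit, pairs, fs = pairs$fs) {
  z <- if (is.function(fit)) fit(pairs) else predict(fit, pairs)
  denoise_metrics(z, pairs$x_hat, pairs$y_hat, fs)
}

subsample_idx <- function(idx, n_max, seed) {
  if (is.null(n_max) || length(idx) <= n_max) return(idx)
  withr::with_seed(seed, sample(idx, n_max))
}

#' Experiment A: one independent training per SNR level
#'
#' For every SNR level of the manifest, trains a fresh network on that
#' level's training pairs and evaluates temporal correlation and the temporal
#' and spectral relative errors on the level's test pairs, optionally across
#' cross-validation folds. Results are tabulated by SNR level, the layout in
#' which per-level denoising performance is conventionally reported.
#'
#' @param manifest a `denoise_manifest`.
#' @param spec an [arch_spec()] (its `input_length` must match the
#'   scenario's segment length).
#' @param config a [train_config()].
#' @param folds number of cross-validation folds; `1` uses a single 80/20
#'   split ([split_dataset()], experiment `"A"`).
#' @param n_per_level optional cap on pairs per level (random, seeded), to
#'   run reduced-scale replications.
#' @param snr_levels levels to run; default all in the manifest.
#' @param verbose print progress.
#' @return An `experiment_result` with `$table` (one row per level x fold)
#'   and the per-cell metric reports.
#' @export
run_experiment_a <- function(manifest, spec, config = train_config(),
                             folds = config$folds, n_per_level = NULL,
                             snr_levels = manifest$snr_levels,
                             verbose = TRUE) {
  for (lv in snr_levels)
    if (!lv %in% manifest$snr_levels)
      stop("SNR level ", lv, " dB missing from the manifest")
  splits <- if (folds > 1L) kfold_split(manifest, folds, config$val_fraction)
  else {
    m <- split_dataset(manifest, "A", val_fraction = config$val_fraction)
    list(list(train = m$split$train, val = m$split$val, test = m$split$test))
  }
  rows <- list(); reports <- list()
  for (lv in snr_levels) {
    for (f in seq_along(splits)) {
      sp <- splits[[f]]
      # train on the full training portion; mrunet3p carves its own
      # validation subset per config$val_fraction for early stopping
      tr_idx <- subsample_idx(c(sp$train, sp$val), n_per_level, config$seed + f)
      te_idx <- subsample_idx(sp$test,
                              if (is.null(n_per_level)) NULL
                              else max(16L, ceiling(n_per_level / 4)),
                              config$seed + 100L + f)
      tr <- realize_pairs(manifest, lv, tr_idx)
      te <- realize_pairs(manifest, lv, te_idx)
      if (verbose)
        message(sprintf("[experiment A] SNR %+d dB, fold %d: %d train / %d test",
                        lv, f, length(tr_idx), length(te_idx)))
      fit <- mrunet3p(tr, spec = spec, config = config, verbose = FALSE)
      rep_ <- evaluate_model(fit, te)
      agg <- aggregate_reports(rep_)
      rows[[length(rows) + 1L]] <- data.frame(
        snr_db = lv, fold = f,
        cc_temporal = agg$mean[agg$metric == "cc_temporal"],
        rrmse_temporal = agg$mean[agg$metric == "rrmse_temporal"],
        rrmse_spectral = agg$mean[agg$metric == "rrmse_spectral"])
      reports[[sprintf("snr%+d_fold%d", lv, f)]] <- rep_
    }
  }
  structure(list(experiment = "A", scenario = manifest$scenario,
                 table = do.call(rbind, rows), reports = reports,
                 spec = spec, config = config),
            class = "experiment_result")
}

#' Experiment B: pooled training across all SNR levels
#'
#' Trains a single network on the training pairs of every SNR level merged
#' together, then reports the full metric suite — percentage artifact
#' reduction in time (eta) and frequency (gamma), temporal and spectral
#' relative errors with their standard deviations, and mean five-band power
#' ratios for the ground-truth, noisy and predicted segments — on the pooled
#' held-out test set.
#'
#' @inheritParams run_experiment_a
#' @param n_train,n_test optional caps on pooled training/test pairs
#'   (random, seeded) for reduced-scale runs.
#' @return An `experiment_result` with the pooled `metric_report`, its
#'   aggregate table, per-SNR-level summaries and the fitted model.
#' @export
run_experiment_b <- function(manifest, spec, config = train_config(),
                             n_train = NULL, n_test = NULL, verbose = TRUE) {
  if (is.null(manifest$split) || !identical(manifest$experiment, "B"))
    manifest <- split_dataset(manifest, "B", val_fraction = 0)
  levels <- manifest$snr_levels
  train_pool <- c(manifest$split$train, manifest$split$val)
  per_level_train <- if (is.null(n_train)) train_pool
  else subsample_idx(train_pool,
                     max(1L, ceiling(n_train / length(levels))), config$seed)
  per_level_test <- if (is.null(n_test)) manifest$split$test
  else subsample_idx(manifest$split$test,
                     max(1L, ceiling(n_test / length(levels))),
                     config$seed + 1L)
  tr <- bind_pairs(lapply(levels, function(lv)
    realize_pairs(manifest, lv, per_level_train)))
  te <- bind_pairs(lapply(levels, function(lv)
    realize_pairs(manifest, lv, per_level_test)))
  if (verbose)
    message(sprintf("[experiment B] %s: %d pooled train / %d pooled test pairs over %d SNR levels",
                    manifest$scenario, nrow(tr$x), nrow(te$x), length(levels)))
  fit <- mrunet3p(tr, spec = spec, config = config, verbose = FALSE)
  rep_ <- evaluate_model(fit, te)
  by_level <- lapply(stats::setNames(levels, paste0("snr", levels)), function(lv) {
    sel <- te$snr_db == lv
    denoise_metrics(predict(fit, te$y_hat[sel, , drop = FALSE]),
                    te$x_hat[sel, , drop = FALSE],
                    te$y_hat[sel, , drop = FALSE], te$fs)
  })
  structure(list(experiment = "B", scenario = manifest$scenario,
                 report = rep_, table = aggregate_reports(rep_),
                 by_level = by_level, fit = fit,
                 n_train = nrow(tr$x), n_test = nrow(te$x),
                 spec = spec, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> experiment %s, scenario %s\n",
              x$experiment, x$scenario))
  if (x$experiment == "A") {
    print(x$table, row.names = FALSE)
  } else {
    cat(sprintf("  %d train / %d test pooled pairs\n", x$n_train, x$n_test))
    print(x$table, row.names = FALSE)
    br <- attr(x$table, "band_ratios")
    if (!is.null(br)) { cat("  mean band power ratios:\n"); print(round(br, 4)) }
  }
  invisible(x)
}
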