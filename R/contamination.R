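#' Solve the artifact scaling factor for a requested SNR
#'
#' With contamination defined as \eqn{y = x + \lambda n} and the
#' signal-to-noise ratio as
#' \eqn{\mathrm{SNR} = 10\log_{10}\{\mathrm{RMS}(x)/\mathrm{RMS}(\lambda n)\}},
#' the scaling factor is
#' \eqn{\lambda = \mathrm{RMS}(x) / \{\mathrm{RMS}(n)\,10^{\mathrm{SNR}/10}\}}.
#' Substituting the result back reproduces the requested SNR exactly; lambda
#' is strictly decreasing in SNR.
#'
#' @param x clean series (or matrix, rows = segments).
#' @param n artifact series of the same shape; must have non-zero energy.
#' @param snr_db requested signal-to-noise ratio in dB.
#' @return Positive scalar (or vector, one per row).
#' @export
solve_lambda <- function(x, n, snr_db) {
  if (is.null(dim(x))) {
    rx <- rms(x); rn <- rms(n)
  } else {
    rx <- rms_rows(x); rn <- rms_rows(n)
  }
  if (any(rn == 0)) stop("artifact has zero energy; lambda undefined")
  if (any(rx == 0)) stop("clean signal has zero energy")
  rx / (rn * 10^(snr_db / 10))
}

# recompute the SNR implied by (x, lambda * n); inverse of solve_lambda
snr_from_mix <- function(x, n, lam) {
  10 * log10(rms(x) / rms(lam * n))
}

#' Contaminate a clean segment with scaled artifacts at a given SNR
#'
#' Linear semi-synthetic mixing: the artifacts are summed into a single noise
#' series \eqn{n}, scaled by the lambda that realises `snr_db` (see
#' [solve_lambda()]), and added to the clean segment:
#' \eqn{y = x + \lambda n}. The pair is then normalized by the standard
#' deviation of the contaminated series (see [normalize_pair()]).
#'
#' @param x clean numeric vector (the ground-truth EEG segment).
#' @param artifacts a numeric vector or a list of one or two vectors (EOG
#'   and/or EMG), all the same length as `x` and at the same sampling rate —
#'   resample first with [resample_signal()] if needed.
#' @param snr_db requested SNR, dB.
#' @param ids optional character labels carried through for provenance
#'   (`x_id` then artifact ids).
#' @return A `contaminated_pair`: list with `x`, `y`, `n`, `lam`, `snr_db`,
#'   `sigma_y`, `x_hat`, `y_hat`, `ids`.
#' @export
mix_segments <- function(x, artifacts, snr_db, ids = NULL) {
  if (!is.list(artifacts)) artifacts <- list(artifacts)
  if (!length(artifacts) %in% 1:2) stop("expected one or two artifact segments")
  for (a in artifacts)
    if (length(a) != length(x))
      stop("length mismatch: clean segment has ", length(x),
           " samples, artifact has ", length(a))
  n <- Reduce(`+`, artifacts)
  lam <- solve_lambda(x, n, snr_db)
  y <- x + lam * n
  pair <- structure(list(x = x, y = y, n = n, lam = lam, snr_db = snr_db,
                         sigma_y = NA_real_, x_hat = NULL, y_hat = NULL,
                         ids = ids),
                    class = "contaminated_pair")
  normalize_pair(pair)
}

#' Normalize a contaminated pair by the noisy segment's standard deviation
#'
#' Divides both the clean and the contaminated series by \eqn{\sigma_y}, the
#' (population) standard deviation of the noisy series, yielding
#' \eqn{\hat x = x/\sigma_y}, \eqn{\hat y = y/\sigma_y} with
#' \eqn{\mathrm{sd}(\hat y) = 1}. This is the scaling under which the network
#' is trained and all metrics are evaluated.
#'
#' @param pair a `contaminated_pair` from [mix_segments()].
#' @return The pair with `sigma_y`, `x_hat`, `y_hat` filled in.
#' @export
normalize_pair <- function(pair) {
  s <- sd_pop(pair$y)
  if (s == 0) stop("contaminated series is constant; cannot normalize")
  pair$sigma_y <- s
  pair$x_hat <- pair$x / s
  pair$y_hat <- pair$y / s
  pair
}

#' @export
print.contaminated_pair <- function(x, ...) {
  cat(sprintf("<contaminated_pair> %d samples, SNR %g dB, lambda %.4g, sigma_y %.4g\n",
              length(x$x), x$snr_db, x$lam, x$sigma_y))
  invisible(x)
}

#' Build a semi-synthetic contamination scenario
#'
#' Pairs clean EEG segments one-to-one with artifact segments under the rule
#' that every EEG, EOG and EMG segment is used at most once (no segment reuse,
#' so no information can leak between later train/test splits). The pairing is
#' a seeded random selection without replacement and is fixed across SNR
#' levels: the same (clean, artifact) couple is re-mixed at every level.
#'
#' Scenarios:
#' \describe{
#'   \item{EOG}{as many pairs as there are EOG segments, mixed at 256 Hz;
#'     requires at least that many EEG segments.}
#'   \item{EMG}{one pair per EEG segment, EEG upsampled to 512 Hz, EMG
#'     segments subsampled without replacement.}
#'   \item{EOG+EMG}{one pair per EOG segment; EEG and EOG upsampled to
#'     512 Hz; a single lambda scales the summed EOG+EMG artifact.}
#' }
#' With full-size banks (4514 EEG / 3400 EOG / 5598 EMG) and ten SNR levels
#' this yields 34,000 (EOG), 45,140 (EMG) and 34,000 (EOG+EMG) contaminated
#' segments. Pairs are not materialized here — see [realize_pairs()] — so
#' large scenarios stay cheap to describe.
#'
#' @param eeg,eog,emg [segment_bank()]s; `eog`/`emg` may be `NULL` when the
#'   scenario does not use them.
#' @param scenario `"EOG"`, `"EMG"` or `"EOG+EMG"`.
#' @param snr_levels integer dB levels; default -7 to +2.
#' @param seed seed for the pairing permutation (recorded in the manifest).
#' @return A `denoise_manifest`: pairing table, aligned clean/artifact
#'   matrices, scenario metadata and counts.
#' @export
build_scenario_dataset <- function(eeg, eog = NULL, emg = NULL,
                                   scenario = c("EOG", "EMG", "EOG+EMG"),
                                   snr_levels = -7:2, seed = 1L) {
  scenario <- match.arg(scenario)
  need <- function(bank, what) if (is.null(bank))
    stop("scenario ", scenario, " requires a ", what, " bank")
  chk <- function(avail, required, what) if (avail < required)
    stop("insufficient ", what, " bank: scenario ", scenario, " requires ",
         required, " segments, only ", avail, " available")

  if (scenario == "EOG") {
    need(eog, "EOG")
    n_pairs <- nrow(eog)
    chk(nrow(eeg), n_pairs, "EEG")
    fs <- 256
    sel <- withr::with_seed(seed, list(
      eeg = sample.int(nrow(eeg), n_pairs),
      a1  = sample.int(nrow(eog), n_pairs)))
    x_mat <- unclass(eeg)[sel$eeg, , drop = FALSE]
    n_mat <- unclass(eog)[sel$a1, , drop = FALSE]
    pairings <- data.frame(eeg_id = bank_ids(eeg)[sel$eeg],
                           eog_id = bank_ids(eog)[sel$a1])
  } else if (scenario == "EMG") {
    need(emg, "EMG")
    n_pairs <- nrow(eeg)
    chk(nrow(emg), n_pairs, "EMG")
    fs <- 512
    sel <- withr::with_seed(seed, list(
      eeg = sample.int(nrow(eeg), n_pairs),
      a1  = sample.int(nrow(emg), n_pairs)))
    eeg_up <- resample_bank(eeg, 512)
    x_mat <- unclass(eeg_up)[sel$eeg, , drop = FALSE]
    n_mat <- unclass(emg)[sel$a1, , drop = FALSE]
    pairings <- data.frame(eeg_id = bank_ids(eeg)[sel$eeg],
                           emg_id = bank_ids(emg)[sel$a1])
  } else {
    need(eog, "EOG"); need(emg, "EMG")
    n_pairs <- nrow(eog)
    chk(nrow(eeg), n_pairs, "EEG")
    chk(nrow(emg), n_pairs, "EMG")
    fs <- 512
    sel <- withr::with_seed(seed, list(
      eeg = sample.int(nrow(eeg), n_pairs),
      a1  = sample.int(nrow(eog), n_pairs),
      a2  = sample.int(nrow(emg), n_pairs)))
    x_mat <- unclass(resample_bank(eeg, 512))[sel$eeg, , drop = FALSE]
    n_mat <- unclass(resample_bank(eog, 512))[sel$a1, , drop = FALSE] +
             unclass(emg)[sel$a2, , drop = FALSE]
    pairings <- data.frame(eeg_id = bank_ids(eeg)[sel$eeg],
                           eog_id = bank_ids(eog)[sel$a1],
                           emg_id = bank_ids(emg)[sel$a2])
  }
  structure(list(scenario = scenario, fs = fs, snr_levels = snr_levels,
                 n_pairs = n_pairs, n_total = n_pairs * length(snr_levels),
                 pairings = pairings, x_mat = x_mat, n_mat = n_mat,
                 seed = seed, split = NULL, experiment = NULL),
            class = "denoise_manifest")
}

#' @export
print.denoise_manifest <- function(x, ...) {
  cat(sprintf("<denoise_manifest> scenario %s @ %g Hz: %d pairs x %d SNR levels (%s dB) = %d contaminated segments\n",
              x$scenario, x$fs, x$n_pairs, length(x$snr_levels),
              paste(range(x$snr_levels), collapse = ".."), x$n_total))
  if (!is.null(x$split)) {
    s <- x$split
    cat(sprintf("  experiment %s split (per level): train %d (incl. %d validation) / test %d\n",
                x$experiment, length(s$train) + length(s$val), length(s$val),
                length(s$test)))
    if (identical(x$experiment, "B"))
      cat(sprintf("  pooled over %d levels: train %d (incl. validation) / test %d\n",
                  length(x$snr_levels),
                  (length(s$train) + length(s$val)) * length(x$snr_levels),
                  length(s$test) * length(x$snr_levels)))
  }
  invisible(x)
}

#' Materialize contaminated pairs for one SNR level
#'
#' Mixes the manifest's (clean, artifact) couples at the requested SNR level
#' and normalizes each pair, vectorised over segments. The per-pair invariants
#' hold exactly: recomputing the SNR from \eqn{(x, \lambda n)} returns the
#' requested level, and each normalized noisy series has unit (population)
#' standard deviation.
#'
#' @param manifest a `denoise_manifest`.
#' @param snr_db one of the manifest's SNR levels.
#' @param indices optional subset of pair indices to materialize.
#' @return A `contaminated_pairs` batch: matrices `x`, `y`, `x_hat`, `y_hat`
#'   (segments in rows) plus vectors `lam`, `sigma_y` and metadata.
#' @export
realize_pairs <- function(manifest, snr_db, indices = NULL) {
  if (!snr_db %in% manifest$snr_levels)
    stop("SNR level ", snr_db, " dB is not part of this manifest")
  idx <- if (is.null(indices)) seq_len(manifest$n_pairs) else indices
  x <- manifest$x_mat[idx, , drop = FALSE]
  n <- manifest$n_mat[idx, , drop = FALSE]
  lam <- solve_lambda(x, n, snr_db)
  y <- x + lam * n
  mu <- rowMeans(y)
  sigma_y <- sqrt(rowMeans((y - mu)^2))
  if (any(sigma_y == 0)) stop("degenerate pair: constant contaminated series")
  structure(list(x = x, y = y, x_hat = x / sigma_y, y_hat = y / sigma_y,
                 lam = lam, sigma_y = sigma_y,
                 snr_db = rep(snr_db, length(idx)), pair_idx = idx,
                 fs = manifest$fs, scenario = manifest$scenario),
            class = "contaminated_pairs")
}

#' @export
print.contaminated_pairs <- function(x, ...) {
  cat(sprintf("<contaminated_pairs> %d pairs of %d samples @ %g Hz (%s), SNR %s dB\n",
              nrow(x$x), ncol(x$x), x$fs, x$scenario,
              paste(sort(unique(x$snr_db)), collapse = "/")))
  invisible(x)
}

# concatenate contaminated_pairs batches (used to pool SNR levels)
bind_pairs <- function(batches) {
  out <- batches[[1L]]
  for (f in c("x", "y", "x_hat", "y_hat"))
    out[[f]] <- do.call(rbind, lapply(batches, `[[`, f))
  for (f in c("lam", "sigma_y", "snr_db", "pair_idx"))
    out[[f]] <- do.call(c, lapply(batches, `[[`, f))
  out
}

#' Materialize a train/validation/test portion of a split manifest
#'
#' Pools the requested portion across all SNR levels of the manifest (or a
#' subset of levels), using the leak-free split stored by [split_dataset()].
#'
#' @param manifest a split `denoise_manifest`.
#' @param portion `"train"`, `"val"` or `"test"`.
#' @param snr_levels levels to include; default all.
#' @return A `contaminated_pairs` batch.
#' @export
realize_split <- function(manifest, portion = c("train", "val", "test"),
                          snr_levels = manifest$snr_levels) {
  portion <- match.arg(portion)
  if (is.null(manifest$split))
    stop("manifest has no split; call split_dataset() first")
  idx <- manifest$split[[portion]]
  bind_pairs(lapply(snr_levels, function(lv) realize_pairs(manifest, lv, idx)))
}

#' Split a scenario dataset into train/validation/test without leakage
#'
#' The split is over pair indices, so a clean EEG segment (and its paired
#' artifact) falls on the same side of the split at every SNR level —
#' re-mixes of one underlying couple can never straddle train and test.
#' The 80% training portion is carved per level (`floor(train_fraction * n)`
#' pairs), the remainder is the test set, and validation takes
#' `floor(val_fraction * )` of the training portion.
#'
#' Experiment `"A"` interprets the split per SNR level (models are trained
#' level by level); experiment `"B"` pools the same per-level splits across
#' all levels into one training and one test set.
#'
#' @param manifest a `denoise_manifest`.
#' @param experiment `"A"` or `"B"`.
#' @param train_fraction fraction of pairs per level in the training portion.
#' @param val_fraction fraction of the training portion held out for
#'   validation.
#' @param seed seed for the split permutation.
#' @return The manifest with `$split` (disjoint `train`, `val`, `test` pair
#'   indices) and `$experiment` set.
#' @export
split_dataset <- function(manifest, experiment = c("A", "B"),
                          train_fraction = 0.8, val_fraction = 0.1,
                          seed = manifest$seed) {
  experiment <- match.arg(experiment)
  if (!(train_fraction > 0 && train_fraction < 1) ||
      !(val_fraction >= 0 && val_fraction < 1))
    stop("fractions must lie in (0, 1)")
  n <- manifest$n_pairs
  n_tr <- floor(train_fraction * n)
  perm <- withr::with_seed(seed, sample.int(n))
  train_portion <- perm[seq_len(n_tr)]
  test <- perm[setdiff(seq_len(n), seq_len(n_tr))]
  n_val <- floor(val_fraction * n_tr)
  val <- train_portion[seq_len(n_val)]
  train <- setdiff(train_portion, val)
  manifest$split <- list(train = train, val = val, test = test)
  manifest$experiment <- experiment
  manifest
}
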