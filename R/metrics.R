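#' Root-mean-square amplitude
#'
#' \eqn{\mathrm{RMS}(w) = \sqrt{\frac{1}{m}\sum_{i=1}^{m} w_i^2}}, the root of
#' the mean of squares (no mean removal).
#'
#' @param w non-empty finite numeric vector.
#' @return Non-negative scalar; zero only for the all-zero series.
#' @export
rms <- function(w) {
  if (length(w) == 0L) stop("rms of an empty series is undefined")
  if (!all(is.finite(w))) stop("rms requires finite input")
  sqrt(mean(w^2))
}

# row-wise RMS of a matrix, used throughout the mixing pipeline
rms_rows <- function(m) sqrt(rowMeans(m^2))

# population standard deviation (divide by m); the normalisation convention
# for sigma_y, on which the unit-variance invariant of y_hat depends
sd_pop <- function(w) sqrt(mean((w - mean(w))^2))

#' Temporal correlation coefficient
#'
#' Pearson correlation \eqn{\mathrm{Cov}(a,b)/\sqrt{\mathrm{Var}(a)\mathrm{Var}(b)}}
#' between two equal-length series; the time-domain similarity measure used to
#' score denoised against ground-truth EEG.
#'
#' @param a,b equal-length numeric vectors, each non-constant.
#' @return Correlation in \eqn{[-1, 1]}.
#' @export
cc_temporal <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ: ", length(a), " vs ", length(b))
  if (length(a) < 2L) stop("need at least 2 samples")
  if (sd_pop(a) == 0 || sd_pop(b) == 0)
    stop("correlation undefined for a constant series (zero variance)")
  stats::cor(a, b)
}

#' One-sided periodogram power spectral density
#'
#' Plain (rectangular-window) periodogram: the squared magnitude of the DFT,
#' folded to positive frequencies and scaled so that
#' \eqn{\sum_k \mathrm{PSD}(f_k)\,\Delta f = \frac{1}{m}\sum_i w_i^2}
#' (Parseval consistency with the signal's mean square). No Welch averaging,
#' no detrending, no taper.
#'
#' @param w finite numeric vector.
#' @param fs sampling rate, Hz.
#' @return A list with `freq` (Hz, from 0 to the Nyquist frequency) and
#'   `psd` (power per Hz).
#' @export
periodogram_psd <- function(w, fs) {
  if (!all(is.finite(w))) stop("periodogram requires finite input")
  n <- length(w)
  sp <- Mod(stats::fft(w))^2 / n^2           # per-bin power, sums to mean square
  nyq <- n %/% 2L
  p <- sp[1:(nyq + 1L)]
  if (n %% 2L == 0L) {
    if (nyq > 1L) p[2:nyq] <- 2 * p[2:nyq]   # fold negative bins; DC & Nyquist unpaired
  } else {
    p[2:(nyq + 1L)] <- 2 * p[2:(nyq + 1L)]
  }
  df <- fs / n
  list(freq = (0:nyq) * df, psd = p / df)
}

#' Spectral correlation coefficient
#'
#' Pearson correlation between the one-sided periodogram PSDs of two signals;
#' the frequency-domain analogue of [cc_temporal()].
#'
#' @inheritParams cc_temporal
#' @param fs sampling rate, Hz.
#' @export
cc_spectral <- function(a, b, fs) {
  pa <- periodogram_psd(a, fs)$psd
  pb <- periodogram_psd(b, fs)$psd
  cc_temporal(pa, pb)
}

#' Percentage reduction in artifacts, temporal domain
#'
#' \deqn{\eta = \left(1 - \frac{1 - CC_{af}}{1 - CC_{bf}}\right) \times 100}
#' where \eqn{CC_{af}} correlates the denoised series with ground truth and
#' \eqn{CC_{bf}} correlates the contaminated series with ground truth. 100
#' means perfect artifact removal, 0 means no improvement over the noisy
#' input; negative values indicate added distortion.
#'
#' @param z_hat denoised (predicted) series.
#' @param x_hat ground-truth clean series.
#' @param y_hat contaminated series.
#' @return Percentage (may be negative).
#' @export
eta <- function(z_hat, x_hat, y_hat) {
  cc_bf <- cc_temporal(y_hat, x_hat)
  if (cc_bf >= 1) stop("eta undefined: contaminated series equals ground truth (CC_bf = 1)")
  cc_af <- cc_temporal(z_hat, x_hat)
  (1 - (1 - cc_af) / (1 - cc_bf)) * 100
}

#' Percentage reduction in artifacts, spectral domain
#'
#' Same construction as [eta()] but with the before/after correlations taken
#' between periodogram PSDs rather than time series.
#'
#' @inheritParams eta
#' @param fs sampling rate, Hz.
#' @export
gamma_pct <- function(z_hat, x_hat, y_hat, fs) {
  cc_bf <- cc_spectral(y_hat, x_hat, fs)
  if (cc_bf >= 1) stop("gamma undefined: contaminated PSD equals ground-truth PSD")
  cc_af <- cc_spectral(z_hat, x_hat, fs)
  (1 - (1 - cc_af) / (1 - cc_bf)) * 100
}

#' Relative root-mean-square error, temporal domain
#'
#' \eqn{\mathrm{RMS}(\hat z - \hat x)/\mathrm{RMS}(\hat x)}.
#'
#' @inheritParams eta
#' @export
rrmse_temporal <- function(z_hat, x_hat) {
  if (length(z_hat) != length(x_hat)) stop("series lengths differ")
  r <- rms(x_hat)
  if (r == 0) stop("rrmse undefined for a zero-energy reference")
  rms(z_hat - x_hat) / r
}

#' Relative root-mean-square error, spectral domain
#'
#' [rrmse_temporal()] applied to the one-sided periodogram PSDs of the two
#' series; blind to phase, so any pair with identical power spectra scores 0.
#'
#' @inheritParams gamma_pct
#' @export
rrmse_spectral <- function(z_hat, x_hat, fs) {
  pz <- periodogram_psd(z_hat, fs)$psd
  px <- periodogram_psd(x_hat, fs)$psd
  r <- rms(px)
  if (r == 0) stop("rrmse undefined for a zero-energy reference")
  rms(pz - px) / r
}

#' Canonical EEG frequency bands
#'
#' The contiguous five-band partition of 1-80 Hz: delta (1-4), theta (4-8),
#' alpha (8-13), beta (13-30) and gamma (30-80 Hz).
#'
#' @return A data.frame with columns `name`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             lo   = c(1, 4, 8, 13, 30),
             hi   = c(4, 8, 13, 30, 80))
}

#' Band power ratios from the periodogram
#'
#' Fraction of periodogram power that each band contributes relative to the
#' whole 1-80 Hz range. Bins are assigned half-open, `lo <= f < hi`, except
#' that the final band edge (80 Hz) is closed so the partition covers 1-80 Hz
#' exactly; the five default ratios therefore sum to 1 for any signal.
#'
#' @param w numeric series.
#' @param fs sampling rate, Hz; the Nyquist frequency must reach 80 Hz.
#' @param bands a band table as returned by [eeg_bands()].
#' @return Named numeric vector of ratios, one per band.
#' @export
band_power_ratios <- function(w, fs, bands = eeg_bands()) {
  if (fs / 2 < max(bands$hi))
    stop("sampling rate too low: Nyquist ", fs / 2, " Hz < band edge ",
         max(bands$hi), " Hz")
  pg <- periodogram_psd(w, fs)
  f <- pg$freq; p <- pg$psd
  f_hi <- max(bands$hi)
  total <- sum(p[f >= min(bands$lo) & f <= f_hi])
  if (total == 0) stop("no power inside the analysis band")
  ratios <- vapply(seq_len(nrow(bands)), function(i) {
    hi_closed <- bands$hi[i] == f_hi
    sel <- f >= bands$lo[i] & (if (hi_closed) f <= bands$hi[i] else f < bands$hi[i])
    if (!any(sel)) stop("band ", bands$name[i], " spans no frequency bins")
    sum(p[sel]) / total
  }, 0)
  stats::setNames(ratios, bands$name)
}

#' Full metric suite for a batch of denoised segments
#'
#' Computes, per segment, the temporal correlation, temporal and spectral
#' percentage artifact reduction (eta, gamma), temporal and spectral RRMSE,
#' and five-band power ratios for the ground-truth, noisy and predicted
#' signals. All metrics are evaluated on the normalized series, matching how
#' the network is trained and scored.
#'
#' @param z_hat,x_hat,y_hat numeric matrices (segments in rows): predictions,
#'   ground truth, contaminated inputs.
#' @param fs sampling rate, Hz.
#' @param bands band table for power ratios; skipped when the sampling rate
#'   cannot resolve them.
#' @return A `metric_report`: list with `per_segment` (data.frame) and
#'   `band_ratios` (per-role matrices), plus `fs` and `n`.
#' @export
denoise_metrics <- function(z_hat, x_hat, y_hat, fs, bands = eeg_bands()) {
  z_hat <- rbind(z_hat); x_hat <- rbind(x_hat); y_hat <- rbind(y_hat)
  stopifnot(all(dim(z_hat) == dim(x_hat)), all(dim(x_hat) == dim(y_hat)))
  n <- nrow(z_hat)
  per <- data.frame(
    cc_temporal    = numeric(n), eta = numeric(n), gamma = numeric(n),
    rrmse_temporal = numeric(n), rrmse_spectral = numeric(n))
  freqs <- (0:(ncol(z_hat) %/% 2L)) * fs / ncol(z_hat)
  has_bins <- vapply(seq_len(nrow(bands)), function(i)
    any(freqs >= bands$lo[i] & freqs < bands$hi[i]), TRUE)
  do_bands <- fs / 2 >= max(bands$hi) && all(has_bins)
  br <- if (do_bands)
    lapply(c(ground_truth = "x", noisy = "y", predicted = "z"), function(role)
      matrix(NA_real_, n, nrow(bands), dimnames = list(NULL, bands$name)))
  for (i in seq_len(n)) {
    z <- z_hat[i, ]; x <- x_hat[i, ]; y <- y_hat[i, ]
    per$cc_temporal[i]    <- cc_temporal(z, x)
    per$eta[i]            <- eta(z, x, y)
    per$gamma[i]          <- gamma_pct(z, x, y, fs)
    per$rrmse_temporal[i] <- rrmse_temporal(z, x)
    per$rrmse_spectral[i] <- rrmse_spectral(z, x, fs)
    if (do_bands) {
      br$ground_truth[i, ] <- band_power_ratios(x, fs, bands)
      br$noisy[i, ]        <- band_power_ratios(y, fs, bands)
      br$predicted[i, ]    <- band_power_ratios(z, fs, bands)
    }
  }
  structure(list(per_segment = per, band_ratios = br, fs = fs, n = n),
            class = "metric_report")
}

#' Aggregate a metric report into mean +/- SD summaries
#'
#' Unweighted mean and standard deviation over segments for every metric, and
#' per-role mean band-power ratios — the layout used to tabulate denoising
#' performance.
#'
#' @param report a `metric_report` from [denoise_metrics()], or a list of them
#'   (pooled by concatenating segments).
#' @return A data.frame of `mean` and `sd` per metric, with mean band ratios
#'   attached as the `"band_ratios"` attribute.
#' @export
aggregate_reports <- function(report) {
  if (inherits(report, "metric_report")) report <- list(report)
  if (length(report) == 0L) stop("no reports to aggregate")
  per <- do.call(rbind, lapply(report, `[[`, "per_segment"))
  agg <- data.frame(
    metric = names(per),
    mean = vapply(per, mean, 0),
    sd   = vapply(per, function(v) if (length(v) > 1L) stats::sd(v) else 0, 0),
    row.names = NULL)
  brs <- lapply(report, `[[`, "band_ratios")
  if (!is.null(brs[[1L]])) {
    roles <- names(brs[[1L]])
    bm <- vapply(roles, function(role)
      colMeans(do.call(rbind, lapply(brs, `[[`, role))), numeric(ncol(brs[[1L]][[1L]])))
    attr(agg, "band_ratios") <- t(bm)
  }
  agg
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d segments @ %g Hz\n", x$n, x$fs))
  agg <- aggregate_reports(x)
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-15s %8.4f +/- %.4f\n", agg$metric[i], agg$mean[i], agg$sd[i]))
  br <- attr(agg, "band_ratios")
  if (!is.null(br)) {
    cat("  mean band power ratios (rows: ground_truth / noisy / predicted):\n")
    print(round(br, 4))
  }
  invisible(x)
}
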