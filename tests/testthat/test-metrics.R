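test_that("temporal correlation matches a two-pass loop oracle", {
  a <- withr::with_seed(3, stats::rnorm(64))
  b <- withr::with_seed(4, stats::rnorm(64))
  expect_equal(cc_temporal(a, b), naive_cor(a, b), tolerance = 1e-12)
  expect_equal(cc_temporal(a, a), 1)
  expect_equal(cc_temporal(a, -a), -1)
  expect_error(cc_temporal(a, rep(1, 64)), "constant")
  expect_error(cc_temporal(a, b[1:10]), "lengths differ")
})

test_that("periodogram matches the naive DFT oracle and Parseval", {
  fs <- 256
  w <- withr::with_seed(9, stats::rnorm(64))
  pg <- periodogram_psd(w, fs)
  expect_equal(pg$psd, naive_psd(w, fs), tolerance = 1e-10)
  # Parseval: integral of the PSD equals the mean square
  df <- fs / length(w)
  expect_equal(sum(pg$psd) * df, mean(w^2), tolerance = 1e-9 * mean(w^2))
  # odd length too
  w1 <- w[1:63]
  expect_equal(periodogram_psd(w1, fs)$psd, naive_psd(w1, fs), tolerance = 1e-10)
  expect_equal(sum(periodogram_psd(w1, fs)$psd) * fs / 63, mean(w1^2),
               tolerance = 1e-9)

  # a bin-centred sinusoid concentrates in one bin; zeros map to zeros
  t <- (0:63) / fs
  s <- sin(2 * pi * 16 * t)          # 16 Hz = bin 4 exactly
  ps <- periodogram_psd(s, fs)
  expect_equal(ps$freq[which.max(ps$psd)], 16)
  expect_gt(max(ps$psd) / sum(ps$psd), 0.999)
  expect_equal(periodogram_psd(numeric(64), fs)$psd, rep(0, 33))
})

test_that("artifact-reduction percentages hit their exact identities", {
  fs <- 256
  x <- withr::with_seed(11, stats::rnorm(64))
  noise <- withr::with_seed(12, stats::rnorm(64))
  y <- x + noise
  expect_equal(eta(x, x, y), 100)
  expect_equal(eta(y, x, y), 0)
  expect_equal(gamma_pct(x, x, y, fs), 100)
  expect_equal(gamma_pct(y, x, y, fs), 0)
  expect_error(eta(x, x, x), "CC_bf")

  # oracle chain: correlations -> percentage reduction
  z <- x + 0.3 * noise
  eta_oracle <- (1 - (1 - naive_cor(z, x)) / (1 - naive_cor(y, x))) * 100
  expect_equal(eta(z, x, y), eta_oracle, tolerance = 1e-10)
  g_oracle <- (1 - (1 - naive_cor(naive_psd(z, fs), naive_psd(x, fs))) /
                 (1 - naive_cor(naive_psd(y, fs), naive_psd(x, fs)))) * 100
  expect_equal(gamma_pct(z, x, y, fs), g_oracle, tolerance = 1e-10)

  # scale invariance: common positive rescaling changes nothing
  expect_equal(eta(3 * z, 3 * x, 3 * y), eta(z, x, y), tolerance = 1e-10)
  expect_equal(gamma_pct(3 * z, 3 * x, 3 * y, fs), gamma_pct(z, x, y, fs),
               tolerance = 1e-8)
})

test_that("relative errors match their oracles and symmetries", {
  fs <- 256
  x <- withr::with_seed(13, stats::rnorm(64))
  z <- withr::with_seed(14, stats::rnorm(64))
  expect_equal(rrmse_temporal(x, x), 0)
  expect_equal(rrmse_temporal(2 * x, x), 1)
  expect_equal(rrmse_temporal(z, x), naive_rms(z - x) / naive_rms(x),
               tolerance = 1e-12)
  expect_equal(rrmse_spectral(x, x, fs), 0)
  # PSD is phase-blind: a sign flip leaves the spectral error at zero
  expect_equal(rrmse_spectral(-x, x, fs), 0)
  pz <- naive_psd(z, fs); px <- naive_psd(x, fs)
  expect_equal(rrmse_spectral(z, x, fs), naive_rms(pz - px) / naive_rms(px),
               tolerance = 1e-10)
  expect_error(rrmse_temporal(z, numeric(64)), "zero-energy")
})

test_that("band power ratios localize sinusoids and sum to one", {
  fs <- 256; t <- (0:511) / fs
  r10 <- band_power_ratios(sin(2 * pi * 10 * t), fs)
  expect_gt(r10[["alpha"]], 0.999)
  r2 <- band_power_ratios(sin(2 * pi * 2 * t), fs)
  expect_gt(r2[["delta"]], 0.999)

  # band-limited noise: ratios match a bin-by-bin summation oracle
  w <- surrogate_bank("EEG", 1, seed = 21)[1, ]
  ratios <- band_power_ratios(w, fs)
  expect_equal(sum(ratios), 1, tolerance = 1e-6)
  p <- naive_psd(w, fs); f <- (0:256) * fs / 512
  oracle <- vapply(seq_len(nrow(eeg_bands())), function(i) {
    b <- eeg_bands()[i, ]
    hi_closed <- b$hi == 80
    sel <- f >= b$lo & (if (hi_closed) f <= b$hi else f < b$hi)
    sum(p[sel]) / sum(p[f >= 1 & f <= 80])
  }, 0)
  expect_equal(unname(ratios), oracle, tolerance = 1e-10)

  expect_error(band_power_ratios(w, 100), "Nyquist")
  expect_error(band_power_ratios(w, fs,
                                 bands = data.frame(name = "x", lo = 10.1, hi = 10.4)),
               "no frequency bins|no power")
})

test_that("metric reports aggregate to means and standard deviations", {
  fs <- 256
  x <- withr::with_seed(31, matrix(stats::rnorm(5 * 512), 5))
  noise <- withr::with_seed(32, matrix(stats::rnorm(5 * 512), 5))
  y <- x + noise
  z <- x + 0.2 * noise
  rep1 <- denoise_metrics(z, x, y, fs)
  expect_s3_class(rep1, "metric_report")
  expect_equal(nrow(rep1$per_segment), 5L)
  expect_true(all(rep1$per_segment$cc_temporal >= -1 &
                    rep1$per_segment$cc_temporal <= 1))
  expect_true(all(rep1$per_segment$rrmse_temporal >= 0))
  # per-signal band ratios sum to 1
  expect_equal(rowSums(rep1$band_ratios$predicted), rep(1, 5), tolerance = 1e-6)

  agg <- aggregate_reports(rep1)
  # loop oracle for the aggregate
  s <- 0; for (v in rep1$per_segment$eta) s <- s + v
  expect_equal(agg$mean[agg$metric == "eta"], s / 5, tolerance = 1e-12)

  # pooling reports concatenates their segments
  rep2 <- denoise_metrics(z + 0.05 * noise, x, y, fs)
  pooled <- aggregate_reports(list(rep1, rep2))
  expect_equal(pooled$mean[pooled$metric == "rrmse_temporal"],
               mean(c(rep1$per_segment$rrmse_temporal,
                      rep2$per_segment$rrmse_temporal)))

  # single report aggregates to itself with zero spread
  one <- denoise_metrics(z[1, , drop = FALSE], x[1, , drop = FALSE],
                         y[1, , drop = FALSE], fs)
  agg1 <- aggregate_reports(one)
  expect_equal(agg1$sd, rep(0, nrow(agg1)))
  expect_equal(agg1$mean[agg1$metric == "cc_temporal"],
               one$per_segment$cc_temporal[1])
  # two identical reports still have zero spread
  agg2 <- aggregate_reports(list(one, one))
  expect_equal(agg2$sd, rep(0, nrow(agg2)))
})
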