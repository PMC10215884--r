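test_that("rms matches its definition on constants, alternations and noise", {
  expect_equal(rms(rep(3, 10)), 3)
  expect_equal(rms(rep(-2.5, 4)), 2.5)
  expect_equal(rms(c(1, -1, 1, -1)), 1)
  w <- withr::with_seed(5, stats::rnorm(512))
  expect_equal(rms(w), naive_rms(w), tolerance = 1e-12)
  expect_error(rms(numeric(0)), "empty")
  expect_error(rms(c(1, NA)), "finite")
})

test_that("lambda solves the SNR equation and round-trips through it", {
  x <- withr::with_seed(1, stats::rnorm(256))
  n <- withr::with_seed(2, stats::rnorm(256))
  n <- n * rms(x) / rms(n)           # equalize RMS
  expect_equal(solve_lambda(x, n, 0), 1)
  expect_equal(solve_lambda(x, n, 10), 0.1)
  for (snr in c(-7, -3, 0, 2, 10)) {
    lam <- solve_lambda(x, n, snr)
    expect_equal(eegdenoise:::snr_from_mix(x, n, lam), snr, tolerance = 1e-6)
  }
  # lambda strictly decreasing in SNR
  lams <- vapply(-7:2, function(s) solve_lambda(x, n, s), 0)
  expect_true(all(diff(lams) < 0))
  expect_error(solve_lambda(x, numeric(256), 0), "zero energy")
})

test_that("mixing reproduces the additive model and the requested SNR", {
  bk <- tiny_banks()
  x <- bk$eeg[1, ]
  a <- bk$eog[1, ]

  # vanishing-noise limit: huge SNR leaves the clean segment untouched
  p <- mix_segments(x, a, snr_db = 100)
  expect_lt(max(abs(p$y - x)), 1e-3 * rms(x))

  # lambda = 1 when RMS(x) = RMS(n) at 0 dB: y = x + n exactly
  a_eq <- a * rms(x) / rms(a)
  p0 <- mix_segments(x, a_eq, snr_db = 0)
  expect_equal(p0$lam, 1)
  expect_equal(p0$y, x + a_eq)

  # combined EOG+EMG artifact at -7 dB round-trips through the SNR equation
  x_up <- resample_signal(x, 256, 512)
  eog_up <- resample_signal(a, 256, 512)
  p2 <- mix_segments(x_up, list(eog_up, bk$emg[1, ]), snr_db = -7)
  expect_equal(eegdenoise:::snr_from_mix(p2$x, p2$n, p2$lam), -7, tolerance = 1e-6)
  expect_equal(p2$y, p2$x + p2$lam * p2$n)

  expect_error(mix_segments(x, bk$emg[1, ], 0), "length mismatch")
  expect_error(mix_segments(x, list(a, a, a), 0), "one or two")
})

test_that("normalization gives the noisy series exactly unit spread", {
  bk <- tiny_banks()
  p <- mix_segments(bk$eeg[2, ], bk$eog[2, ], snr_db = -3)
  expect_equal(eegdenoise:::sd_pop(p$y_hat), 1, tolerance = 1e-9)
  expect_equal(p$y_hat, p$y / p$sigma_y)
  expect_equal(p$x_hat * p$sigma_y, p$x, tolerance = 1e-12)

  # y with population sd 2 halves
  y <- rep(c(1, -1), 16) * 2
  pair <- structure(list(x = y, y = y), class = "contaminated_pair")
  out <- normalize_pair(pair)
  expect_equal(out$sigma_y, 2)
  expect_equal(out$y_hat, y / 2)
  bad <- structure(list(x = y, y = rep(1, 32)), class = "contaminated_pair")
  expect_error(normalize_pair(bad), "constant")
})

test_that("scenario manifests pair segments once and count correctly", {
  bk <- tiny_banks(n = 10L)
  man <- build_scenario_dataset(bk$eeg, eog = bk$eog, scenario = "EOG",
                                snr_levels = -7:2, seed = 3)
  expect_equal(man$n_pairs, 10L)
  expect_equal(man$n_total, 100L)
  expect_equal(man$fs, 256)
  # no reuse of any segment within the scenario
  expect_false(anyDuplicated(man$pairings$eeg_id) > 0)
  expect_false(anyDuplicated(man$pairings$eog_id) > 0)

  # single-level scenario counts
  man1 <- build_scenario_dataset(bk$eeg, eog = bk$eog, scenario = "EOG",
                                 snr_levels = 0, seed = 3)
  expect_equal(man1$n_total, 10L)

  # EMG scenario resamples EEG to 512 Hz
  man2 <- build_scenario_dataset(bk$eeg, emg = bk$emg, scenario = "EMG",
                                 snr_levels = c(-7, 2), seed = 3)
  expect_equal(man2$fs, 512)
  expect_equal(ncol(man2$x_mat), 1024L)

  # combined scenario sums one EOG and one EMG artifact per pair
  man3 <- build_scenario_dataset(bk$eeg, eog = bk$eog, emg = bk$emg,
                                 scenario = "EOG+EMG", snr_levels = 0, seed = 3)
  expect_equal(ncol(man3$n_mat), 1024L)
  expect_named(man3$pairings, c("eeg_id", "eog_id", "emg_id"))

  # insufficient banks are rejected with required vs available
  small_eeg <- surrogate_bank("EEG", 4, seed = 1)
  expect_error(build_scenario_dataset(small_eeg, eog = bk$eog, scenario = "EOG"),
               "requires 10 segments, only 4")
})

test_that("realized pairs satisfy the SNR and unit-variance invariants", {
  bk <- tiny_banks(n = 8L)
  man <- build_scenario_dataset(bk$eeg, eog = bk$eog, scenario = "EOG",
                                snr_levels = -7:2, seed = 11)
  for (lv in c(-7, 0, 2)) {
    pr <- realize_pairs(man, lv)
    expect_equal(dim(pr$y_hat), dim(pr$x_hat))
    for (i in seq_len(nrow(pr$x))) {
      got <- eegdenoise:::snr_from_mix(pr$x[i, ], pr$y[i, ] - pr$x[i, ], 1)
      expect_equal(got, lv, tolerance = 1e-6)
      expect_equal(eegdenoise:::sd_pop(pr$y_hat[i, ]), 1, tolerance = 1e-9)
    }
  }
  expect_error(realize_pairs(man, 5), "not part of this manifest")
})

test_that("splits are leak-free, disjoint and conserve counts", {
  bk <- tiny_banks(n = 20L)
  man <- build_scenario_dataset(bk$eeg, eog = bk$eog, scenario = "EOG",
                                snr_levels = -1:1, seed = 2)
  man <- split_dataset(man, "B")
  s <- man$split
  expect_length(intersect(s$train, s$test), 0L)
  expect_length(intersect(s$val, s$test), 0L)
  expect_length(intersect(s$train, s$val), 0L)
  expect_setequal(c(s$train, s$val, s$test), seq_len(20L))
  # 80/20 with floor, validation 10% of the training portion
  expect_length(s$test, 4L)
  expect_length(c(s$train, s$val), 16L)
  expect_length(s$val, 1L)

  # the same clean ids are on the same side at every level by construction
  tr <- realize_split(man, "train")
  te <- realize_split(man, "test")
  tr_ids <- unique(man$pairings$eeg_id[tr$pair_idx])
  te_ids <- unique(man$pairings$eeg_id[te$pair_idx])
  expect_length(intersect(tr_ids, te_ids), 0L)
  # experiment B pools each portion across all levels
  expect_equal(nrow(tr$x), length(s$train) * 3L)

  expect_error(split_dataset(man, "C"))
  expect_error(split_dataset(man, "A", train_fraction = 1.2), "fractions")
})
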