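# small surrogate banks shared across tests; sized for speed, not realism
tiny_banks <- function(n = 12L, seed = 42L) {
  list(eeg = surrogate_bank("EEG", n, seed = seed),
       eog = surrogate_bank("EOG", n, seed = seed + 1L),
       emg = surrogate_bank("EMG", n, seed = seed + 2L))
}

# naive O(n^2) DFT, the independent oracle for all spectral metrics
naive_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1L), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1L)) / n)), 0 + 0i)
}

# one-sided PSD built from the naive DFT, bin by bin
naive_psd <- function(x, fs) {
  n <- length(x)
  p2 <- Mod(naive_dft(x))^2 / n^2
  nyq <- n %/% 2L
  p <- p2[1:(nyq + 1L)]
  if (n %% 2L == 0L) { if (nyq > 1L) p[2:nyq] <- 2 * p[2:nyq] } else
    p[2:(nyq + 1L)] <- 2 * p[2:(nyq + 1L)]
  p / (fs / n)
}

# two-pass covariance-based correlation, element-wise loop
naive_cor <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  cov <- 0; va <- 0; vb <- 0
  for (i in seq_len(n)) {
    cov <- cov + (a[i] - ma) * (b[i] - mb)
    va <- va + (a[i] - ma)^2
    vb <- vb + (b[i] - mb)^2
  }
  cov / sqrt(va * vb)
}

naive_rms <- function(w) {
  s <- 0
  for (i in seq_along(w)) s <- s + w[i]^2
  sqrt(s / length(w))
}
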