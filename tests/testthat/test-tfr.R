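test_that("analytic signal keeps the real part and empties negative frequencies", {
  set.seed(1)
  for (n in c(33, 64)) {
    x <- rnorm(n)
    z <- analytic_signal(x)
    expect_equal(Re(z), x, tolerance = 1e-12)
    Z <- stats::fft(z)
    neg <- if (n %% 2 == 0) (n / 2 + 2):n else ((n + 1) / 2 + 1):n
    expect_lt(max(Mod(Z[neg])) / max(Mod(Z)), 1e-10)
  }
  # analytic signal of a cosine has near-unit magnitude away from edges
  t <- (0:127) / 16
  z <- analytic_signal(cos(2 * pi * 3 * t))
  expect_lt(max(abs(Mod(z[20:108]) - 1)), 0.05)
  expect_error(analytic_signal(numeric(0)), "empty")
})

test_that("window construction enforces shape invariants", {
  for (fam in c("hamming", "gaussian")) {
    w <- tfr_window(fam, 21)
    expect_equal(w$values, rev(w$values))       # symmetric
    expect_equal(max(w$values), 1)              # unit peak
    expect_equal(w$values[11], 1)
  }
  expect_error(tfr_window("hamming", 10), "odd")
})

test_that("spectrogram matches its defining double sum and localizes tones", {
  set.seed(2)
  x <- rnorm(40)
  hw <- tfr_window("hamming", 11)
  S <- tfr_spectrogram(x, h = hw, n_freq = 16)
  B <- oracle_spectrogram(x, hw, 16)
  expect_lt(max(abs(S$values - B)) / max(B), 1e-10)
  expect_true(all(S$values >= 0))
  # zero signal
  S0 <- tfr_spectrogram(numeric(32), h = hw, n_freq = 16)
  expect_equal(max(abs(S0$values)), 0)
  # complex exponential on an exact bin: column max at that bin, interior t
  n_freq <- 16
  m0 <- 5
  z <- exp(2i * pi * m0 * (0:63) / (2 * n_freq))
  Sz <- tfr_spectrogram(z, h = hw, n_freq = n_freq)
  for (t in 10:54)
    expect_equal(which.max(Sz$values[t, ]), m0 + 1L)
  expect_error(tfr_spectrogram(rnorm(8), h = tfr_window("hamming", 11)),
               "longer than signal")
})

test_that("spectrogram satisfies Parseval's relation over full bins", {
  set.seed(3)
  x <- rnorm(48)
  hw <- tfr_window("hamming", 13)
  hw_unit <- hw
  hw_unit$values <- hw$values / sqrt(sum(hw$values^2))
  S <- tfr_spectrogram(x, h = hw_unit, n_freq = 16, two_sided = TRUE)
  n_fft <- 32
  L <- 6
  for (t in c(10, 24, 39)) {
    seg <- (t - L):(t + L)
    local_energy <- sum((x[seg] * hw_unit$values)^2)
    expect_equal(sum(S$values[t, ]) / n_fft, local_energy,
                 tolerance = 1e-6)
  }
})

test_that("Gabor equals the spectrogram with the same Gaussian window", {
  set.seed(4)
  x <- rnorm(50)
  gw <- tfr_window("gaussian", 13)
  G <- tfr_gabor(x, h = gw, n_freq = 16)
  S <- tfr_spectrogram(x, h = gw, n_freq = 16)
  expect_lt(max(abs(G$values - S$values)) / max(S$values), 1e-10)
  expect_error(tfr_gabor(x, h = tfr_window("hamming", 13)), "Gaussian")
})

test_that("pseudo Wigner-Ville matches its lag sum, is real, localizes tones", {
  set.seed(5)
  x <- rnorm(40)
  hw <- tfr_window("hamming", 11)
  P <- tfr_pwv(x, h = hw, n_freq = 16)
  B <- oracle_pwv(analytic_signal(x), hw, 16)
  expect_lt(max(abs(P$values - B)) / max(abs(B)), 1e-10)
  expect_lt(P$imag_residual, 1e-10)
  P0 <- tfr_pwv(numeric(32), h = hw, n_freq = 16)
  expect_equal(max(abs(P0$values)), 0)
  # analytic tone: interior column max at the nearest bin to f0
  fs <- 20; f0 <- 5
  tone <- generate_test_signal("tone", fs, 3.2, f0 = f0)
  Pt <- tfr_pwv(tone, fs = fs, n_freq = 32)
  k0 <- which.min(abs(Pt$freqs - f0))
  for (t in 20:44)
    expect_equal(which.max(Pt$values[t, ]), k0)
})

test_that("smoothed PWV matches its triple sum and degenerates to PWV", {
  set.seed(6)
  x <- rnorm(36)
  hw <- tfr_window("hamming", 9)
  gw <- tfr_window("hamming", 5)
  SP <- tfr_spwv(x, h = hw, g = gw, n_freq = 16)
  B <- oracle_spwv(analytic_signal(x), hw, gw, 16)
  expect_lt(max(abs(SP$values - B)) / max(abs(B)), 1e-10)
  # g = unit impulse reproduces the PWV exactly
  g1 <- tfr_window("hamming", 1)
  SP1 <- tfr_spwv(x, h = hw, g = g1, n_freq = 16)
  P <- tfr_pwv(x, h = hw, n_freq = 16)
  expect_identical(SP1$values, P$values)
})

test_that("time smoothing attenuates cross-terms between two tones", {
  fs <- 20
  x <- generate_test_signal("two_tone", fs, 6.4, f0 = 2, f1 = 8)
  P <- tfr_pwv(x, fs = fs, n_freq = 64)
  SP <- tfr_spwv(x, fs = fs, n_freq = 64)
  # cross-terms live midway between the tones (around 5 Hz)
  mid <- which(P$freqs > 4 & P$freqs < 6)
  interior <- 30:98
  expect_lt(max(abs(SP$values[interior, mid])),
            max(abs(P$values[interior, mid])))
})

test_that("reassignment relocates but conserves absolute mass", {
  set.seed(7)
  for (kind in c("spectrogram", "gabor", "pwv", "spwv")) {
    x <- rnorm(48)
    base_tag <- c(spectrogram = "tfrsp", gabor = "tfrgabor",
                  pwv = "tfrpwv", spwv = "tfrspwv")[kind]
    base <- tfr_compute(x, method = base_tag, n_freq = 32)
    re <- tfr_reassign(kind, x, n_freq = 32)
    expect_true(all(re$values >= 0))
    expect_lt(abs(sum(re$values) - sum(abs(base$values))) /
                sum(abs(base$values)), 1e-8)
  }
  z <- tfr_reassign("spectrogram", numeric(32), n_freq = 16)
  expect_equal(max(abs(z$values)), 0)
  expect_error(tfr_reassign("wavelet", rnorm(32)), "arg")
})

test_that("the reassigned spectrogram concentrates a pure tone", {
  fs <- 20
  x <- generate_test_signal("tone", fs, 8, f0 = 4)
  rs <- tfr_reassign("spectrogram", x, fs = fs, n_freq = 64)
  per_freq <- colSums(rs$values)
  k0 <- which.min(abs(rs$freqs - 4))
  expect_gte(sum(per_freq[(k0 - 1):(k0 + 1)]) / sum(per_freq), 0.95)
})

test_that("fast reassigned transforms match the direct-sum transcription", {
  set.seed(8)
  x <- rnorm(40)
  for (m in c("tfrrsp", "tfrrgab", "tfrrpwv", "tfrrspwv")) {
    fast <- tfr_compute(x, method = m, n_freq = 16)
    slow <- oracle_tfr(x, m, 16)
    expect_lt(max(abs(fast$values - slow)) / max(slow), 1e-10)
  }
})

test_that("all methods are covariant to time translation in the interior", {
  set.seed(9)
  n <- 72; s <- 5
  burst <- exp(-0.5 * ((1:24 - 12) / 4)^2) * sin(2 * pi * 0.3 * (1:24))
  x <- numeric(n); x[25:48] <- burst
  xs <- numeric(n); xs[(25 + s):(48 + s)] <- burst
  for (m in tfr_methods()) {
    A <- tfr_compute(x, method = m, n_freq = 16)$values
    B <- tfr_compute(xs, method = m, n_freq = 16)$values
    interior <- 22:50
    expect_lt(max(abs(B[interior + s, ] - A[interior, ])) /
                max(abs(A)), 1e-6)
  }
})

test_that("each reassigned TFR of a chirp is more concentrated than its base", {
  fs <- 20
  ch <- generate_test_signal("chirp", fs, 8, f0 = 1, f1 = 8)
  pairs <- list(c("tfrsp", "tfrrsp"), c("tfrgabor", "tfrrgab"),
                c("tfrpwv", "tfrrpwv"), c("tfrspwv", "tfrrspwv"))
  for (p in pairs) {
    e_base <- renyi_entropy(
      normalize_window(tfr_compute(ch, fs, p[1])$values), 3)
    e_re <- renyi_entropy(
      normalize_window(tfr_compute(ch, fs, p[2])$values), 3)
    expect_lt(e_re, e_base)
  }
})
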