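# Literal brute-force transcriptions of the defining sums, kept free of the
# package's FFT machinery so they can serve as independent oracles.

oracle_spectrogram <- function(x, hw, n_freq) {
  T <- length(x); n_fft <- 2L * n_freq; L <- (hw$length - 1L) / 2L
  out <- matrix(0, T, n_freq)
  for (t in seq_len(T)) {
    for (k in 0:(n_freq - 1L)) {
      s <- 0 + 0i
      for (u in seq_len(T)) {
        d <- u - t
        if (abs(d) <= L)
          s <- s + x[u] * Conj(hw$values[d + L + 1L]) *
            exp(-2i * pi * k * u / n_fft)
      }
      out[t, k + 1L] <- Mod(s)^2
    }
  }
  out
}

oracle_pwv <- function(xa, hw, n_freq) {
  T <- length(xa); L <- (hw$length - 1L) / 2L
  out <- matrix(0, T, n_freq)
  for (t in seq_len(T)) {
    for (k in 0:(n_freq - 1L)) {
      s <- 0 + 0i
      for (m in -L:L) {
        if (t + m >= 1 && t + m <= T && t - m >= 1 && t - m <= T)
          s <- s + hw$values[m + L + 1L] * xa[t + m] * Conj(xa[t - m]) *
            exp(-2i * pi * k * m / n_freq)
      }
      out[t, k + 1L] <- Re(s)
    }
  }
  out
}

oracle_spwv <- function(xa, hw, gw, n_freq) {
  T <- length(xa); L <- (hw$length - 1L) / 2L; Lg <- (gw$length - 1L) / 2L
  out <- matrix(0, T, n_freq)
  for (t in seq_len(T)) {
    for (k in 0:(n_freq - 1L)) {
      s <- 0 + 0i
      for (m in -L:L) {
        inner <- 0 + 0i
        for (u in -Lg:Lg) {
          tt <- t + u
          if (tt + m >= 1 && tt + m <= T && tt - m >= 1 && tt - m <= T)
            inner <- inner + gw$values[u + Lg + 1L] * xa[tt + m] *
              Conj(xa[tt - m])
        }
        s <- s + hw$values[m + L + 1L] * inner * exp(-2i * pi * k * m / n_freq)
      }
      out[t, k + 1L] <- Re(s)
    }
  }
  out
}

# direct-sum STFT with an arbitrary window-value vector (for centroids)
.oracle_stft <- function(x, wvals, tau, n_fft) {
  T <- length(x)
  out <- matrix(0 + 0i, T, n_fft)
  for (t in seq_len(T)) {
    for (k in 0:(n_fft - 1L)) {
      s <- 0 + 0i
      for (j in seq_along(tau)) {
        u <- t + tau[j]
        if (u >= 1 && u <= T)
          s <- s + x[u] * wvals[j] * exp(-2i * pi * k * tau[j] / n_fft)
      }
      out[t, k + 1L] <- s
    }
  }
  out
}

.oracle_snap <- function(v, n) min(max(ceiling(v - 0.5), 1L), n)

.oracle_relocate <- function(base, dt, dk, eps = 1e-12) {
  mass <- abs(base)
  nt <- nrow(mass); nk <- ncol(mass)
  floor_mass <- eps * max(mass)
  out <- matrix(0, nt, nk)
  for (t in seq_len(nt)) {
    for (k in seq_len(nk)) {
      if (mass[t, k] > floor_mass &&
          is.finite(dt[t, k]) && is.finite(dk[t, k])) {
        tt <- .oracle_snap(t + dt[t, k], nt)
        kk <- .oracle_snap(k + dk[t, k], nk)
      } else {
        tt <- t; kk <- k
      }
      out[tt, kk] <- out[tt, kk] + mass[t, k]
    }
  }
  out
}

# brute-force reassigned spectrogram / Gabor (direct-sum transforms)
oracle_reassigned_stft <- function(x, hw, n_freq) {
  n_fft <- 2L * n_freq
  Fh <- .oracle_stft(x, hw$values, hw$tau, n_fft)[, seq_len(n_freq)]
  Fth <- .oracle_stft(x, hw$tau * hw$values, hw$tau, n_fft)[, seq_len(n_freq)]
  Fdh <- .oracle_stft(x, hw$deriv, hw$tau, n_fft)[, seq_len(n_freq)]
  base <- Mod(Fh)^2
  denom <- Fh
  denom[Mod(denom) == 0] <- NA_complex_
  dt <- Re(Fth / denom)
  dk <- -Im(Fdh / denom) * n_fft / (2 * pi)
  .oracle_relocate(base, dt, dk)
}

oracle_reassigned_pwv <- function(xa, hw, n_freq) {
  base <- oracle_pwv(xa, hw, n_freq)
  dwin <- hw; dwin$values <- hw$deriv
  aux <- matrix(0, length(xa), n_freq)
  T <- length(xa); L <- (hw$length - 1L) / 2L
  for (t in seq_len(T)) {
    for (k in 0:(n_freq - 1L)) {
      s <- 0 + 0i
      for (m in -L:L) {
        if (t + m >= 1 && t + m <= T && t - m >= 1 && t - m <= T)
          s <- s + hw$deriv[m + L + 1L] * xa[t + m] * Conj(xa[t - m]) *
            exp(-2i * pi * k * m / n_freq)
      }
      aux[t, k + 1L] <- Im(s)
    }
  }
  denom <- base
  denom[denom == 0] <- NA_real_
  dk <- -aux / denom * n_freq / (2 * pi)
  dt <- matrix(0, nrow(base), ncol(base))
  .oracle_relocate(base, dt, dk)
}

oracle_reassigned_spwv <- function(xa, hw, gw, n_freq) {
  base <- oracle_spwv(xa, hw, gw, n_freq)
  gt <- gw; gt$values <- gw$tau * gw$values
  dh <- hw; dh$values <- hw$deriv
  num_t <- oracle_spwv_complex(xa, hw, gt, n_freq)
  num_k <- oracle_spwv_complex(xa, dh, gw, n_freq)
  denom <- base
  denom[denom == 0] <- NA_real_
  dt <- Re(num_t) / denom
  dk <- -Im(num_k) / denom * n_freq / (2 * pi)
  .oracle_relocate(base, dt, dk)
}

# complex-valued variant of the smoothed pseudo Wigner-Ville sum
oracle_spwv_complex <- function(xa, hw, gw, n_freq) {
  T <- length(xa); L <- (hw$length - 1L) / 2L; Lg <- (gw$length - 1L) / 2L
  out <- matrix(0 + 0i, T, n_freq)
  for (t in seq_len(T)) {
    for (k in 0:(n_freq - 1L)) {
      s <- 0 + 0i
      for (m in -L:L) {
        inner <- 0 + 0i
        for (u in -Lg:Lg) {
          tt <- t + u
          if (tt + m >= 1 && tt + m <= T && tt - m >= 1 && tt - m <= T)
            inner <- inner + gw$values[u + Lg + 1L] * xa[tt + m] *
              Conj(xa[tt - m])
        }
        s <- s + hw$values[m + L + 1L] * inner * exp(-2i * pi * k * m / n_freq)
      }
      out[t, k + 1L] <- s
    }
  }
  out
}

oracle_renyi <- function(p, alpha) (1 / (1 - alpha)) * log2(sum(p^alpha))

oracle_shannon <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log2(v)
  s
}

# brute-force TFR of any method tag, on the package's default windows
oracle_tfr <- function(x, method, n_freq) {
  dw <- default_windows(length(x))
  xa <- analytic_signal(x)
  switch(method,
    tfrsp = oracle_spectrogram(x, dw$h, n_freq),
    tfrgabor = oracle_spectrogram(x, dw$gabor, n_freq),
    tfrpwv = oracle_pwv(xa, dw$h, n_freq),
    tfrspwv = oracle_spwv(xa, dw$h, dw$g, n_freq),
    tfrrsp = oracle_reassigned_stft(x, dw$h, n_freq),
    tfrrgab = oracle_reassigned_stft(x, dw$gabor, n_freq),
    tfrrpwv = oracle_reassigned_pwv(xa, dw$h, n_freq),
    tfrrspwv = oracle_reassigned_spwv(xa, dw$h, dw$g, n_freq),
    stop("unknown method"))
}
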