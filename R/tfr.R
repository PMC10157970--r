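#' Smoothing windows for time-frequency analysis
#'
#' Constructs an odd-length, symmetric, unit-peak smoothing window together
#' with its analytic derivative (needed by the reassignment operators) and
#' its lag-weighted variant.
#'
#' @param family `"hamming"` or `"gaussian"`.
#' @param length odd window length in samples.
#' @param sigma Gaussian standard deviation in samples (default `length/6`).
#' @return list of class `tfr_window` with elements `values`, `deriv`
#'   (d/dtau), `tau` (sample offsets `-L..L`), `family`, `length`.
#' @export
tfr_window <- function(family = c("hamming", "gaussian"), length,
                       sigma = length / 6) {
  family <- match.arg(family)
  length <- as.integer(length)
  if (length < 1L || length %% 2L == 0L)
    stop("window length must be odd and positive, got ", length)
  L <- (length - 1L) %/% 2L
  tau <- seq.int(-L, L)
  if (family == "hamming") {
    if (L == 0L) {
      v <- 1; dv <- 0
    } else {
      v <- 0.54 + 0.46 * cos(pi * tau / L)
      dv <- -0.46 * (pi / L) * sin(pi * tau / L)
    }
  } else {
    v <- exp(-0.5 * (tau / sigma)^2)
    dv <- -(tau / sigma^2) * v
  }
  structure(list(values = v, deriv = dv, tau = tau,
                 family = family, length = length),
            class = "tfr_window")
}

# next odd integer >= x (at least 3)
.next_odd <- function(x) {
  n <- max(3L, as.integer(ceiling(x)))
  if (n %% 2L == 0L) n + 1L else n
}

#' Default smoothing windows for a signal of given length
#'
#' Hamming frequency-smoothing window `h` of the next odd length at or above
#' a quarter of the signal; Hamming time-smoothing window `g` of the next
#' odd length at or above a tenth of the signal; a Gaussian of the same
#' length as `h` (sigma = length/6) for the Gabor representation.
#'
#' @param n signal length in samples.
#' @return list with `tfr_window` elements `h`, `g`, `gabor`.
#' @export
default_windows <- function(n) {
  lh <- .next_odd(n / 4)
  list(h = tfr_window("hamming", lh),
       g = tfr_window("hamming", .next_odd(n / 10)),
       gabor = tfr_window("gaussian", lh))
}

#' Discrete analytic signal
#'
#' FFT-based analytic signal: the output's real part equals the input and
#' its spectrum vanishes on the negative-frequency bins, following the
#' usual discrete Hilbert convention (DC and, for even lengths, the Nyquist
#' bin are kept with unit weight).
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty input")
  if (is.complex(x)) stop("`x` must be real")
  X <- stats::fft(x)
  w <- numeric(n)
  if (n %% 2L == 0L) {
    w[1] <- 1; w[n / 2 + 1] <- 1
    if (n > 2) w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1
    if (n > 1) w[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * w, inverse = TRUE) / n
}

# Construct a tfr_matrix object (values stored time x frequency)
.tfr_matrix <- function(values, times, freqs, method, window_spec) {
  structure(list(values = values, times = times, freqs = freqs,
                 method = method, window_spec = window_spec),
            class = "tfr_matrix")
}

#' @export
print.tfr_matrix <- function(x, ...) {
  cat(sprintf("<tfr_matrix> %s: %d time bins x %d frequency bins\n",
              x$method, nrow(x$values), ncol(x$values)))
  cat(sprintf("  t: %.3f..%.3f s, f: %.3f..%.3f Hz\n",
              min(x$times), max(x$times), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' @export
plot.tfr_matrix <- function(x, ...) {
  graphics::image(x$times, x$freqs, abs(x$values),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  main = x$method, ...)
  invisible(x)
}

# Sliding-window kernel -> full-bin FFT transform.
# rows: window value per lag (already multiplied in); returns n_fft x T
# complex matrix F[k+1, t] = sum_tau kern[tau, t] * exp(-2i*pi*k*tau/n_fft).
.lag_fft <- function(kern, tau, n_fft) {
  rpos <- (tau %% n_fft) + 1L
  K <- matrix(0i, n_fft, ncol(kern))
  if (anyDuplicated(rpos)) {
    for (j in seq_along(rpos)) K[rpos[j], ] <- K[rpos[j], ] + kern[j, ]
  } else {
    K[rpos, ] <- kern
  }
  stats::mvfft(K)
}

# STFT kernel matrix: rows lag tau in -L..L, columns time 1..T,
# entries x[t + tau] * h[tau] (zero outside the signal).
.stft_kernel <- function(x, hv, tau) {
  T <- length(x)
  idx <- outer(tau, seq_len(T), `+`)
  ok <- idx >= 1L & idx <= T
  xm <- matrix(if (is.complex(x)) 0i else 0, length(tau), T)
  xm[ok] <- x[idx[ok]]
  xm * hv
}

# Full STFT (all n_fft bins); hw is a tfr_window.
.stft <- function(x, hw, n_fft, which = c("h", "th", "dh")) {
  which <- match.arg(which)
  hv <- switch(which, h = hw$values, th = hw$tau * hw$values, dh = hw$deriv)
  .lag_fft(.stft_kernel(x, hv, hw$tau), hw$tau, n_fft)
}

# Wigner-Ville lag-product kernel B[tau_idx, t] = x[t+tau] * Conj(x[t-tau])
.wv_kernel <- function(x, tau) {
  T <- length(x)
  i1 <- outer(tau, seq_len(T), `+`)
  i2 <- outer(-tau, seq_len(T), `+`)
  ok <- i1 >= 1L & i1 <= T & i2 >= 1L & i2 <= T
  out <- matrix(0i, length(tau), T)
  out[ok] <- x[i1[ok]] * Conj(x[i2[ok]])
  out
}

# time-smoothing matrix G[u, t] = g(u - t) for u, t = 1..T
.time_smear <- function(gw, T, weighted = FALSE) {
  diffs <- outer(seq_len(T), seq_len(T), `-`)
  G <- matrix(0, T, T)
  ok <- abs(diffs) <= (gw$length - 1L) %/% 2L
  gv <- gw$values
  if (weighted) gv <- gw$tau * gv
  G[ok] <- gv[diffs[ok] + (gw$length - 1L) %/% 2L + 1L]
  G
}

.tfr_axes <- function(n, fs, t0, n_freq) {
  list(times = t0 + (seq_len(n) - 1L) / fs,
       freqs = (seq_len(n_freq) - 1L) * fs / (2L * n_freq))
}

#' Spectrogram
#'
#' Squared magnitude of the short-time Fourier transform with frequency
#' smoothing window `h`: the local energy of the signal around each
#' time-frequency point. Frequencies are reported on `n_freq` bins covering
#' `[0, fs/2)`.
#'
#' @param x numeric (or complex) signal.
#' @param fs sampling rate in Hz (default 1, i.e. normalized frequency).
#' @param h a [tfr_window()] (default: Hamming, next odd >= length(x)/4).
#' @param n_freq number of frequency bins on `[0, fs/2)`.
#' @param t0 time of the first sample (s).
#' @param two_sided keep all `2 * n_freq` FFT bins covering `[0, fs)`;
#'   mainly for energy-bookkeeping checks.
#' @return a `tfr_matrix` (time bins x frequency bins, nonnegative).
#' @export
tfr_spectrogram <- function(x, fs = 1, h = NULL, n_freq = 64, t0 = 0,
                            two_sided = FALSE) {
  if (is.null(h)) h <- default_windows(length(x))$h
  if (h$length > length(x))
    stop("window (", h$length, ") longer than signal (", length(x), ")")
  n_fft <- 2L * n_freq
  if (n_fft < h$length)
    stop("need 2 * n_freq >= window length")
  F <- .stft(x, h, n_fft)
  S <- Mod(F)^2
  keep <- if (two_sided) seq_len(n_fft) else seq_len(n_freq)
  ax <- .tfr_axes(length(x), fs, t0, n_freq)
  freqs <- if (two_sided) (seq_len(n_fft) - 1L) * fs / n_fft else ax$freqs
  .tfr_matrix(t(S[keep, , drop = FALSE]), ax$times, freqs,
              "tfrsp", list(h = h))
}

#' Gabor representation
#'
#' Squared-magnitude Gabor coefficients on the time-frequency lattice:
#' identical to the spectrogram computed with a Gaussian analysis window.
#'
#' @inheritParams tfr_spectrogram
#' @param h a Gaussian [tfr_window()]; default Gaussian of the spectrogram
#'   default length with `sigma = length/6`.
#' @return a `tfr_matrix` (nonnegative).
#' @export
tfr_gabor <- function(x, fs = 1, h = NULL, n_freq = 64, t0 = 0) {
  if (is.null(h)) h <- default_windows(length(x))$gabor
  if (h$family != "gaussian")
    stop("the Gabor representation uses a Gaussian window")
  out <- tfr_spectrogram(x, fs = fs, h = h, n_freq = n_freq, t0 = t0)
  out$method <- "tfrgabor"
  out
}

#' Pseudo Wigner-Ville distribution
#'
#' Discrete integer-lag pseudo Wigner-Ville distribution
#' `PW[t, k] = sum_tau h(tau) x(t+tau) x*(t-tau) exp(-2i pi k tau / n_freq)`
#' with frequency bins `k * fs / (2 n_freq)`, i.e. the classical doubled
#' frequency convention of the discrete Wigner-Ville family. The output is
#' real but may be negative (cross-term oscillation).
#'
#' @inheritParams tfr_spectrogram
#' @param h odd-length frequency smoothing [tfr_window()].
#' @param analytic precondition real input with [analytic_signal()]
#'   (default `TRUE`) to suppress negative-frequency interference.
#' @return a `tfr_matrix` (real-valued).
#' @export
tfr_pwv <- function(x, fs = 1, h = NULL, n_freq = 64, t0 = 0,
                    analytic = TRUE) {
  if (is.null(h)) h <- default_windows(length(x))$h
  if (h$length %% 2L == 0L) stop("`h` must have odd length")
  if (analytic && !is.complex(x)) x <- analytic_signal(x)
  kern <- .wv_kernel(x, h$tau) * h$values
  F <- .lag_fft(kern, h$tau, n_freq)
  vals <- t(Re(F))
  ax <- .tfr_axes(length(x), fs, t0, n_freq)
  out <- .tfr_matrix(vals, ax$times, ax$freqs, "tfrpwv", list(h = h))
  out$imag_residual <- max(abs(Im(F))) / max(abs(Re(F)), .Machine$double.eps)
  out
}

#' Smoothed pseudo Wigner-Ville distribution
#'
#' Pseudo Wigner-Ville with an additional time-smoothing window `g`
#' convolved along time before the lag Fourier transform; `g` equal to a
#' unit impulse reproduces [tfr_pwv()] exactly.
#'
#' @inheritParams tfr_pwv
#' @param g odd-length time smoothing [tfr_window()].
#' @return a `tfr_matrix` (real-valued).
#' @export
tfr_spwv <- function(x, fs = 1, h = NULL, g = NULL, n_freq = 64, t0 = 0,
                     analytic = TRUE) {
  dw <- NULL
  if (is.null(h) || is.null(g)) dw <- default_windows(length(x))
  if (is.null(h)) h <- dw$h
  if (is.null(g)) g <- dw$g
  if (h$length %% 2L == 0L || g$length %% 2L == 0L)
    stop("`h` and `g` must have odd length")
  if (analytic && !is.complex(x)) x <- analytic_signal(x)
  B <- .wv_kernel(x, h$tau)
  G <- .time_smear(g, length(x))
  kern <- (B %*% G) * h$values
  F <- .lag_fft(kern, h$tau, n_freq)
  ax <- .tfr_axes(length(x), fs, t0, n_freq)
  .tfr_matrix(t(Re(F)), ax$times, ax$freqs, "tfrspwv", list(h = h, g = g))
}

# round half toward the lower index, then clip into 1..n
.snap_bin <- function(v, n) {
  r <- ceiling(v - 0.5)
  pmin(pmax(r, 1L), n)
}

# Relocate |base| mass to the rounded centroid bins. dt: time displacement
# in samples; dk: frequency displacement in bins (same orientation as the
# stored time x frequency matrix). Cells below eps * max|base| (or with a
# non-finite centroid) keep their mass in place.
.reassign_mass <- function(base_vals, dt, dk, eps = 1e-12) {
  mass <- abs(base_vals)
  nt <- nrow(mass); nk <- ncol(mass)
  tgrid <- matrix(seq_len(nt), nt, nk)
  kgrid <- matrix(seq_len(nk), nt, nk, byrow = TRUE)
  floor_mass <- eps * max(mass)
  live <- mass > floor_mass & is.finite(dt) & is.finite(dk)
  that <- tgrid; khat <- kgrid
  that[live] <- .snap_bin(tgrid[live] + dt[live], nt)
  khat[live] <- .snap_bin(kgrid[live] + dk[live], nk)
  li <- that + (khat - 1L) * nt
  acc <- rowsum(as.vector(mass), as.vector(li))
  out <- matrix(0, nt, nk)
  out[as.integer(rownames(acc))] <- acc
  out
}

# displacement fields for STFT-family reassignment (spectrogram / Gabor)
.stft_displacements <- function(x, h, n_fft, keep) {
  Fh <- .stft(x, h, n_fft)[keep, , drop = FALSE]
  Fth <- .stft(x, h, n_fft, "th")[keep, , drop = FALSE]
  Fdh <- .stft(x, h, n_fft, "dh")[keep, , drop = FALSE]
  denom <- Fh
  denom[Mod(denom) == 0] <- NA_complex_
  # time centroid: t + Re{F_th / F_h}; frequency: k - Im{F_dh / F_h} * n/(2pi)
  list(dt = t(Re(Fth / denom)),
       dk = t(-Im(Fdh / denom) * n_fft / (2 * pi)),
       base = t(Mod(Fh)^2))
}

#' Reassigned time-frequency representations
#'
#' Computes the reassigned variant of one of the four base representations.
#' Each cell's absolute mass is relocated to the grid cell nearest the local
#' center of gravity of the signal energy, estimated with the classical
#' ratio-of-auxiliary-transforms operators: for the short-time Fourier
#' family, `t_hat = t + Re{F_Th / F_h}` and
#' `nu_hat = nu - Im{F_Dh / F_h} / (2 pi)` (with `Th(tau) = tau h(tau)` and
#' `Dh = dh/dtau`); for the Wigner-Ville family, the analogous ratios with
#' the lag-weighted time window and the frequency-window derivative. Ties
#' round toward the lower bin index, mass landing outside the grid is
#' clipped to the boundary bin, and cells below `1e-12` of the peak keep
#' their mass in place; total absolute mass is conserved exactly.
#'
#' @param kind base representation: `"spectrogram"`, `"gabor"`, `"pwv"`
#'   or `"spwv"`.
#' @inheritParams tfr_spwv
#' @param h,g smoothing windows (defaults as in the base representations).
#' @return a nonnegative `tfr_matrix` with method tag `tfrrsp`, `tfrrgab`,
#'   `tfrrpwv` or `tfrrspwv`.
#' @export
tfr_reassign <- function(kind = c("spectrogram", "gabor", "pwv", "spwv"),
                         x, fs = 1, h = NULL, g = NULL, n_freq = 64, t0 = 0,
                         analytic = TRUE) {
  kind <- match.arg(kind)
  n <- length(x)
  dw <- default_windows(n)
  ax <- .tfr_axes(n, fs, t0, n_freq)
  if (kind %in% c("spectrogram", "gabor")) {
    if (is.null(h)) h <- if (kind == "gabor") dw$gabor else dw$h
    n_fft <- 2L * n_freq
    dsp <- .stft_displacements(x, h, n_fft, seq_len(n_freq))
    vals <- .reassign_mass(dsp$base, dsp$dt, dsp$dk)
    tag <- if (kind == "gabor") "tfrrgab" else "tfrrsp"
    return(.tfr_matrix(vals, ax$times, ax$freqs, tag, list(h = h)))
  }
  if (is.null(h)) h <- dw$h
  if (analytic && !is.complex(x)) x <- analytic_signal(x)
  if (kind == "pwv") {
    B <- .wv_kernel(x, h$tau)
    Fh <- .lag_fft(B * h$values, h$tau, n_freq)
    Fdh <- .lag_fft(B * h$deriv, h$tau, n_freq)
    base <- t(Re(Fh))
    denom <- t(Re(Fh))
    denom[denom == 0] <- NA_real_
    dk <- -t(Im(Fdh)) / denom * n_freq / (2 * pi)
    dt <- matrix(0, nrow(base), ncol(base))  # no time spread to undo
    vals <- .reassign_mass(base, dt, dk)
    return(.tfr_matrix(vals, ax$times, ax$freqs, "tfrrpwv", list(h = h)))
  }
  # spwv
  if (is.null(g)) g <- dw$g
  B <- .wv_kernel(x, h$tau)
  G <- .time_smear(g, n)
  Gt <- .time_smear(g, n, weighted = TRUE)
  Fgh <- .lag_fft((B %*% G) * h$values, h$tau, n_freq)
  Ftgh <- .lag_fft((B %*% Gt) * h$values, h$tau, n_freq)
  Fgdh <- .lag_fft((B %*% G) * h$deriv, h$tau, n_freq)
  base <- t(Re(Fgh))
  denom <- base
  denom[denom == 0] <- NA_real_
  dt <- t(Re(Ftgh)) / denom
  dk <- -t(Im(Fgdh)) / denom * n_freq / (2 * pi)
  vals <- .reassign_mass(base, dt, dk)
  .tfr_matrix(vals, ax$times, ax$freqs, "tfrrspwv", list(h = h, g = g))
}

#' Method tags of the available representations
#' @return character vector of the eight method tags.
#' @export
tfr_methods <- function() {
  c("tfrsp", "tfrrsp", "tfrgabor", "tfrrgab",
    "tfrpwv", "tfrrpwv", "tfrspwv", "tfrrspwv")
}

#' Compute a time-frequency representation by method tag
#'
#' Dispatcher over the eight Cohen's-class representations: spectrogram
#' (`tfrsp`), reassigned spectrogram (`tfrrsp`), Gabor (`tfrgabor`),
#' reassigned Gabor (`tfrrgab`), pseudo Wigner-Ville (`tfrpwv`), reassigned
#' pseudo Wigner-Ville (`tfrrpwv`), smoothed pseudo Wigner-Ville
#' (`tfrspwv`) and reassigned smoothed pseudo Wigner-Ville (`tfrrspwv`).
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param method one of [tfr_methods()].
#' @param n_freq frequency bins on `[0, fs/2)`.
#' @param t0 time of the first sample (s).
#' @param h,g optional smoothing windows.
#' @param analytic analytic-signal preconditioning for the Wigner-Ville
#'   family.
#' @return a `tfr_matrix`.
#' @export
tfr_compute <- function(x, fs = 1, method = "tfrsp", n_freq = 64, t0 = 0,
                        h = NULL, g = NULL, analytic = TRUE) {
  switch(method,
    tfrsp    = tfr_spectrogram(x, fs, h, n_freq, t0),
    tfrgabor = tfr_gabor(x, fs, h, n_freq, t0),
    tfrpwv   = tfr_pwv(x, fs, h, n_freq, t0, analytic),
    tfrspwv  = tfr_spwv(x, fs, h, g, n_freq, t0, analytic),
    tfrrsp   = tfr_reassign("spectrogram", x, fs, h, g, n_freq, t0, analytic),
    tfrrgab  = tfr_reassign("gabor", x, fs, h, g, n_freq, t0, analytic),
    tfrrpwv  = tfr_reassign("pwv", x, fs, h, g, n_freq, t0, analytic),
    tfrrspwv = tfr_reassign("spwv", x, fs, h, g, n_freq, t0, analytic),
    stop("unknown TFR method: ", method)
  )
}
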