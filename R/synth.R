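#' Configuration of the synthetic motor-imagery dataset generator
#'
#' Describes a multi-participant sensorimotor-rhythm paradigm emulation:
#' trials of 7.5 s (epoch -5.5..2 s around MI onset) containing a baseline
#' segment, a pre-MI cue segment and a 1.5 s MI segment, two movement
#' classes and two guidance conditions, recorded on the 31-channel motor
#' montage plus three EOG channels at 1 kHz.
#'
#' Trial content: pink (1/f) background noise on every channel; ongoing mu
#' (10 Hz) and beta (20 Hz) oscillations over the sensorimotor strip that
#' desynchronize by `erd_depth` over the contralateral channels during MI;
#' a slow movement-related cortical potential (MRCP, 0.2-5 Hz band) of
#' `mrcp_amplitude` during MI whose spatial pattern differs slightly
#' between classes; `complexity_boost` additional low-frequency transient
#' tone/chirp components injected only during MI with class-independent
#' random parameters (these carry the time-frequency complexity change
#' that entropy features detect); and stereotyped 300 ms biphasic blinks
#' on the EOG channels leaking into EEG by `eog_gain` with a frontal
#' gradient.
#'
#' @param n_participants number of synthetic participants.
#' @param n_trials_per_class trials per movement class per participant
#'   (split evenly over conditions).
#' @param classes movement-class labels.
#' @param conditions guidance-condition labels (pure labels: no
#'   physiological difference is generated unless effects are configured).
#' @param fs sampling rate (Hz).
#' @param epoch_window trial span in seconds relative to MI onset.
#' @param segment_windows paradigm segments, see [default_segment_windows()].
#' @param mrcp_amplitude MRCP peak amplitude (microvolts).
#' @param erd_depth fractional mu/beta attenuation during MI, in `[0, 1]`.
#' @param complexity_boost number of extra transient components during MI.
#' @param noise_sigma broadband RMS of the 1/f background (microvolts).
#' @param smr_amplitude mu rhythm amplitude (microvolts); beta is half.
#' @param transient_amplitude typical amplitude (microvolts) of one MI
#'   transient component; per-component amplitudes are drawn uniformly
#'   within 30 percent of this value.
#' @param slow_rhythm_amplitude amplitude (microvolts) of the ongoing slow
#'   (about 1-1.6 Hz) cortical rhythm present throughout the recording; it
#'   is the single dominant component of the low-frequency analysis band
#'   during baseline, against which the extra MI components raise the
#'   time-frequency complexity.
#' @param eog_gain ocular leakage coefficient into frontal EEG.
#' @param gap inter-trial gap (s).
#' @param seed base RNG seed; participant `p` uses `seed + 7919 * p`.
#' @param keep_components store per-trial clean component traces in the
#'   ground truth (memory-hungry; for validation only).
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_participants = 5, n_trials_per_class = 40,
                         classes = c("right", "up"),
                         conditions = c("VtG", "noVtG"),
                         fs = 1000, epoch_window = c(-5.5, 2),
                         segment_windows = default_segment_windows(),
                         mrcp_amplitude = 5, erd_depth = 0.5,
                         complexity_boost = 4, noise_sigma = 2,
                         smr_amplitude = 4, slow_rhythm_amplitude = 8,
                         transient_amplitude = 10, eog_gain = 0.2, gap = 1,
                         seed = 1, keep_components = FALSE) {
  stopifnot(n_participants >= 1, n_trials_per_class >= 1,
            erd_depth >= 0, erd_depth <= 1, fs > 0)
  for (nm in names(segment_windows)) {
    w <- segment_windows[[nm]]
    if (w[1] < epoch_window[1] || w[2] > epoch_window[2])
      stop("segment `", nm, "` outside the epoch window")
  }
  structure(as.list(environment()), class = "synth_config")
}

# approximate 10/20 grid coordinates from a channel name:
# x lateral (negative = left), y anterior-posterior (F row = 2 .. P row = -2)
.chan_pos <- function(names) {
  row <- sub("([0-9]+|z)$", "", names)
  num <- sub("^.*?([0-9]+|z)$", "\\1", names)
  y <- c(F = 2, FC = 1, C = 0, CP = -1, P = -2)[row]
  k <- suppressWarnings(as.integer(num))          # NA for the z (midline) row
  x <- ifelse(is.na(k), 0, ifelse(k %% 2L == 1L, -(k + 1L) / 2L, k / 2L))
  cbind(x = as.numeric(x), y = as.numeric(y))
}

# 1/f amplitude-shaped Gaussian noise, unit sd, length n
.pink_noise <- function(n, fs, floor_hz = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- 1 / sqrt(pmax(f, floor_hz))
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Hann-tapered envelope on a sample index range
.taper <- function(n) {
  if (n < 4L) return(rep(1, n))
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

.generate_participant <- function(cfg, p) {
  set.seed(cfg$seed + 7919L * p)
  eeg_names <- motor_montage()
  eog_names <- c("EOG1", "EOG2", "EOG3")
  ch_names <- c(eeg_names, eog_names)
  n_eeg <- length(eeg_names)
  pos <- .chan_pos(eeg_names)
  fs <- cfg$fs
  trial_len <- diff(cfg$epoch_window)
  n_classes <- length(cfg$classes)
  n_trials <- cfg$n_trials_per_class * n_classes
  slot <- trial_len + cfg$gap
  n_samp <- as.integer(round((n_trials * slot + cfg$gap) * fs))

  # trial table: class x condition balanced, randomized order
  lab <- rep(cfg$classes, each = cfg$n_trials_per_class)
  cond <- unlist(lapply(seq_len(n_classes), function(i)
    rep_len(cfg$conditions, cfg$n_trials_per_class)))
  ord <- sample.int(n_trials)
  lab <- lab[ord]; cond <- cond[ord]
  trial_start <- cfg$gap + (seq_len(n_trials) - 1L) * slot      # seconds
  onset_s <- trial_start - cfg$epoch_window[1]                  # MI onset
  events <- data.frame(sample = as.integer(round(onset_s * fs)) + 1L,
                       label = lab, condition = cond,
                       stringsAsFactors = FALSE)

  data <- matrix(0, length(ch_names), n_samp)
  rownames(data) <- ch_names
  tvec <- (seq_len(n_samp) - 1) / fs

  # (a) 1/f background on every channel
  for (i in seq_along(ch_names))
    data[i, ] <- cfg$noise_sigma * .pink_noise(n_samp, fs)

  # (b) sensorimotor rhythms with MI-locked desynchronization
  smr_w <- exp(-(pos[, "y"]^2) / 2 - (pos[, "x"]^2) / 8)
  erd_sel <- exp(-((pos[, "x"] + 2)^2 + pos[, "y"]^2) / 4)  # centered at C3
  mi_env <- numeric(n_samp)
  ramp <- 0.2
  mi_w <- cfg$segment_windows$mi
  for (k in seq_len(n_trials)) {
    a <- onset_s[k] + mi_w[1]; b <- onset_s[k] + mi_w[2]
    seg <- tvec >= a - ramp & tvec <= b + ramp
    tt <- tvec[seg]
    env <- pmin(1, pmax(0, pmin((tt - (a - ramp)) / ramp,
                                ((b + ramp) - tt) / ramp)))
    mi_env[seg] <- pmax(mi_env[seg], env)
  }
  mu_osc <- sin(2 * pi * 10 * tvec + stats::runif(1, 0, 2 * pi))
  beta_osc <- sin(2 * pi * 20 * tvec + stats::runif(1, 0, 2 * pi))
  # lognormal waxing-waning keeps the envelope positive and its
  # between-segment ratio tight enough that ERD dominates it
  amp_drift <- exp(0.2 * .pink_noise(n_samp, fs, floor_hz = 0.1))
  smr_sig <- (cfg$smr_amplitude * mu_osc + 0.5 * cfg$smr_amplitude *
                beta_osc) * amp_drift
  comp_store <- if (cfg$keep_components)
    array(0, c(n_trials, n_eeg, as.integer(round(trial_len * fs)))) else NULL
  for (i in seq_len(n_eeg)) {
    gain <- smr_w[i] * (1 - cfg$erd_depth * erd_sel[i] * mi_env)
    data[i, ] <- data[i, ] + gain * smr_sig
    if (cfg$keep_components) {
      for (k in seq_len(n_trials)) {
        i0 <- as.integer(round(trial_start[k] * fs)) + 1L
        idx <- i0:(i0 + dim(comp_store)[3] - 1L)
        comp_store[k, i, ] <- (gain * smr_sig)[idx]
      }
    }
  }

  # ongoing slow cortical rhythm: the dominant low-frequency-band component
  # outside MI (single ridge, hence a low-entropy baseline)
  f_slow <- stats::runif(1, 1.2, 1.8)
  slow_osc <- sin(2 * pi * f_slow * tvec + stats::runif(1, 0, 2 * pi))
  slow_drift <- 1 + 0.3 * .pink_noise(n_samp, fs, floor_hz = 0.1)
  slow_w <- exp(-((pos[, "x"] - 0.3)^2 + (pos[, "y"] + 0.5)^2) / 6)
  data[seq_len(n_eeg), ] <- data[seq_len(n_eeg), ] +
    outer(slow_w, cfg$slow_rhythm_amplitude * slow_osc * slow_drift)

  # (c) class-dependent slow movement-related potential during MI
  centers <- list(c(-0.8, -0.1), c(0.1, 0.2), c(-0.3, 1.0), c(1.2, -1.0))
  mrcp_pat <- lapply(seq_len(n_classes), function(i) {
    cc <- centers[[(i - 1L) %% length(centers) + 1L]]
    exp(-((pos[, "x"] - cc[1])^2 + (pos[, "y"] - cc[2])^2) / 3)
  })
  names(mrcp_pat) <- cfg$classes
  mi_len <- mi_w[2] - mi_w[1]
  # (d) extra transient low-frequency components during MI only
  for (k in seq_len(n_trials)) {
    a_samp <- as.integer(round((onset_s[k] + mi_w[1]) * fs)) + 1L
    n_mi <- as.integer(round(mi_len * fs))
    idx <- a_samp:(a_samp + n_mi - 1L)
    tt <- (seq_len(n_mi) - 1) / fs
    # biphasic deflection with its energy inside the analysis band
    bump <- sin(2 * pi * 1.3 * tt) * .taper(n_mi)
    amp <- cfg$mrcp_amplitude * exp(stats::rnorm(1, 0, 0.2))
    pat <- mrcp_pat[[lab[k]]]
    contrib <- outer(pat, amp * bump)
    if (cfg$complexity_boost > 0) {
      for (cb in seq_len(cfg$complexity_boost)) {
        dur <- stats::runif(1, min(1.0, mi_len), mi_len)
        on <- stats::runif(1, 0, mi_len - dur)
        f0 <- stats::runif(1, 1.5, 4.5)
        f1 <- min(4.8, max(1.2, f0 + stats::runif(1, -1.5, 1.5)))
        camp <- cfg$transient_amplitude * stats::runif(1, 0.7, 1.3)
        span <- tt >= on & tt <= on + dur
        ts <- tt[span] - on
        wave <- camp * .taper(sum(span)) *
          sin(2 * pi * (f0 * ts + (f1 - f0) / (2 * dur) * ts^2))
        cpos <- c(stats::runif(1, -2, 2), stats::runif(1, -1, 1))
        cpat <- exp(-((pos[, "x"] - cpos[1])^2 +
                        (pos[, "y"] - cpos[2])^2) / 2)
        contrib[, span] <- contrib[, span] + outer(cpat, wave)
      }
    }
    data[seq_len(n_eeg), idx] <- data[seq_len(n_eeg), idx] + contrib
  }

  # (e) blinks on EOG, leaking into EEG with a frontal gradient
  n_blinks <- max(1L, stats::rpois(1, n_samp / fs / 10))
  blink_len <- as.integer(round(0.3 * fs))
  bt <- (seq_len(blink_len) - 1) / fs
  blink_shape <- sin(2 * pi * bt / 0.3) * .taper(blink_len)
  blink_sig <- numeric(n_samp)
  starts <- sort(sample.int(n_samp - blink_len, n_blinks))
  for (s in starts) {
    amp <- stats::runif(1, 100, 200)
    blink_sig[s:(s + blink_len - 1L)] <-
      blink_sig[s:(s + blink_len - 1L)] + amp * blink_shape
  }
  eog_w <- c(1, 0.8, 0.6)
  for (j in seq_along(eog_names))
    data[n_eeg + j, ] <- data[n_eeg + j, ] + eog_w[j] * blink_sig
  leak <- cfg$eog_gain * (0.2 + 0.8 * (pos[, "y"] + 2) / 4)
  data[seq_len(n_eeg), ] <- data[seq_len(n_eeg), ] +
    outer(leak, blink_sig)

  rec <- continuous_eeg(data, fs = fs, channel_names = ch_names,
                        eog_channels = eog_names, events = events,
                        participant_id = sprintf("synth%02d", p))
  truth <- list(seed = cfg$seed + 7919L * p, events = events,
                erd_channels = eeg_names[erd_sel > 0.7],
                erd_selectivity = stats::setNames(erd_sel, eeg_names),
                mrcp_patterns = mrcp_pat, mi_env_fraction = mean(mi_env))
  if (cfg$keep_components) {
    truth$smr_components <- comp_store
    truth$trial_start_s <- trial_start
  }
  list(recording = rec, truth = truth)
}

#' Generate a synthetic multi-participant motor-imagery dataset
#'
#' @param cfg a [synth_config()].
#' @param participants integer vector of participant indices to generate
#'   (default all). Each participant's stream is seeded independently, so
#'   any subset reproduces exactly the same recordings.
#' @return list with `participants` (list of [continuous_eeg()]) and
#'   `ground_truth` (per-participant seeds, event tables and injected
#'   effect descriptions).
#' @export
generate_dataset <- function(cfg = synth_config(),
                             participants = seq_len(cfg$n_participants)) {
  stopifnot(inherits(cfg, "synth_config"))
  out <- lapply(participants, function(p) .generate_participant(cfg, p))
  list(participants = lapply(out, `[[`, "recording"),
       ground_truth = c(list(config = unclass(cfg)),
                        stats::setNames(lapply(out, `[[`, "truth"),
                                        sprintf("synth%02d", participants))))
}

#' Closed-form test signals
#'
#' Analytic fixtures with documented ground truth for validating the
#' time-frequency and entropy machinery.
#'
#' @param kind `"tone"`, `"two_tone"`, `"chirp"`, `"impulse"` or
#'   `"tone_switch"` (one tone before the switch time, two after).
#' @param fs sampling rate (Hz).
#' @param duration length in seconds (`duration * fs >= 16`).
#' @param f0,f1 component frequencies (Hz); for `"chirp"` the start and
#'   end of the linear frequency sweep.
#' @param amp amplitude.
#' @param t_switch switch time for `"tone_switch"` (default midpoint).
#' @param at impulse time (default midpoint).
#' @return numeric vector of `round(duration * fs)` samples.
#' @export
generate_test_signal <- function(kind = c("tone", "two_tone", "chirp",
                                          "impulse", "tone_switch"),
                                 fs, duration, f0 = fs / 8, f1 = fs / 4,
                                 amp = 1, t_switch = duration / 2,
                                 at = duration / 2) {
  kind <- match.arg(kind)
  n <- as.integer(round(duration * fs))
  if (n < 16L) stop("need duration * fs >= 16")
  t <- (seq_len(n) - 1) / fs
  switch(kind,
    tone = amp * sin(2 * pi * f0 * t),
    two_tone = amp * (sin(2 * pi * f0 * t) + sin(2 * pi * f1 * t)),
    chirp = amp * sin(2 * pi * (f0 * t + (f1 - f0) / (2 * duration) * t^2)),
    impulse = {
      x <- numeric(n)
      x[max(1L, min(n, as.integer(round(at * fs)) + 1L))] <- amp
      x
    },
    tone_switch = {
      x <- amp * sin(2 * pi * f0 * t)
      x[t >= t_switch] <- x[t >= t_switch] +
        amp * sin(2 * pi * f1 * t[t >= t_switch])
      x
    })
}
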