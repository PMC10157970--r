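#' Motor-area channel montage
#'
#' The 31 channels around the sensorimotor strip used for decoding:
#' frontal, fronto-central, central, centro-parietal and parietal rows of
#' the 10/20 extended montage.
#'
#' @return character vector of 31 channel names.
#' @export
motor_montage <- function() {
  c("F3", "F1", "Fz", "F2", "F4",
    "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "P3", "P1", "Pz", "P2", "P4")
}

# minimum signal length accepted by the zero-phase filter (padding needs)
.min_filt_len <- function(order) 6L * (order + 1L)

# forward-backward filtering with odd-reflection end padding, so slow
# filter transients settle outside the retained span
.filtfilt_pad <- function(bf, x, pad) {
  n <- length(x)
  pad <- max(1L, min(n - 1L, as.integer(pad)))
  front <- 2 * x[1] - x[(pad + 1L):2]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(front, x, back))
  as.numeric(y[(pad + 1L):(pad + n)])
}

.bandpass_vec <- function(x, low, high, order, fs) {
  if (length(x) < .min_filt_len(order))
    stop("signal too short for zero-phase filtering (", length(x),
         " samples, need >= ", .min_filt_len(order), ")")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  .filtfilt_pad(bf, x, ceiling(3 * fs / low))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an `order`-th order Butterworth band-pass design forward and
#' backward (`filtfilt`), so the net group delay is zero and the effective
#' magnitude response is the squared one-pass response.
#'
#' @param x a [continuous_eeg()], an [epoch_set()] (filtered per trial and
#'   channel), or a numeric vector.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order one-pass filter order (default 4).
#' @param fs sampling rate; only needed for plain numeric input.
#' @return object of the same type as `x`.
#' @export
eeg_bandpass <- function(x, low, high, order = 4, fs = NULL) {
  UseMethod("eeg_bandpass")
}

.check_band <- function(low, high, fs) {
  if (!(low > 0 && high > low && high < fs / 2))
    stop("invalid band edges: need 0 < low < high < fs/2 (fs = ", fs, " Hz)")
}

#' @export
eeg_bandpass.numeric <- function(x, low, high, order = 4, fs = NULL) {
  if (is.null(fs)) stop("`fs` required for numeric input")
  .check_band(low, high, fs)
  .bandpass_vec(x, low, high, order, fs)
}

#' @export
eeg_bandpass.continuous_eeg <- function(x, low, high, order = 4, fs = NULL) {
  .check_band(low, high, x$fs)
  x$data <- t(apply(x$data, 1L, .bandpass_vec,
                    low = low, high = high, order = order, fs = x$fs))
  rownames(x$data) <- x$channel_names
  x
}

#' @export
eeg_bandpass.epoch_set <- function(x, low, high, order = 4, fs = NULL) {
  .check_band(low, high, x$fs)
  d <- dim(x$data)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      x$data[i, j, ] <- .bandpass_vec(x$data[i, j, ], low, high, order, x$fs)
  x
}

.resample_vec <- function(x, fs_in, fs_out) {
  n_out <- as.integer(ceiling(length(x) * fs_out / fs_in))
  if (fs_out < fs_in) {
    bf <- signal::butter(8, 0.9 * fs_out / fs_in)
    x <- .filtfilt_pad(bf, x, 30 * ceiling(fs_in / fs_out))
  }
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::spline((seq_along(x) - 1) / fs_in, x, xout = t_out)$y
}

#' Resample EEG with anti-alias filtering
#'
#' Decimation applies a zero-phase 8th-order Butterworth anti-alias
#' low-pass at 90 percent of the new Nyquist frequency before
#' interpolating onto the output grid. Output length is
#' `ceiling(n * fs_out / fs_in)` so the duration is preserved within one
#' output sample.
#'
#' @param x a [continuous_eeg()], [epoch_set()] or numeric vector.
#' @param fs_out target rate in Hz (`fs_out <= fs`).
#' @param fs input rate; only for numeric input.
#' @return object of the same type with `fs` updated; event sample indices
#'   of a `continuous_eeg` are rescaled onto the new grid.
#' @export
eeg_resample <- function(x, fs_out, fs = NULL) UseMethod("eeg_resample")

#' @export
eeg_resample.numeric <- function(x, fs_out, fs = NULL) {
  if (is.null(fs)) stop("`fs` required for numeric input")
  if (!is.numeric(fs_out) || fs_out <= 0) stop("`fs_out` must be positive")
  if (fs_out > fs) stop("upsampling not supported: fs_out > fs")
  if (fs_out == fs) return(x)
  .resample_vec(x, fs, fs_out)
}

#' @export
eeg_resample.continuous_eeg <- function(x, fs_out, fs = NULL) {
  if (!is.numeric(fs_out) || fs_out <= 0) stop("`fs_out` must be positive")
  if (fs_out == x$fs) return(x)
  if (fs_out > x$fs) stop("upsampling not supported: fs_out > fs")
  newdata <- t(apply(x$data, 1L, .resample_vec, fs_in = x$fs, fs_out = fs_out))
  if (!is.null(x$events))
    x$events$sample <- pmax(1L, pmin(ncol(newdata),
      as.integer(round((x$events$sample - 1L) * fs_out / x$fs)) + 1L))
  x$data <- newdata
  rownames(x$data) <- x$channel_names
  x$fs <- fs_out
  x
}

#' @export
eeg_resample.epoch_set <- function(x, fs_out, fs = NULL) {
  if (!is.numeric(fs_out) || fs_out <= 0) stop("`fs_out` must be positive")
  if (fs_out == x$fs) return(x)
  if (fs_out > x$fs) stop("upsampling not supported: fs_out > fs")
  d <- dim(x$data)
  n_out <- length(.resample_vec(x$data[1, 1, ], x$fs, fs_out))
  out <- array(0, c(d[1], d[2], n_out))
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      out[i, j, ] <- .resample_vec(x$data[i, j, ], x$fs, fs_out)
  dimnames(out) <- list(NULL, x$channel_names, NULL)
  x$data <- out
  x$fs <- fs_out
  x
}

#' Cut event-locked epochs out of a continuous recording
#'
#' @param x a [continuous_eeg()] with a non-empty event table.
#' @param window length-2 numeric, epoch limits in seconds relative to each
#'   event (e.g. `c(-5.5, 2)`).
#' @param segment_windows paradigm segment annotation attached to the
#'   result; see [default_segment_windows()].
#' @return an [epoch_set()]; trials follow event order, each with
#'   `round(diff(window) * fs)` samples.
#' @export
epoch_trials <- function(x, window, segment_windows = default_segment_windows()) {
  stopifnot(inherits(x, "continuous_eeg"))
  if (is.null(x$events) || nrow(x$events) == 0L)
    stop("recording has no events to epoch around")
  if (length(window) != 2L || window[1] >= window[2])
    stop("`window` must be an increasing length-2 interval in seconds")
  n_samp <- as.integer(round(diff(window) * x$fs))
  offset <- as.integer(round(window[1] * x$fs))
  n_ch <- nrow(x$data)
  ev <- x$events
  out <- array(0, c(nrow(ev), n_ch, n_samp))
  for (k in seq_len(nrow(ev))) {
    i0 <- ev$sample[k] + offset
    i1 <- i0 + n_samp - 1L
    if (i0 < 1L || i1 > ncol(x$data))
      stop("epoch window for trial ", k, " (samples ", i0, "..", i1,
           ") exceeds the recording bounds")
    out[k, , ] <- x$data[, i0:i1]
  }
  epoch_set(out, fs = x$fs, t0 = window[1], channel_names = x$channel_names,
            labels = ev$label, condition = ev$condition,
            eog_channels = x$eog_channels, segment_windows = segment_windows,
            participant_id = x$participant_id)
}

#' Reject trials on an amplitude criterion
#'
#' A trial is kept when the maximum absolute potential over all non-EOG
#' channels is at most `amp_threshold` (inclusive). Optionally, trials whose
#' per-channel variance is an outlier across trials can also be dropped.
#'
#' @param e an [epoch_set()].
#' @param amp_threshold peak-to-zero amplitude bound in microvolts.
#' @param var_z optional z-score bound on log per-channel trial variance
#'   (default `NULL`, off).
#' @return list with `epochs` (the retained trials) and `rejected`
#'   (integer indices of dropped trials, possibly empty).
#' @export
reject_trials <- function(e, amp_threshold = 100, var_z = NULL) {
  stopifnot(inherits(e, "epoch_set"))
  if (!is.numeric(amp_threshold) || amp_threshold <= 0)
    stop("`amp_threshold` must be positive")
  eeg <- .eeg_channel_idx(e)
  n_trials <- dim(e$data)[1]
  peak <- vapply(seq_len(n_trials),
                 function(i) max(abs(e$data[i, eeg, , drop = FALSE])), 0)
  bad <- peak > amp_threshold
  if (!is.null(var_z) && n_trials >= 3L) {
    lv <- log(vapply(seq_len(n_trials), function(i) {
      mean(apply(e$data[i, eeg, , drop = FALSE][1, , ], 1L, stats::var))
    }, 0))
    z <- (lv - mean(lv)) / stats::sd(lv)
    bad <- bad | (abs(z) > var_z)
  }
  if (all(bad))
    stop("all ", n_trials, " trials rejected at threshold ",
         amp_threshold, " microvolts")
  keep <- which(!bad)
  e$data <- e$data[keep, , , drop = FALSE]
  e$labels <- e$labels[keep]
  e$condition <- e$condition[keep]
  e$meta$rejected_trials <- which(bad)
  list(epochs = e, rejected = which(bad))
}

#' Remove ocular contamination by least-squares EOG regression
#'
#' Fits, on the trial-concatenated data, the least-squares projection of
#' every EEG channel onto the EOG channels (plus an intercept) and subtracts
#' it. Residual EEG channels have zero sample covariance with every EOG
#' channel. Deterministic stand-in for component-based ocular cleaning; the
#' EOG channels themselves are left untouched so later stages can drop them.
#'
#' @param e an [epoch_set()] that still contains its EOG channels.
#' @return the cleaned `epoch_set`; a no-op (with a warning) when no EOG
#'   channels are present.
#' @export
regress_out_eog <- function(e) {
  stopifnot(inherits(e, "epoch_set"))
  eog <- which(e$channel_names %in% e$eog_channels)
  if (!length(eog)) {
    warning("no EOG channels present; returning data unchanged")
    return(e)
  }
  eeg <- .eeg_channel_idx(e)
  d <- dim(e$data)
  # channels x (trials * samples), trial-concatenated
  flat <- matrix(aperm(e$data, c(2, 3, 1)), nrow = d[2])
  E <- cbind(1, t(flat[eog, , drop = FALSE]))
  coef <- qr.solve(E, t(flat[eeg, , drop = FALSE]))
  cleaned <- t(flat[eeg, , drop = FALSE]) - E %*% coef
  flat[eeg, ] <- t(cleaned)
  e$data <- aperm(array(flat, c(d[2], d[3], d[1])), c(3, 1, 2))
  dimnames(e$data) <- list(NULL, e$channel_names, NULL)
  e$meta$eog_regression <- list(coefficients = coef)
  e
}

#' Select (and reorder) channels
#'
#' @param e an [epoch_set()].
#' @param keep character vector of channel names; output channel order
#'   follows `keep`.
#' @return the sliced `epoch_set`.
#' @export
select_channels <- function(e, keep) {
  stopifnot(inherits(e, "epoch_set"))
  keep <- as.character(keep)
  unknown <- setdiff(keep, e$channel_names)
  if (length(unknown))
    stop("unknown channel name(s): ", paste(unknown, collapse = ", "))
  idx <- match(keep, e$channel_names)
  e$data <- e$data[, idx, , drop = FALSE]
  e$channel_names <- keep
  e$eog_channels <- intersect(e$eog_channels, keep)
  dimnames(e$data) <- list(NULL, keep, NULL)
  e
}

#' Preprocessing configuration
#'
#' Defaults of the amplitude-feature chain: resample to 200 Hz, 1-40 Hz
#' 4th-order zero-phase Butterworth, epoch -5.5..2 s around MI onset,
#' reject trials above 100 microvolts, EOG regression, 0.2-5 Hz zero-phase
#' band for amplitude features, downsample to the 20 Hz feature rate, keep
#' the 31 motor-area channels.
#'
#' @param filter_low,filter_high,filter_order broadband filter (Hz / order).
#' @param fs_intermediate intermediate rate (Hz).
#' @param fs_feature feature rate (Hz).
#' @param band_feature length-2 numeric, amplitude-feature band (Hz).
#' @param epoch_window length-2 numeric, seconds relative to MI onset.
#' @param epoch_pad margin in seconds epoched on each side of
#'   `epoch_window` so that filter edge transients fall outside the
#'   retained span; the margin is cropped again after the last filtering
#'   stage. Set to 0 when the recording has no room around the first or
#'   last trial.
#' @param amp_threshold rejection bound in microvolts.
#' @param channels_keep channels retained at the end (`NULL` = the motor
#'   montage intersected with available channels).
#' @param segment_windows paradigm segments; see [default_segment_windows()].
#' @return named list of class `preprocess_config`.
#' @export
preprocess_config <- function(filter_low = 1, filter_high = 40,
                              filter_order = 4, fs_intermediate = 200,
                              fs_feature = 20, band_feature = c(0.2, 5),
                              epoch_window = c(-5.5, 2), epoch_pad = 1,
                              amp_threshold = 100, channels_keep = NULL,
                              segment_windows = default_segment_windows()) {
  structure(list(filter_low = filter_low, filter_high = filter_high,
                 filter_order = filter_order,
                 fs_intermediate = fs_intermediate, fs_feature = fs_feature,
                 band_feature = band_feature, epoch_window = epoch_window,
                 epoch_pad = epoch_pad,
                 amp_threshold = amp_threshold, channels_keep = channels_keep,
                 segment_windows = segment_windows),
            class = "preprocess_config")
}

#' Full amplitude-feature preprocessing chain
#'
#' Runs the standard chain on a continuous recording: downsample to the
#' intermediate rate, broadband zero-phase filter, epoch around the event
#' markers, amplitude-threshold trial rejection, EOG regression, band-limit
#' to the low-frequency amplitude band, downsample to the feature rate and
#' select the motor channels (EOG channels are dropped at this point).
#'
#' @param x a [continuous_eeg()] with events.
#' @param config a [preprocess_config()].
#' @return an [epoch_set()] of amplitude features at the feature rate.
#' @export
preprocess_epochs <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "continuous_eeg"))
  cfg <- config
  y <- eeg_resample(x, cfg$fs_intermediate)
  y <- eeg_bandpass(y, cfg$filter_low, cfg$filter_high, cfg$filter_order)
  pad <- max(0, cfg$epoch_pad)
  e <- epoch_trials(y, cfg$epoch_window + c(-pad, pad), cfg$segment_windows)
  e <- reject_trials(e, cfg$amp_threshold)$epochs
  e <- regress_out_eog(e)
  e <- eeg_bandpass(e, cfg$band_feature[1], cfg$band_feature[2],
                    cfg$filter_order)
  e <- eeg_resample(e, cfg$fs_feature)
  if (pad > 0) {
    tv <- epoch_times(e)
    keep_t <- which(tv >= cfg$epoch_window[1] - 1e-9 &
                      tv <= cfg$epoch_window[2] - 1e-9)
    e$data <- e$data[, , keep_t, drop = FALSE]
    e$t0 <- tv[keep_t[1]]
  }
  keep <- cfg$channels_keep
  if (is.null(keep))
    keep <- intersect(motor_montage(), e$channel_names)
  if (!length(keep))
    keep <- setdiff(e$channel_names, e$eog_channels)
  e <- select_channels(e, keep)
  e$meta$preprocess <- unclass(cfg)
  e
}
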