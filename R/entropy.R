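#' Normalize a nonnegative array to a discrete probability distribution
#'
#' Takes absolute values (quadratic representations may be negative because
#' of cross-term oscillation) and divides by the total so cells sum to one,
#' making entropy in bits well defined.
#'
#' @param p numeric matrix or array.
#' @return array of the same shape summing to 1.
#' @export
normalize_window <- function(p) {
  p <- abs(p)
  s <- sum(p)
  if (!is.finite(s) || s <= 0)
    stop("cannot normalize: window has no positive mass")
  p / s
}

.check_prob <- function(p) {
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6)
    stop("input is not normalized (sum = ", format(sum(p)), "); ",
         "apply normalize_window() first")
}

#' Renyi entropy (bits)
#'
#' `(1 / (1 - alpha)) * log2(sum(p^alpha))` of a normalized distribution.
#' Order `alpha = 3` is the conventional choice for time-frequency
#' distributions, where odd integer orders damp the oscillating cross-terms.
#'
#' @param p normalized nonnegative array (cells sum to 1).
#' @param alpha entropy order, `alpha > 0`, `alpha != 1`.
#' @return entropy in bits (scalar, `>= 0`).
#' @export
renyi_entropy <- function(p, alpha = 3) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("`alpha` must be a positive scalar")
  if (alpha == 1)
    stop("alpha = 1 is the Shannon limit; use shannon_entropy()")
  .check_prob(p)
  (1 / (1 - alpha)) * log2(sum(p^alpha))
}

#' Shannon entropy (bits)
#'
#' `-sum(p * log2(p))` with `0 * log2(0) = 0`, of a normalized distribution.
#'
#' @param p normalized nonnegative array (cells sum to 1).
#' @return entropy in bits, between 0 and `log2(length(p))`.
#' @export
shannon_entropy <- function(p) {
  .check_prob(p)
  pos <- p[p > 0]
  -sum(pos * log2(pos))
}

# Column-sum statistics of |values| needed for windowed entropies.
# A: time x freq nonnegative matrix. Returns per-time-row sums of a,
# a^alpha and a*log2(a).
.entropy_row_stats <- function(A, alpha) {
  s1 <- rowSums(A)
  sa <- rowSums(A^alpha)
  Al <- A
  pos <- A > 0
  Al[pos] <- A[pos] * log2(A[pos])
  Al[!pos] <- 0
  list(s1 = s1, sa = sa, sl = rowSums(Al))
}

# windowed sums of a per-time statistic: W[c] = sum(s[(c-half)..(c+half)])
.window_sums <- function(s, centers, half) {
  cs <- c(0, cumsum(s))
  cs[centers + half + 1L] - cs[centers - half]
}

#' Short-term entropy of a time-frequency representation
#'
#' Slides a centered window of `window_len` seconds along the time axis of
#' a TFR in steps of `step` seconds; at each center, the absolute TFR
#' restricted to the window (all frequencies) is normalized to unit sum and
#' its Renyi or Shannon entropy is computed. Only centers where the full
#' window fits inside the epoch produce values; an all-zero window yields
#' the maximum `log2(cells)` (with a warning), so degenerate segments do
#' not abort batch runs.
#'
#' @param tfr a `tfr_matrix` (or a plain time x frequency matrix plus
#'   `times`).
#' @param window_len window width in seconds (1 s or 0.5 s in the standard
#'   analysis).
#' @param step slide step in seconds (default 0.05 s).
#' @param kind `"renyi"` or `"shannon"`.
#' @param alpha Renyi order (default 3; ignored for Shannon).
#' @param times time axis when `tfr` is a plain matrix.
#' @return list of class `entropy_series` with `values` (bits), `times`
#'   (window centers, s), `params`, `method`.
#' @export
short_term_entropy <- function(tfr, window_len = 0.5, step = 0.05,
                               kind = c("shannon", "renyi"), alpha = 3,
                               times = NULL) {
  kind <- match.arg(kind)
  if (inherits(tfr, "tfr_matrix")) {
    A <- abs(tfr$values); times <- tfr$times; method <- tfr$method
  } else {
    A <- abs(as.matrix(tfr)); method <- "matrix"
    if (is.null(times)) stop("`times` required for plain matrix input")
  }
  nt <- nrow(A)
  if (nt < 2L) stop("need at least two time bins")
  dt <- times[2] - times[1]
  if (window_len <= step || step <= 0)
    stop("need window_len > step > 0")
  half <- floor(window_len / 2 / dt + 1e-9)
  if (2L * half + 1L > nt)
    stop("entropy window (", window_len, " s) longer than the epoch")
  step_n <- max(1L, as.integer(round(step / dt)))
  centers <- seq.int(half + 1L, nt - half, by = step_n)
  n_cells <- (2L * half + 1L) * ncol(A)
  st <- .entropy_row_stats(A, alpha)
  W1 <- .window_sums(st$s1, centers, half)
  vals <- numeric(length(centers))
  zero <- W1 <= 0
  if (any(zero))
    warning(sum(zero), " all-zero window(s); reporting maximum entropy")
  if (kind == "renyi") {
    Wa <- .window_sums(st$sa, centers, half)
    vals[!zero] <- (1 / (1 - alpha)) *
      (log2(Wa[!zero]) - alpha * log2(W1[!zero]))
  } else {
    Wl <- .window_sums(st$sl, centers, half)
    vals[!zero] <- log2(W1[!zero]) - Wl[!zero] / W1[!zero]
  }
  vals[zero] <- log2(n_cells)
  structure(list(values = vals, times = times[centers],
                 params = list(kind = kind, alpha = alpha,
                               window_len = window_len, step = step,
                               n_cells = n_cells),
                 method = method),
            class = "entropy_series")
}

#' @export
print.entropy_series <- function(x, ...) {
  cat(sprintf("<entropy_series> %s entropy of %s: %d centers, %.3f..%.3f s\n",
              x$params$kind, x$method, length(x$values),
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
plot.entropy_series <- function(x, ...) {
  plot(x$times, x$values, type = "l", xlab = "time (s)",
       ylab = "entropy (bits)",
       main = paste(x$params$kind, "entropy,", x$method), ...)
  invisible(x)
}

#' Feature tensor
#'
#' trials x channels x time-points feature array (amplitude or entropy)
#' with the per-trial labels needed by the classifier.
#'
#' @param values numeric array trials x channels x time-points.
#' @param times time axis (s, relative to MI onset).
#' @param labels,condition per-trial labels.
#' @param feature_kind `"amplitude"`, `"renyi"` or `"shannon"`.
#' @param tfr_method source TFR tag or `NA` for amplitude features.
#' @param segment_windows paradigm segments carried from the epochs.
#' @param participant_id optional identifier.
#' @param params feature parameters (window length etc.).
#' @return object of class `feature_tensor`.
#' @export
feature_tensor <- function(values, times, labels, condition,
                           feature_kind, tfr_method = NA_character_,
                           segment_windows = default_segment_windows(),
                           participant_id = NA_character_, params = list()) {
  stopifnot(length(dim(values)) == 3L,
            dim(values)[3] == length(times),
            dim(values)[1] == length(labels))
  if (length(condition) == 1L) condition <- rep(condition, length(labels))
  structure(list(values = values, times = times,
                 labels = as.character(labels),
                 condition = as.character(condition),
                 feature_kind = feature_kind, tfr_method = tfr_method,
                 segment_windows = segment_windows,
                 participant_id = participant_id, params = params),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_tensor> %s%s: %d trials x %d channels x %d times\n",
              x$feature_kind,
              if (!is.na(x$tfr_method)) paste0(" (", x$tfr_method, ")") else "",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Amplitude features from preprocessed epochs
#'
#' Wraps the band-limited, downsampled epoch amplitudes directly as the
#' classifier's feature tensor.
#'
#' @param epochs an [epoch_set()] at the feature rate.
#' @return a [feature_tensor()] with `feature_kind = "amplitude"`.
#' @export
amplitude_features <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  feature_tensor(epochs$data, epoch_times(epochs), epochs$labels,
                 epochs$condition, "amplitude",
                 segment_windows = epochs$segment_windows,
                 participant_id = epochs$participant_id)
}

#' Short-term entropy features from preprocessed epochs
#'
#' For every trial and channel, computes the requested time-frequency
#' representation of the amplitude-feature signal and its short-term
#' entropy series; stacks the results into a feature tensor.
#'
#' @param epochs an [epoch_set()] at the feature rate (20 Hz in the
#'   standard chain).
#' @param method TFR tag, one of [tfr_methods()].
#' @param kind `"shannon"` or `"renyi"`.
#' @param window_len entropy window in seconds.
#' @param step slide step in seconds.
#' @param alpha Renyi order.
#' @param n_freq TFR frequency bins.
#' @return a [feature_tensor()].
#' @export
entropy_features <- function(epochs, method = "tfrrpwv",
                             kind = c("shannon", "renyi"),
                             window_len = 0.5, step = 0.05, alpha = 3,
                             n_freq = 64) {
  kind <- match.arg(kind)
  grid <- entropy_feature_grid(epochs, methods = method, kinds = kind,
                               window_lens = window_len, step = step,
                               alpha = alpha, n_freq = n_freq)
  grid[[1]]
}

#' Entropy features for a grid of TFR methods, kinds and window lengths
#'
#' Computes each trial/channel TFR once and derives every requested
#' (entropy kind x window length) series from it, which is the economical
#' way to populate the full feature comparison.
#'
#' @inheritParams entropy_features
#' @param methods character vector of TFR tags.
#' @param kinds character vector from `"shannon"`, `"renyi"`.
#' @param window_lens numeric vector of window lengths (s).
#' @return named list of [feature_tensor()]s, names
#'   `"<method>_<kind>_w<window>"`.
#' @export
entropy_feature_grid <- function(epochs, methods = "tfrrpwv",
                                 kinds = "shannon", window_lens = 0.5,
                                 step = 0.05, alpha = 3, n_freq = 64) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  times <- epoch_times(epochs)
  combos <- expand.grid(kind = kinds, wl = window_lens,
                        method = methods, stringsAsFactors = FALSE)
  out <- vector("list", nrow(combos))
  names(out) <- sprintf("%s_%s_w%g", combos$method, combos$kind, combos$wl)
  arrs <- vector("list", nrow(combos))
  ctimes <- vector("list", nrow(combos))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      x <- epochs$data[i, j, ]
      for (m in unique(combos$method)) {
        tf <- tfr_compute(x, fs = epochs$fs, method = m, n_freq = n_freq,
                          t0 = epochs$t0)
        for (ci in which(combos$method == m)) {
          es <- short_term_entropy(tf, window_len = combos$wl[ci],
                                   step = step, kind = combos$kind[ci],
                                   alpha = alpha)
          if (is.null(arrs[[ci]])) {
            arrs[[ci]] <- array(NA_real_, c(d[1], d[2], length(es$values)))
            ctimes[[ci]] <- es$times
          }
          arrs[[ci]][i, j, ] <- es$values
        }
      }
    }
  }
  for (ci in seq_len(nrow(combos))) {
    out[[ci]] <- feature_tensor(
      arrs[[ci]], ctimes[[ci]], epochs$labels, epochs$condition,
      combos$kind[ci], combos$method[ci],
      segment_windows = epochs$segment_windows,
      participant_id = epochs$participant_id,
      params = list(window_len = combos$wl[ci], step = step, alpha = alpha,
                    n_freq = n_freq))
  }
  out
}

#' Export a feature tensor as a long data frame
#'
#' @param x a [feature_tensor()].
#' @param channel_names optional channel names (defaults to indices).
#' @return `data.frame` with columns trial, channel, time, value, label,
#'   condition.
#' @export
features_to_df <- function(x, channel_names = NULL) {
  stopifnot(inherits(x, "feature_tensor"))
  d <- dim(x$values)
  if (is.null(channel_names)) channel_names <- as.character(seq_len(d[2]))
  data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(channel_names, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    value = as.vector(x$values),
    label = rep(x$labels, times = d[2] * d[3]),
    condition = rep(x$condition, times = d[2] * d[3]),
    stringsAsFactors = FALSE)
}
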