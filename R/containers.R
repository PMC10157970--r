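#' Continuous multichannel EEG recording
#'
#' Light-weight container for a continuous recording: a channels x samples
#' matrix of potentials in microvolts, its sampling rate, ordered channel
#' names (10/20 convention), the subset of channels carrying the
#' electrooculogram (EOG), and an event table marking trial onsets.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz, positive scalar.
#' @param channel_names character vector, one name per row of `data`.
#' @param eog_channels character vector of names in `channel_names` flagged
#'   as EOG; they are excluded from artifact-threshold checks and used as
#'   regressors for ocular-artifact removal.
#' @param events `data.frame` with columns `sample` (1-based index of the
#'   movement-imagery onset), `label` (trial class, e.g. `"right"`/`"up"`),
#'   and `condition` (e.g. `"VtG"`/`"noVtG"`, or `"none"`). May be `NULL`
#'   for recordings without markers.
#' @param participant_id optional identifier carried through the pipeline.
#'
#' @return An object of class `continuous_eeg`.
#' @export
continuous_eeg <- function(data, fs, channel_names,
                           eog_channels = character(),
                           events = NULL, participant_id = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nrow(data))
    stop("`channel_names` must have one entry per data row (channel)")
  if (anyDuplicated(channel_names))
    stop("duplicated channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  eog_channels <- as.character(eog_channels)
  missing_eog <- setdiff(eog_channels, channel_names)
  if (length(missing_eog))
    stop("EOG channels not present in `channel_names`: ",
         paste(missing_eog, collapse = ", "))
  if (!is.null(events)) {
    events <- as.data.frame(events)
    need <- c("sample", "label", "condition")
    miss <- setdiff(need, names(events))
    if (length(miss))
      stop("`events` must have columns: ", paste(need, collapse = ", "))
    if (any(events$sample < 1 | events$sample > ncol(data)))
      stop("event sample indices outside the recording")
  }
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 eog_channels = eog_channels, events = events,
                 participant_id = participant_id),
            class = "continuous_eeg")
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("<continuous_eeg> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (length(x$eog_channels))
    cat("  EOG:", paste(x$eog_channels, collapse = ", "), "\n")
  if (!is.null(x$events))
    cat(sprintf("  %d events (%s)\n", nrow(x$events),
                paste(unique(x$events$label), collapse = "/")))
  invisible(x)
}

#' Default segment windows of the trial paradigm
#'
#' Named intervals, in seconds relative to the motor-imagery onset (t = 0):
#' baseline rest (-3.5 to -2 s, the latter part of the fixation-cross
#' display), pre-MI cue period (-2 to 0 s) and the motor-imagery period
#' (0 to 1.5 s).
#'
#' @return Named list of length-2 numeric vectors.
#' @export
default_segment_windows <- function() {
  list(baseline = c(-3.5, -2), pre_mi = c(-2, 0), mi = c(0, 1.5))
}

#' Labeled epoched EEG
#'
#' Container for epoched data: trials x channels x samples array at a common
#' sampling rate, with the epoch timeline expressed relative to the
#' motor-imagery onset (t = 0) and per-trial class / condition labels.
#'
#' @param data numeric array, trials x channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample in seconds relative to MI onset
#'   (negative for pre-onset data).
#' @param channel_names character, one per channel.
#' @param labels per-trial class labels.
#' @param condition per-trial condition labels (recycled if length 1).
#' @param eog_channels names of EOG channels still present in `data`.
#' @param segment_windows named list of `baseline`, `pre_mi`, `mi` intervals
#'   in seconds relative to MI onset; see [default_segment_windows()].
#' @param participant_id optional identifier.
#' @param meta free-form list of provenance notes accumulated by the
#'   preprocessing steps.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, t0, channel_names, labels,
                      condition = "none", eog_channels = character(),
                      segment_windows = default_segment_windows(),
                      participant_id = NA_character_, meta = list()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array: trials x channels x samples")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive")
  n_trials <- dim(data)[1]
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(data)[2])
    stop("`channel_names` length must equal the channel dimension")
  labels <- as.character(labels)
  if (length(labels) != n_trials)
    stop("`labels` must have one entry per trial")
  condition <- as.character(condition)
  if (length(condition) == 1L) condition <- rep(condition, n_trials)
  if (length(condition) != n_trials)
    stop("`condition` must have one entry per trial")
  if (length(setdiff(eog_channels, channel_names)))
    stop("`eog_channels` must be a subset of `channel_names`")
  t_end <- t0 + dim(data)[3] / fs
  for (nm in names(segment_windows)) {
    w <- segment_windows[[nm]]
    if (length(w) != 2L || w[1] >= w[2])
      stop("segment window `", nm, "` must be an increasing length-2 interval")
    if (w[1] < t0 - 1e-9 || w[2] > t_end + 1e-9)
      stop("segment window `", nm, "` lies outside the epoch [",
           signif(t0, 4), ", ", signif(t_end, 4), "] s")
  }
  dimnames(data) <- list(NULL, channel_names, NULL)
  structure(list(data = data, fs = fs, t0 = t0,
                 channel_names = channel_names, labels = labels,
                 condition = condition, eog_channels = eog_channels,
                 segment_windows = segment_windows,
                 participant_id = participant_id, meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  timeline: %.2f .. %.2f s (t = 0 at MI onset)\n",
              x$t0, x$t0 + d[3] / x$fs))
  cat("  classes:", paste(sprintf("%s (%d)", names(table(x$labels)),
                                  table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Time vector of an epoch set
#' @param e an `epoch_set`.
#' @return numeric vector of sample times in seconds relative to MI onset.
#' @export
epoch_times <- function(e) {
  stopifnot(inherits(e, "epoch_set"))
  e$t0 + (seq_len(dim(e$data)[3]) - 1L) / e$fs
}

# Indices of non-EOG channels
.eeg_channel_idx <- function(x) {
  which(!(x$channel_names %in% x$eog_channels))
}

#' Save / load pipeline containers
#'
#' Epoch sets, feature tensors and decoding results are persisted as single
#' RDS files (R's native serialization); these helpers exist so scripts and
#' the command-line tool share one canonical container format.
#'
#' @param x object to save.
#' @param path file path (conventionally `.rds`).
#' @return `read_container` returns the deserialized object.
#' @export
write_container <- function(x, path) {
  saveRDS(x, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  readRDS(path)
}
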