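.trim <- function(x) sub("\\s+$", "", sub("^\\s+", "", x))

.read_ascii <- function(con, n) .trim(rawToChar(readBin(con, "raw", n)))

#' Read an EDF recording
#'
#' Parses the 256-byte EDF header, the per-signal headers and the int16
#' data records, applying each signal's physical scaling. All retained
#' signals must share one sampling rate; an `"EDF Annotations"` signal
#' (EDF+) is dropped.
#'
#' @param path path to the `.edf` file.
#' @param eog_channels channel names to flag as EOG.
#' @param events optional event table to attach (EDF itself carries no
#'   trial markers in the base format).
#' @return a [continuous_eeg()]; physical units are taken as recorded
#'   (conventionally microvolts for EEG).
#' @export
read_edf <- function(path, eog_channels = character(), events = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .read_ascii(con, 8)
  if (!startsWith(version, "0"))
    stop("not an EDF file (version field: ", version, ")")
  invisible(readBin(con, "raw", 80 + 80 + 8 + 8))  # patient/recording/date
  header_bytes <- as.integer(.read_ascii(con, 8))
  invisible(readBin(con, "raw", 44))
  n_records <- as.integer(.read_ascii(con, 8))
  rec_dur <- as.numeric(.read_ascii(con, 8))
  ns <- as.integer(.read_ascii(con, 4))
  if (is.na(ns) || ns < 1) stop("corrupt EDF header: no signals")
  rd_field <- function(width) {
    vapply(seq_len(ns), function(i) .read_ascii(con, width), "")
  }
  labels <- rd_field(16)
  invisible(readBin(con, "raw", 80L * ns))  # transducer
  invisible(readBin(con, "raw", 8L * ns))   # physical dimension
  phys_min <- as.numeric(rd_field(8))
  phys_max <- as.numeric(rd_field(8))
  dig_min <- as.numeric(rd_field(8))
  dig_max <- as.numeric(rd_field(8))
  invisible(readBin(con, "raw", 80L * ns))  # prefiltering
  spr <- as.integer(rd_field(8))
  invisible(readBin(con, "raw", 32L * ns))  # reserved
  seek(con, header_bytes)
  keep <- labels != "EDF Annotations"
  if (length(unique(spr[keep])) != 1L)
    stop("signals with differing sampling rates are not supported")
  total <- sum(spr)
  raw <- readBin(con, "integer", n = total * n_records, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < total * n_records)
    stop("EDF data section truncated")
  data <- matrix(0, sum(keep), spr[keep][1] * n_records)
  offs <- c(0, cumsum(spr))
  row <- 0L
  for (i in seq_len(ns)) {
    if (!keep[i]) next
    row <- row + 1L
    sel <- as.vector(outer(seq_len(spr[i]) + offs[i],
                           (seq_len(n_records) - 1L) * total, `+`))
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    data[row, ] <- (raw[sel] - dig_min[i]) * scale + phys_min[i]
  }
  fs <- spr[keep][1] / rec_dur
  continuous_eeg(data, fs = fs, channel_names = labels[keep],
                 eog_channels = intersect(eog_channels, labels[keep]),
                 events = events)
}

# parse a BrainVision ini-style file into section -> named character vector
.bv_ini <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(;|$)", lines)]
  out <- list(); sec <- "global"
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      sec <- .trim(gsub("\\[|\\]", "", ln))
      out[[sec]] <- character()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[sec]][.trim(kv[1])] <- .trim(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording (vhdr/vmrk/data triplet)
#'
#' Supports binary IEEE float-32 / int-16 and ASCII data files in
#' multiplexed or vectorized orientation, applies per-channel resolution
#' scaling, and converts `.vmrk` stimulus markers into the event table.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @param eog_channels channel names to flag as EOG.
#' @param marker_map optional named character vector mapping marker
#'   descriptions to trial-class labels; unmapped stimulus markers keep
#'   their description as label. Condition is `"none"` unless the mapped
#'   label contains `"label/condition"`.
#' @return a [continuous_eeg()].
#' @export
read_brainvision <- function(vhdr, eog_channels = character(),
                             marker_map = NULL) {
  hdr <- .bv_ini(vhdr)
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: ", vhdr)
  n_ch <- as.integer(ci["NumberOfChannels"])
  fs <- 1e6 / as.numeric(ci["SamplingInterval"])
  dir <- dirname(vhdr)
  chan <- hdr[["Channel Infos"]]
  parts <- strsplit(unname(chan), ",")
  ch_names <- vapply(parts, `[`, "", 1L)
  resolution <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, 0)
  data_file <- file.path(dir, ci["DataFile"])
  fmt <- toupper(ci["DataFormat"])
  orient <- toupper(ci["DataOrientation"])
  if (fmt == "BINARY") {
    bfmt <- toupper(hdr[["Binary Infos"]]["BinaryFormat"])
    sz <- file.info(data_file)$size
    if (bfmt == "IEEE_FLOAT_32") {
      vals <- readBin(data_file, "numeric", n = sz / 4, size = 4,
                      endian = "little")
    } else if (bfmt == "INT_16") {
      vals <- readBin(data_file, "integer", n = sz / 2, size = 2,
                      signed = TRUE, endian = "little")
    } else stop("unsupported BinaryFormat: ", bfmt)
  } else if (fmt == "ASCII") {
    vals <- as.numeric(t(as.matrix(utils::read.table(data_file))))
    if (orient == "VECTORIZED")
      vals <- as.numeric(as.matrix(utils::read.table(data_file)))
  } else stop("unsupported DataFormat: ", fmt)
  n_samp <- length(vals) %/% n_ch
  vals <- vals[seq_len(n_samp * n_ch)]
  data <- if (orient == "MULTIPLEXED") {
    matrix(vals, nrow = n_ch)           # channels fastest
  } else {
    t(matrix(vals, nrow = n_samp))      # one channel after another
  }
  data <- data * resolution
  events <- NULL
  mf <- ci["MarkerFile"]
  if (!is.na(mf) && nzchar(mf) && file.exists(file.path(dir, mf))) {
    mk <- .bv_ini(file.path(dir, mf))[["Marker Infos"]]
    if (length(mk)) {
      mp <- strsplit(unname(mk), ",")
      type <- vapply(mp, `[`, "", 1L)
      desc <- vapply(mp, `[`, "", 2L)
      posn <- as.integer(vapply(mp, `[`, "", 3L))
      stim <- type == "Stimulus"
      if (any(stim)) {
        lab <- desc[stim]
        if (!is.null(marker_map)) {
          mapped <- marker_map[lab]
          lab <- ifelse(is.na(mapped), lab, mapped)
        }
        cnd <- ifelse(grepl("/", lab), sub("^[^/]*/", "", lab), "none")
        lab <- sub("/.*$", "", lab)
        events <- data.frame(sample = posn[stim], label = lab,
                             condition = cnd, stringsAsFactors = FALSE)
      }
    }
  }
  continuous_eeg(data, fs = fs, channel_names = ch_names,
                 eog_channels = intersect(eog_channels, ch_names),
                 events = events)
}
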