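# Independent writers for the container formats, transcribed from the
# format documents (not from the package readers), used for roundtrips.

write_edf_fixture <- function(path, data, fs, labels,
                              phys_range = c(-200, 200)) {
  n_ch <- nrow(data); n_samp <- ncol(data)
  rec_dur <- 1
  spr <- as.integer(fs * rec_dur)
  n_rec <- n_samp %/% spr
  stopifnot(n_rec * spr == n_samp)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * n_ch
  writeChar(paste0(pad("0", 8), pad("patient X", 80), pad("recording", 80),
                   pad("01.01.26", 8), pad("00.00.00", 8),
                   pad(hdr_bytes, 8), pad("", 44), pad(n_rec, 8),
                   pad(rec_dur, 8), pad(n_ch, 4)),
            con, eos = NULL)
  field <- function(vals, w)
    writeChar(paste(vapply(vals, pad, "", w = w), collapse = ""),
              con, eos = NULL)
  dig_min <- -32768; dig_max <- 32767
  field(labels, 16)
  field(rep("AgAgCl electrode", n_ch), 80)
  field(rep("uV", n_ch), 8)
  field(rep(phys_range[1], n_ch), 8)
  field(rep(phys_range[2], n_ch), 8)
  field(rep(dig_min, n_ch), 8)
  field(rep(dig_max, n_ch), 8)
  field(rep("none", n_ch), 80)
  field(rep(spr, n_ch), 8)
  field(rep("", n_ch), 32)
  scale <- (phys_range[2] - phys_range[1]) / (dig_max - dig_min)
  dig <- round((data - phys_range[1]) / scale + dig_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_len(n_ch))
      writeBin(as.integer(dig[i, cols]), con, size = 2, endian = "little")
  }
  invisible(path)
}

write_brainvision_fixture <- function(stem, data, fs, labels, markers = NULL,
                                      format = c("binary", "ascii")) {
  format <- match.arg(format)
  vhdr <- paste0(stem, ".vhdr"); vmrk <- paste0(stem, ".vmrk")
  dfile <- paste0(stem, if (format == "binary") ".eeg" else ".dat")
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", basename(dfile)),
           paste0("MarkerFile=", basename(vmrk)),
           paste0("DataFormat=", toupper(format)),
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nrow(data)),
           paste0("SamplingInterval=", format(1e6 / fs, scientific = FALSE)),
           if (format == "binary") c("[Binary Infos]",
                                     "BinaryFormat=IEEE_FLOAT_32"),
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,uV", seq_len(nrow(data)), labels))
  writeLines(hdr, vhdr)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (!is.null(markers))
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                        seq_len(nrow(markers)) + 1L,
                        markers$desc, markers$sample))
  writeLines(mk, vmrk)
  if (format == "binary") {
    con <- file(dfile, "wb")
    writeBin(as.numeric(data), con, size = 4, endian = "little")
    close(con)
  } else {
    utils::write.table(t(data), dfile, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(vhdr)
}

# small feature tensor with an optional class effect in the MI window
make_feature_fixture <- function(n_per_class = 20, n_ch = 6, effect = 0,
                                 seed = 1, baseline_effect = 0) {
  set.seed(seed)
  times <- seq(-3.5, 1.75, by = 0.05)
  n_t <- length(times)
  n <- 2L * n_per_class
  vals <- array(rnorm(n * n_ch * n_t), c(n, n_ch, n_t))
  labels <- rep(c("right", "up"), each = n_per_class)
  mi <- times >= 0 & times <= 1.5
  vals[labels == "right", , mi] <- vals[labels == "right", , mi] + effect
  if (baseline_effect != 0)
    vals[, , mi] <- vals[, , mi] + baseline_effect
  feature_tensor(vals, times, labels, "none", "amplitude")
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# small fast synthetic configuration for generator-level tests
small_synth_config <- function(...) {
  args <- list(n_participants = 1, n_trials_per_class = 8, fs = 200,
               gap = 1)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}
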