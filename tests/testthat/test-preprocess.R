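test_that("zero-phase band-pass preserves in-band tones and kills out-of-band", {
  fs <- 200
  t <- (0:1999) / fs
  # linearity: zeros in, zeros out
  expect_equal(eeg_bandpass(numeric(400), 1, 40, fs = fs), numeric(400))
  # 20 Hz tone through 1-40 Hz: analytic squared Butterworth magnitude at
  # 20 Hz is 1 to well below 1%, so the filtered amplitude must match
  x <- sin(2 * pi * 20 * t)
  y <- eeg_bandpass(x, 1, 40, fs = fs)
  core <- 400:1600
  expect_lt(abs(stats::sd(y[core]) / stats::sd(x[core]) - 1), 0.01)
  # 80 Hz tone: residual RMS < 1% of input
  x2 <- sin(2 * pi * 80 * t)
  y2 <- eeg_bandpass(x2, 1, 40, fs = fs)
  expect_lt(stats::sd(y2[core]) / stats::sd(x2), 0.01)
})

test_that("band edges and signal length are validated", {
  expect_error(eeg_bandpass(rnorm(100), 0, 40, fs = 200), "invalid band")
  expect_error(eeg_bandpass(rnorm(100), 1, 120, fs = 200), "invalid band")
  expect_error(eeg_bandpass(rnorm(10), 1, 40, fs = 200), "too short")
})

test_that("zero-phase filtering keeps a symmetric pulse symmetric", {
  n <- 2001
  x <- exp(-0.5 * ((seq_len(n) - 1001) / 30)^2)
  y <- eeg_bandpass(x, 1, 40, fs = 200)
  expect_lt(max(abs(y - rev(y))) / max(abs(y)), 1e-8)
})

test_that("resampling preserves DC, duration and in-band content", {
  expect_equal(eeg_resample(rep(3.5, 400), 50, fs = 200), rep(3.5, 100),
               tolerance = 1e-6)
  y <- eeg_resample(numeric(1000) + seq(0, 0, length.out = 1000), 20,
                    fs = 200)
  expect_lte(abs(length(y) - 100), 1)
  # 5 Hz sinusoid, 1 kHz -> 200 Hz, against the closed-form resampled tone
  t1 <- (0:4999) / 1000
  x <- sin(2 * pi * 5 * t1)
  z <- eeg_resample(x, 200, fs = 1000)
  ref <- sin(2 * pi * 5 * (seq_along(z) - 1) / 200)
  core <- 50:(length(z) - 50)
  expect_gt(stats::cor(z[core], ref[core]), 0.999)
  expect_error(eeg_resample(x, -5, fs = 1000), "positive")
})

test_that("epoching indexes trials exactly and preserves labels", {
  fs <- 200
  x <- matrix(seq_len(3000) - 1, nrow = 1)  # ramp: value = 0-based index
  ev <- data.frame(sample = c(1001, 1801, 2401),
                   label = c("right", "up", "right"),
                   condition = c("VtG", "noVtG", "VtG"))
  rec <- continuous_eeg(x, fs, "Cz", events = ev)
  e <- epoch_trials(rec, c(0, 0.1),
                    segment_windows = list(mi = c(0, 0.1)))
  expect_equal(dim(e$data), c(3, 1, 20))
  expect_equal(as.numeric(e$data[1, 1, 1]), 1000)  # ramp value at the event
  expect_equal(e$labels, ev$label)
  expect_equal(e$condition, ev$condition)
  e2 <- epoch_trials(rec, c(-1, 1),
                     segment_windows = list(mi = c(0, 1)))
  expect_equal(dim(e2$data)[3], 400)
  ev_bad <- data.frame(sample = 2950, label = "up", condition = "none")
  rec_bad <- continuous_eeg(x, fs, "Cz", events = ev_bad)
  expect_error(epoch_trials(rec_bad, c(0, 1),
                            segment_windows = list(mi = c(0, 1))),
               "trial 1")
})

test_that("amplitude rejection keeps the threshold inclusive and reports indices", {
  set.seed(7)
  dat <- array(stats::runif(10 * 2 * 50, -50, 50), c(10, 2, 50))
  e <- epoch_set(dat, 20, -1, c("C3", "C4"), labels = rep("right", 10),
                 segment_windows = list(mi = c(0, 1)))
  r <- reject_trials(e, 100)
  expect_length(r$rejected, 0)
  dat2 <- dat
  dat2[4, 1, 10] <- 500
  e2 <- epoch_set(dat2, 20, -1, c("C3", "C4"), labels = rep("right", 10),
                  segment_windows = list(mi = c(0, 1)))
  r2 <- reject_trials(e2, 100)
  expect_equal(r2$rejected, 4L)
  expect_equal(dim(r2$epochs$data)[1], 9)
  # boundary: threshold exactly at the global max rejects nothing
  r3 <- reject_trials(e2, 500)
  expect_length(r3$rejected, 0)
  expect_error(reject_trials(e2, 1e-9), "all 10 trials")
})

test_that("EOG regression removes proportional contamination and decorrelates", {
  set.seed(11)
  n <- 400
  eogs <- matrix(rnorm(2 * n), 2)
  clean <- matrix(rnorm(2 * n), 2)
  dat <- array(0, c(1, 4, n))
  dat[1, 1, ] <- 2 * eogs[1, ]              # pure contamination
  dat[1, 2, ] <- clean[2, ]                 # independent channel
  dat[1, 3, ] <- eogs[1, ]
  dat[1, 4, ] <- eogs[2, ]
  e <- epoch_set(dat, 20, 0, c("Cz", "Pz", "EOG1", "EOG2"),
                 labels = "right", eog_channels = c("EOG1", "EOG2"),
                 segment_windows = list(mi = c(0, 1)))
  out <- regress_out_eog(e)
  expect_lt(sqrt(mean(out$data[1, 1, ]^2)) / sqrt(mean(dat[1, 1, ]^2)),
            1e-10)
  # independent channel essentially unchanged (coefficient noise only)
  expect_gt(stats::cor(out$data[1, 2, ], clean[2, ]), 0.99)
  # least-squares orthogonality of every EEG channel to every EOG channel
  for (i in 1:2) for (j in 3:4)
    expect_lt(abs(stats::cov(out$data[1, i, ], dat[1, j, ])), 1e-8)
  e_no <- epoch_set(dat[, 1:2, , drop = FALSE], 20, 0, c("Cz", "Pz"),
                    labels = "right", segment_windows = list(mi = c(0, 1)))
  expect_warning(regress_out_eog(e_no), "no EOG")
})

test_that("channel selection reorders and validates names", {
  dat <- array(seq_len(2 * 3 * 10), c(2, 3, 10))
  e <- epoch_set(dat, 20, 0, c("C3", "Cz", "C4"), labels = c("a", "b"),
                 segment_windows = list(mi = c(0, 0.4)))
  ident <- select_channels(e, c("C3", "Cz", "C4"))
  expect_equal(ident$data, e$data)
  one <- select_channels(e, "Cz")
  expect_equal(dim(one$data)[2], 1)
  expect_equal(one$data[1, 1, ], e$data[1, 2, ])
  rev2 <- select_channels(e, c("C4", "C3"))
  expect_equal(rev2$channel_names, c("C4", "C3"))
  expect_equal(rev2$data[2, 1, ], e$data[2, 3, ])
  expect_error(select_channels(e, "Oz"), "Oz")
  expect_length(motor_montage(), 31)
})

test_that("the amplitude-feature chain passes in-band and suppresses out-of-band content", {
  fs <- 200
  t <- (0:2999) / fs
  chain <- function(x) {
    y <- eeg_bandpass(x, 1, 40, fs = fs)
    y <- eeg_bandpass(y, 0.2, 5, fs = fs)
    eeg_resample(y, 20, fs = fs)
  }
  # 10 Hz is outside the 0.2-5 Hz amplitude band: near-zero output away
  # from the filter edge transients
  out10 <- chain(sin(2 * pi * 10 * t))
  core <- 30:(length(out10) - 30)
  expect_lt(stats::sd(out10[core]), 0.01)
  # 2 Hz lies inside every band of the chain: amplitude within 5%
  out2 <- chain(sin(2 * pi * 2 * t))
  expect_lt(abs(stats::sd(out2[core]) * sqrt(2) - 1), 0.05)
})

test_that("preprocessing is deterministic", {
  cfg <- small_synth_config(seed = 3)
  rec <- generate_dataset(cfg, participants = 1)$participants[[1]]
  p1 <- preprocess_epochs(rec)
  p2 <- preprocess_epochs(rec)
  expect_identical(p1, p2)
  expect_equal(p1$fs, 20)
  expect_equal(dim(p1$data)[2], 31)       # EOG dropped, motor montage kept
  expect_false(any(p1$channel_names %in% c("EOG1", "EOG2", "EOG3")))
})
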