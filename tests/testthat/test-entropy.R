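test_that("window normalization takes absolute values and sums to one", {
  expect_equal(normalize_window(matrix(2, 2, 2)), matrix(0.25, 2, 2))
  expect_equal(normalize_window(matrix(c(-1, 0, 0, 1), 2)),
               matrix(c(0.5, 0, 0, 0.5), 2))
  set.seed(1)
  for (i in 1:20) {
    p <- normalize_window(matrix(rnorm(30), 5))
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p >= 0))
  }
  expect_error(normalize_window(matrix(0, 3, 3)), "no positive mass")
})

test_that("Renyi and Shannon entropies reproduce hand-checked values", {
  expect_equal(renyi_entropy(matrix(1 / 64, 8, 8), 3), 6, tolerance = 1e-12)
  expect_equal(shannon_entropy(matrix(1 / 64, 8, 8)), 6, tolerance = 1e-12)
  degenerate <- c(1, rep(0, 63))
  expect_equal(renyi_entropy(degenerate, 3), 0)
  expect_equal(shannon_entropy(degenerate), 0)
  # p = (1/2, 1/4, 1/8, 1/8): sum p^3 = 37/256, R3 = -log2(37/256)/2
  p <- matrix(c(0.5, 0.25, 0.125, 0.125), 2)
  expect_equal(renyi_entropy(p, 3), -log2(37 / 256) / 2, tolerance = 1e-12)
  expect_equal(renyi_entropy(p, 3), 1.39527, tolerance = 1e-5)
  expect_equal(shannon_entropy(p), 1.75, tolerance = 1e-12)
})

test_that("entropy input contracts are enforced", {
  expect_error(renyi_entropy(c(0.5, 0.4), 3), "not normalized")
  expect_error(shannon_entropy(c(0.5, 0.6)), "not normalized")
  expect_error(renyi_entropy(c(0.5, 0.5), 1), "shannon_entropy")
  expect_error(renyi_entropy(c(0.5, 0.5), -2), "positive")
})

test_that("fast entropies match literal sums on random matrices", {
  set.seed(2)
  for (i in 1:25) {
    p <- normalize_window(matrix(stats::rexp(64), 8))
    expect_lt(abs(renyi_entropy(p, 3) - oracle_renyi(p, 3)), 1e-12)
    expect_lt(abs(shannon_entropy(p) - oracle_shannon(p)), 1e-12)
  }
})

test_that("entropy properties hold on random distributions", {
  set.seed(3)
  for (i in 1:300) {
    p <- normalize_window(stats::rexp(32))
    # Renyi entropy is nonincreasing in alpha, so Shannon >= Renyi(3)
    expect_gte(shannon_entropy(p) + 1e-12, renyi_entropy(p, 3))
    # permutation invariance
    q <- sample(p)
    expect_equal(shannon_entropy(q), shannon_entropy(p), tolerance = 1e-12)
    expect_equal(renyi_entropy(q, 3), renyi_entropy(p, 3),
                 tolerance = 1e-12)
    # mixing toward uniform does not decrease Shannon entropy
    lam <- stats::runif(1)
    mix <- (1 - lam) * p + lam / length(p)
    expect_gte(shannon_entropy(mix) + 1e-12, shannon_entropy(p))
  }
  # maximum at uniform, any size
  for (n in c(4, 64, 1024)) {
    expect_equal(shannon_entropy(rep(1 / n, n)), log2(n), tolerance = 1e-12)
    expect_equal(renyi_entropy(rep(1 / n, n), 3), log2(n),
                 tolerance = 1e-12)
  }
})

test_that("short-term entropy matches per-window normalization and trims edges", {
  set.seed(4)
  A <- matrix(abs(rnorm(60 * 16)), 60, 16)
  times <- (0:59) / 20
  tf <- structure(list(values = A, times = times, freqs = 0:15,
                       method = "test"), class = "tfr_matrix")
  for (kind in c("shannon", "renyi")) {
    es <- short_term_entropy(tf, 0.5, 0.05, kind)
    half <- 5L
    centers <- (half + 1L):(60L - half)
    expect_equal(es$times, times[centers])
    brute <- vapply(centers, function(cc) {
      w <- normalize_window(A[(cc - half):(cc + half), ])
      if (kind == "shannon") oracle_shannon(w) else oracle_renyi(w, 3)
    }, 0)
    expect_equal(es$values, brute, tolerance = 1e-10)
  }
  # constant TFR: entropy equals log2(window cells) at every center
  tfc <- structure(list(values = matrix(2.5, 60, 16), times = times,
                        freqs = 0:15, method = "c"), class = "tfr_matrix")
  esc <- short_term_entropy(tfc, 0.5, 0.05, "shannon")
  expect_equal(esc$values, rep(log2(11 * 16), length(esc$values)),
               tolerance = 1e-10)
  expect_error(short_term_entropy(tf, 10, 0.05), "longer than the epoch")
})

test_that("a component count increase raises the short-term entropy", {
  fs <- 20
  x <- generate_test_signal("tone_switch", fs, 12, f0 = 2, f1 = 7,
                            t_switch = 6)
  tf <- tfr_compute(x, fs, "tfrsp")
  for (w in c(1, 0.5)) {
    es <- short_term_entropy(tf, w, 0.05, "shannon")
    pre <- es$values[es$times < 6 - w / 2 - 0.5]
    post <- es$values[es$times > 6 + w / 2 + 0.5]
    expect_gt(mean(post), mean(pre))
  }
})

test_that("feature tensors have the right shape, labels and determinism", {
  set.seed(5)
  dat <- array(rnorm(2 * 3 * 80), c(2, 3, 80))
  dat[2, , ] <- dat[1, , ]                      # identical trials
  e <- epoch_set(dat, 20, -2, c("C3", "Cz", "C4"),
                 labels = c("right", "right"),
                 segment_windows = list(baseline = c(-2, -1),
                                        mi = c(0, 1)))
  ft <- entropy_features(e, "tfrsp", "shannon", 0.5)
  expect_s3_class(ft, "feature_tensor")
  expect_equal(dim(ft$values)[1:2], c(2, 3))
  expect_equal(ft$labels, e$labels)
  # identical trials give identical feature rows
  expect_equal(ft$values[1, , ], ft$values[2, , ])
  # grid computation agrees with the single-combination path
  grid <- entropy_feature_grid(e, "tfrsp", c("shannon", "renyi"), 0.5)
  expect_equal(grid$tfrsp_shannon_w0.5$values, ft$values)
  df <- features_to_df(ft, e$channel_names)
  expect_equal(nrow(df), prod(dim(ft$values)))
  expect_true(all(c("trial", "channel", "time", "value", "label") %in%
                    names(df)))
})

test_that("synthetic MI trials separate from baseline in mean entropy", {
  cfg <- small_synth_config(seed = 21)
  rec <- generate_dataset(cfg, participants = 1)$participants[[1]]
  ep <- preprocess_epochs(rec)
  ft <- entropy_features(ep, "tfrrpwv", "shannon", 0.5)
  mi <- ft$times >= ft$segment_windows$mi[1] &
    ft$times <= ft$segment_windows$mi[2]
  bl <- ft$times >= ft$segment_windows$baseline[1] &
    ft$times <= ft$segment_windows$baseline[2]
  mi_m <- apply(ft$values[, , mi], 1, mean)
  bl_m <- apply(ft$values[, , bl], 1, mean)
  pooled_sd <- sqrt((stats::var(mi_m) + stats::var(bl_m)) / 2)
  d <- (mean(mi_m) - mean(bl_m)) / pooled_sd
  expect_gt(abs(d), 0.5)
})
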