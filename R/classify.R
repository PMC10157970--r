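#' Classification task specification
#'
#' Defines a binary decoding task on a feature tensor: either one MI class
#' against another (`"class_vs_class"`, e.g. right vs up) or one MI class
#' against the within-trial baseline segment (`"class_vs_baseline"`),
#' optionally restricted to one experimental condition.
#'
#' @param contrast `"class_vs_class"` or `"class_vs_baseline"`.
#' @param class_a positive class label (e.g. `"right"`).
#' @param class_b negative class label for `"class_vs_class"`.
#' @param condition keep only trials of this condition (`NULL` = all).
#' @param mi_window MI period in seconds relative to onset.
#' @param baseline_window baseline period in seconds relative to onset.
#' @return list of class `task_spec`.
#' @export
task_spec <- function(contrast = c("class_vs_baseline", "class_vs_class"),
                      class_a, class_b = NULL, condition = NULL,
                      mi_window = c(0, 1.5), baseline_window = c(-3.5, -2)) {
  contrast <- match.arg(contrast)
  if (contrast == "class_vs_class" && is.null(class_b))
    stop("`class_b` required for a class-vs-class task")
  structure(list(contrast = contrast, class_a = class_a, class_b = class_b,
                 condition = condition, mi_window = mi_window,
                 baseline_window = baseline_window),
            class = "task_spec")
}

.in_window <- function(times, w) times >= w[1] - 1e-9 & times <= w[2] + 1e-9

#' Build per-time-point design data for a task
#'
#' For class-vs-class, every retained trial contributes one sample per
#' time-point, labelled by its class. For class-vs-baseline, each trial of
#' the target class contributes an MI-period sample (label 1) and a
#' baseline sample (label 0) taken from the trial's own baseline window,
#' with MI and baseline time-points paired by rank order; classes are
#' balanced by construction and every sample carries its trial id so
#' cross-validation can split at trial level.
#'
#' @param features a [feature_tensor()].
#' @param spec a [task_spec()].
#' @return list with `X` (samples x channels x n_times array), `y` (0/1
#'   labels), `trial` (trial index per sample), `times` (evaluated
#'   time-points), `mi_mask` (which time-points lie in the MI window).
#' @export
build_task <- function(features, spec) {
  stopifnot(inherits(features, "feature_tensor"), inherits(spec, "task_spec"))
  keep <- rep(TRUE, length(features$labels))
  if (!is.null(spec$condition)) keep <- features$condition == spec$condition
  times <- features$times
  if (spec$contrast == "class_vs_class") {
    keep <- keep & features$labels %in% c(spec$class_a, spec$class_b)
    idx <- which(keep)
    if (length(idx) < 4L) stop("too few trials after filtering")
    tsel <- which(.in_window(times, c(min(times), max(times))))
    X <- features$values[idx, , tsel, drop = FALSE]
    y <- as.integer(features$labels[idx] == spec$class_a)
    if (length(unique(y)) < 2L) stop("task needs both classes present")
    return(list(X = X, y = y, trial = idx, times = times[tsel],
                mi_mask = .in_window(times[tsel], spec$mi_window)))
  }
  keep <- keep & features$labels == spec$class_a
  idx <- which(keep)
  if (length(idx) < 4L) stop("too few trials after filtering")
  mi_idx <- which(.in_window(times, spec$mi_window))
  base_idx <- which(.in_window(times, spec$baseline_window))
  if (!length(mi_idx) || !length(base_idx))
    stop("no usable time-points: MI or baseline window does not overlap the ",
         "feature time axis [", signif(min(times), 4), ", ",
         signif(max(times), 4), "] s (entropy edge trimming?)")
  n_pts <- min(length(mi_idx), length(base_idx))
  mi_idx <- mi_idx[seq_len(n_pts)]
  base_idx <- base_idx[seq_len(n_pts)]
  n_tr <- length(idx)
  X <- array(NA_real_, c(2L * n_tr, dim(features$values)[2], n_pts))
  for (t in seq_len(n_pts)) {
    X[, , t] <- rbind(features$values[idx, , mi_idx[t]],
                      features$values[idx, , base_idx[t]])
  }
  list(X = X, y = rep(c(1L, 0L), each = n_tr),
       trial = c(idx, idx), times = times[mi_idx],
       mi_mask = rep(TRUE, n_pts))
}

#' Shrinkage-regularized linear discriminant analysis
#'
#' Two-class LDA on the pooled within-class covariance shrunk toward the
#' scaled identity `nu * I` (`nu` = mean eigenvalue), with the shrinkage
#' intensity chosen by the analytic Ledoit-Wolf-style formula rather than
#' cross-validation, so the fit is deterministic and well-posed even with
#' more channels than samples.
#'
#' @param X samples x features numeric matrix.
#' @param y binary labels (two distinct values; the larger sorted value is
#'   the positive class).
#' @param gamma optional fixed shrinkage intensity in `[0, 1]`; `NULL`
#'   (default) selects it analytically.
#' @return list of class `slda` with weight vector `w`, bias `b`,
#'   shrinkage `gamma`, class levels.
#' @export
fit_slda <- function(X, y, gamma = NULL) {
  X <- as.matrix(X)
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("`y` must contain exactly two classes")
  i0 <- y == lev[1]; i1 <- y == lev[2]
  if (sum(i0) < 2L || sum(i1) < 2L)
    stop("need at least 2 samples per class")
  m0 <- colMeans(X[i0, , drop = FALSE])
  m1 <- colMeans(X[i1, , drop = FALSE])
  Z <- rbind(sweep(X[i0, , drop = FALSE], 2, m0),
             sweep(X[i1, , drop = FALSE], 2, m1))
  n <- nrow(Z); p <- ncol(Z)
  S <- crossprod(Z) / n
  nu <- sum(diag(S)) / p
  if (is.null(gamma)) {
    # analytic shrinkage toward nu * I (Ledoit-Wolf form on centered data)
    Z2 <- Z^2
    varS <- (crossprod(Z2) / n - S^2) / n
    Tm <- diag(nu, p)
    den <- sum((S - Tm)^2)
    gamma <- if (den <= 0) 0 else min(1, max(0, sum(varS) / den))
  }
  St <- (1 - gamma) * S + gamma * nu * diag(p)
  w <- solve(St, m1 - m0)
  b <- -sum(w * (m0 + m1)) / 2
  structure(list(w = as.numeric(w), b = b, gamma = gamma, levels = lev),
            class = "slda")
}

#' @export
predict.slda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  score <- as.numeric(newdata %*% object$w + object$b)
  ifelse(score > 0, object$levels[2], object$levels[1])
}

#' Classification accuracy (percent)
#'
#' `100 * (TP + TN) / n`.
#'
#' @param TP,TN true positive / true negative counts.
#' @param n total number of classified samples.
#' @return accuracy in percent.
#' @export
accuracy_score <- function(TP, TN, n) {
  if (any(n <= 0)) stop("`n` must be positive")
  if (any(TP + TN > n) || any(TP < 0) || any(TN < 0))
    stop("need 0 <= TP + TN <= n")
  100 * (TP + TN) / n
}

#' F1 score (percent)
#'
#' `100 * TP / (TP + 0.5 * (FP + FN))`, the harmonic mean of precision and
#' recall. When `TP = FP = FN = 0` the score is undefined and `NA` is
#' returned with a warning.
#'
#' @param TP,FP,FN confusion counts.
#' @return F1 in percent (or `NA` for the degenerate case).
#' @export
f1_score <- function(TP, FP, FN) {
  if (any(TP < 0) || any(FP < 0) || any(FN < 0))
    stop("counts must be nonnegative")
  den <- TP + 0.5 * (FP + FN)
  out <- ifelse(den > 0, 100 * TP / den, NA_real_)
  if (any(is.na(out)))
    warning("F1 undefined (TP = FP = FN = 0); returning NA")
  out
}

#' Time-resolved cross-validated decoding
#'
#' Runs the task's decoding with five repeated stratified random
#' train/test splits at trial level (75% train / 25% test by default): in
#' every fold a separate shrinkage-LDA model is fitted per time-point on
#' the training trials only, so a trial's MI and baseline samples never
#' straddle the split. Per-time-point accuracy and F1 are averaged over
#' folds, and their means over the MI window are the headline scores.
#'
#' @param features a [feature_tensor()].
#' @param spec a [task_spec()].
#' @param n_folds number of random splits (default 5).
#' @param train_frac fraction of trials used for training (default 0.75).
#' @param seed RNG seed; identical seeds give identical results.
#' @return list of class `decoding_result` with `per_time_accuracy`,
#'   `per_time_f1`, `times`, `mi_mean_accuracy`, `mi_mean_f1`, `folds`
#'   (test-trial sets), `confusion` (summed over folds and MI window),
#'   `seed`, `participant_id`.
#' @export
crossvalidate <- function(features, spec, n_folds = 5, train_frac = 0.75,
                          seed = 1) {
  task <- build_task(features, spec)
  trials <- unique(task$trial)
  trial_class <- vapply(trials,
                        function(tr) task$y[match(tr, task$trial)], 0L)
  if (spec$contrast == "class_vs_class") {
    per_class <- table(trial_class)
    if (any(per_class < 8L))
      stop("need at least 8 trials per class, got ",
           paste(per_class, collapse = "/"))
  } else if (length(trials) < 8L) {
    stop("need at least 8 trials, got ", length(trials))
  }
  n_t <- length(task$times)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  folds <- vector("list", n_folds)
  acc <- f1 <- matrix(NA_real_, n_folds, n_t)
  conf <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (f in seq_len(n_folds)) {
    train_trials <- unlist(lapply(split(trials, trial_class), function(tr) {
      sample(tr, max(1L, round(train_frac * length(tr))))
    }), use.names = FALSE)
    test_trials <- setdiff(trials, train_trials)
    folds[[f]] <- sort(test_trials)
    tr_mask <- task$trial %in% train_trials
    te_mask <- !tr_mask
    if (length(unique(task$y[te_mask])) < 2L)
      stop("a fold's test set lacks one class; increase the trial count")
    for (t in seq_len(n_t)) {
      mdl <- fit_slda(task$X[tr_mask, , t, drop = FALSE][, , 1],
                      task$y[tr_mask])
      pred <- predict(mdl, task$X[te_mask, , t, drop = FALSE][, , 1])
      truth <- task$y[te_mask]
      TP <- sum(pred == 1 & truth == 1); TN <- sum(pred == 0 & truth == 0)
      FP <- sum(pred == 1 & truth == 0); FN <- sum(pred == 0 & truth == 1)
      acc[f, t] <- accuracy_score(TP, TN, length(truth))
      f1[f, t] <- if (TP + FP + FN > 0) f1_score(TP, FP, FN) else NA_real_
      if (task$mi_mask[t])
        conf <- conf + c(TP = TP, TN = TN, FP = FP, FN = FN)
    }
  }
  per_acc <- colMeans(acc)
  per_f1 <- colMeans(f1, na.rm = TRUE)
  mi <- task$mi_mask
  structure(list(per_time_accuracy = per_acc, per_time_f1 = per_f1,
                 times = task$times,
                 mi_mean_accuracy = mean(per_acc[mi]),
                 mi_mean_f1 = mean(per_f1[mi], na.rm = TRUE),
                 folds = folds, confusion = conf, seed = seed,
                 spec = spec,
                 participant_id = features$participant_id),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> %s %s%s: MI-period accuracy %.2f%%, F1 %.2f%%\n",
    x$spec$contrast, x$spec$class_a,
    if (!is.null(x$spec$class_b)) paste0(" vs ", x$spec$class_b) else
      " vs baseline",
    x$mi_mean_accuracy, x$mi_mean_f1))
  invisible(x)
}

#' Grand average over participants
#'
#' Unweighted mean over participants of the per-participant MI-window mean
#' accuracy and F1.
#'
#' @param results list of `decoding_result`s, one per participant.
#' @return list with `accuracy`, `f1` (percent) and the per-participant
#'   values.
#' @export
grand_average <- function(results) {
  if (!length(results)) stop("empty result list")
  acc <- vapply(results, function(r) r$mi_mean_accuracy, 0)
  f1 <- vapply(results, function(r) r$mi_mean_f1, 0)
  list(accuracy = mean(acc), f1 = mean(f1),
       per_participant_accuracy = acc, per_participant_f1 = f1)
}
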