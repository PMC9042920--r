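#' Sliding-window configuration for asynchronous classification
#'
#' Defaults: 1.06 s window (68 samples at 64 Hz), 15.625 ms step (1 sample),
#' 2 s refractory period after each detection, and a (0, 2] s match window
#' after a true onset for scoring.
#'
#' @param window Window width in samples.
#' @param step Step in samples (1 = every sample).
#' @param refractory Refractory period, seconds.
#' @param match_window Match window, seconds.
#' @export
sliding_config <- function(window = 68L, step = 1L, refractory = 2,
                           match_window = 2) {
  list(window = as.integer(window), step = as.integer(step),
       refractory = refractory, match_window = match_window)
}

# Binary PEP probability at every window position of a continuous 64 Hz
# block. Window `t` covers samples (t - window + 1):t and its detection
# time is the time of its last sample, (t - 1)/rate. Computed via causal
# convolution: S_ij(t) = sum_tau (W' X)_i(t - window + tau) V(tau, j), so
# the BCSP features of all windows come from k_s x k_t filterings of the
# spatially projected signal.
#' @noRd
stream_probabilities <- function(decoder, x, prepend = NULL) {
  x <- as_continuous_eeg(x)
  dat <- if (is.null(prepend)) x$data else cbind(prepend, x$data)
  w <- nrow(decoder$bcsp$V)
  if (ncol(dat) < w) stopf("block shorter than one window")
  Y <- crossprod(decoder$bcsp$W, dat)
  ks <- ncol(decoder$bcsp$W); kt <- ncol(decoder$bcsp$V)
  n <- ncol(dat)
  Smat <- array(NA_real_, c(ks, kt, n))
  for (j in seq_len(kt)) {
    kern <- rev(decoder$bcsp$V[, j])
    for (i in seq_len(ks))
      Smat[i, j, ] <- stats::filter(Y[i, ], kern, method = "convolution",
                                    sides = 1)
  }
  valid <- w:n
  feats <- matrix(NA_real_, length(valid), ks + kt)
  S2 <- Smat[, , valid, drop = FALSE]^2
  feats[, seq_len(ks)] <- t(apply(S2, c(1, 3), sum))
  feats[, ks + seq_len(kt)] <- t(apply(S2, c(2, 3), sum))
  p <- predict(decoder$svm_bin,
               apply_normalizer(decoder$norm_bin, feats),
               type = "prob")[, "pep"]
  full <- rep(-Inf, n)
  full[valid] <- p
  full
}

#' Simulated-online sliding-window classification of a block
#'
#' Slides the detection window sample by sample over preprocessed 64 Hz
#' data, emits a detection whenever the calibrated PEP probability reaches
#' the threshold outside the refractory period, and labels each detection
#' with the 4-class stage applied to the lag-compensated epoch.
#'
#' @param decoder A tuned [pep_decoder()].
#' @param x A [continuous_eeg()] at 64 Hz (online preprocessing: no epoch
#'   rejection).
#' @param cfg A [sliding_config()].
#' @param threshold Override of the decoder's tuned threshold.
#' @param label Run the second (4-class) stage on each detection.
#' @param state Streaming state from a previous chunk (carries the window
#'   tail and the refractory clock); pass `TRUE` to start a stream.
#' @return A data.frame of detections (`time` s, `sample`, `prob`,
#'   `label`); when streaming, the continuation state is attached as
#'   attribute `"state"`.
#' @export
stream_classify <- function(decoder, x, cfg = sliding_config(),
                            threshold = NULL, label = TRUE, state = NULL) {
  x <- as_continuous_eeg(x)
  threshold <- threshold %||% decoder$threshold
  if (is.na(threshold)) stopf("no detection threshold available")
  prepend <- if (is.list(state)) state$tail else NULL
  offset <- if (is.list(state)) state$offset else 0L
  p <- stream_probabilities(decoder, x, prepend)
  refr <- round(cfg$refractory * x$rate)
  npre <- if (is.null(prepend)) 0L else ncol(prepend)
  if (cfg$step > 1L) { # coarser stepping: only window ends on the step grid
    pos <- seq_along(p)
    p[((pos - cfg$window) %% cfg$step) != 0] <- -Inf
  }
  # first eligible window end (0-based for the scanner)
  start0 <- cfg$window - 1L
  if (is.list(state) && is.finite(state$last_det)) {
    gate <- state$last_det + refr - (offset - npre) - 1L
    start0 <- max(start0, gate)
  }
  idx <- refractory_scan_cpp(p, threshold, refr, start0)
  abs_idx <- idx + offset - npre
  times <- (abs_idx - 1) / x$rate
  labels <- rep(NA_character_, length(idx))
  if (label && length(idx)) {
    if (is.na(decoder$lag)) stopf("decoder has no tuned time lag")
    for (i in seq_along(idx)) {
      ep <- lag_shifted_epoch(x, (idx[i] - npre - 1) / x$rate, decoder$lag,
                              decoder$pre, decoder$len - decoder$pre)
      if (!is.null(ep))
        labels[i] <- as.character(pep_expression(decoder, ep))
    }
  }
  out <- data.frame(time = times, sample = abs_idx,
                    prob = if (length(idx)) p[idx] else numeric(0),
                    label = labels, stringsAsFactors = FALSE)
  if (!is.null(state)) {
    w <- cfg$window
    full <- if (is.null(prepend)) x$data else cbind(prepend, x$data)
    tail_mat <- full[, max(1, ncol(full) - w + 2):ncol(full),
                     drop = FALSE]
    attr(out, "state") <- list(
      tail = tail_mat, offset = offset + ncol(x$data),
      last_det = if (length(abs_idx)) abs_idx[length(abs_idx)] else
        if (is.list(state)) state$last_det else -Inf)
  }
  out
}

#' Match detections to true onsets
#'
#' A detection is a true positive when it falls in `(0, match_window]`
#' seconds after an as-yet-unmatched onset (earliest onset first);
#' otherwise it is a false positive. Unmatched onsets are false negatives.
#'
#' @param detections Detection times, seconds (sorted).
#' @param onsets True onset times, seconds (sorted).
#' @param match_window Match window, seconds.
#' @return A list with `tp`, `fp`, `fn`, `lags` (per true positive),
#'   `matched` (onset index per detection, NA for FP).
#' @export
match_detections <- function(detections, onsets, match_window = 2) {
  detections <- sort(detections)
  onsets <- sort(onsets)
  used <- rep(FALSE, length(onsets))
  matched <- rep(NA_integer_, length(detections))
  lags <- numeric(0)
  for (i in seq_along(detections)) {
    d <- detections[i]
    cand <- which(!used & d - onsets > 0 & d - onsets <= match_window)
    if (length(cand)) {
      j <- cand[1]                 # earliest unmatched onset
      used[j] <- TRUE
      matched[i] <- j
      lags <- c(lags, d - onsets[j])
    }
  }
  list(tp = sum(!is.na(matched)), fp = sum(is.na(matched)),
       fn = sum(!used), lags = lags, matched = matched)
}

#' Precision, recall and F1 from detection counts
#'
#' Implements `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)` and
#' `F1 = 2*TP/(2*TP+FP+FN)`. Undefined ratios (empty denominator) are
#' reported as 0 with a warning.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return A list with `precision`, `recall`, `f1`.
#' @export
f1_from_counts <- function(tp, fp, fn) {
  if (tp < 0 || fp < 0 || fn < 0) stopf("counts must be non-negative")
  if (tp + fp + fn == 0) stopf("no events to score")
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    warnf("no positives predicted; precision defined as 0"); 0 }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    warnf("no true events; recall defined as 0"); 0 }
  f1 <- 2 * tp / (2 * tp + fp + fn)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Optimize the detection threshold on the tuning block
#'
#' Evaluates the sliding-window detector at `n` evenly spaced probability
#' thresholds in (0, 1), scoring each by the F1 of its matched detections
#' against the true onsets, and returns the maximizer (ties: the highest
#' threshold, i.e. the fewest false positives).
#'
#' @param decoder A fitted [pep_decoder()] (threshold not needed).
#' @param x Preprocessed 64 Hz [continuous_eeg()] of the tuning block.
#' @param onsets True perturbation onset times, seconds.
#' @param cfg A [sliding_config()].
#' @param n Number of thresholds (default 500).
#' @return A list with `threshold`, `f1`, and the full `table`
#'   (threshold, tp, fp, fn, f1).
#' @export
optimize_threshold <- function(decoder, x, onsets, cfg = sliding_config(),
                               n = 500) {
  x <- as_continuous_eeg(x)
  p <- stream_probabilities(decoder, x)
  refr <- round(cfg$refractory * x$rate)
  thresholds <- seq_len(n) / (n + 1)
  tab <- data.frame(threshold = thresholds, tp = 0L, fp = 0L, fn = 0L,
                    f1 = 0)
  for (i in seq_len(n)) {
    idx <- refractory_scan_cpp(p, thresholds[i], refr, cfg$window - 1L)
    m <- match_detections((idx - 1) / x$rate, onsets, cfg$match_window)
    tab$tp[i] <- m$tp; tab$fp[i] <- m$fp; tab$fn[i] <- m$fn
    denom <- 2 * m$tp + m$fp + m$fn
    tab$f1[i] <- if (denom > 0) 2 * m$tp / denom else 0
  }
  if (all(tab$f1 == 0))
    warnf("all candidate thresholds score F1 = 0; returning the highest")
  best <- order(-tab$f1, -tab$threshold)[1]
  list(threshold = tab$threshold[best], f1 = tab$f1[best], table = tab)
}

#' Evaluate the tuned asynchronous model on the validation block
#'
#' Binary accuracy is the percentage of perturbations detected correctly,
#' `100 * TP / (TP + FN)`; false positives enter the F1 score only.
#' 4-class metrics are computed over the correctly detected (TP) trials:
#' macro F1 is the mean of the per-class one-vs-rest F1 scores, and the
#' 4-class confusion matrix is marginalized into angle (5 vs 10 degrees)
#' and direction (left vs right) tables.
#'
#' @param decoder A tuned [pep_decoder()].
#' @param x Preprocessed 64 Hz [continuous_eeg()] of the validation block.
#' @param truth Data.frame with `time` (s) and `label` of the true
#'   perturbations.
#' @param cfg A [sliding_config()].
#' @param validation_block Optional block id, checked against the decoder's
#'   calibration/tuning provenance.
#' @return A list of class `pep_async_result`.
#' @export
validate_async <- function(decoder, x, truth, cfg = sliding_config(),
                           validation_block = NA_integer_) {
  if (!is.na(validation_block)) {
    prov <- decoder$provenance
    if (validation_block %in% prov$calibration_blocks ||
        identical(validation_block, prov$tuning_block))
      stopf("validation block %d was used for training or tuning",
            validation_block)
  }
  det <- stream_classify(decoder, x, cfg)
  m <- match_detections(det$time, truth$time, cfg$match_window)
  counts <- f1_from_counts(m$tp, m$fp, m$fn)
  binary_accuracy <- 100 * m$tp / (m$tp + m$fn)
  classes <- decoder$classes
  conf <- matrix(0L, length(classes), length(classes),
                 dimnames = list(true = classes, predicted = classes))
  if (m$tp > 0) {
    tp_idx <- which(!is.na(m$matched))
    for (i in tp_idx) {
      tl <- truth$label[m$matched[i]]
      pl <- det$label[i]
      if (!is.na(pl)) conf[tl, pl] <- conf[tl, pl] + 1L
    }
  }
  per_class_f1 <- vapply(classes, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  angle_of <- function(l) sub("^(left|right)", "", l)
  dir_of <- function(l) sub("[0-9.]+$", "", l)
  marginal <- function(f) {
    g <- unique(f(classes))
    out <- matrix(0L, length(g), length(g), dimnames = list(true = g,
                                                            predicted = g))
    for (a in classes) for (b in classes)
      out[f(a), f(b)] <- out[f(a), f(b)] + conf[a, b]
    out
  }
  multiclass_available <- m$tp > 0 && sum(conf) > 0
  structure(list(
    tp = m$tp, fp = m$fp, fn = m$fn,
    precision = counts$precision, recall = counts$recall,
    f1 = counts$f1, binary_accuracy = binary_accuracy,
    lags = m$lags,
    multiclass_available = multiclass_available,
    confusion = conf,
    confusion_angle = marginal(angle_of),
    confusion_direction = marginal(dir_of),
    per_class_f1 = per_class_f1,
    macro_f1 = if (multiclass_available) mean(per_class_f1) else
      NA_real_,
    multiclass_accuracy = if (multiclass_available)
      100 * sum(diag(conf)) / sum(conf) else NA_real_),
    class = "pep_async_result")
}

#' @export
print.pep_async_result <- function(x, ...) {
  cat(sprintf("<async validation> TP %d FP %d FN %d | binary accuracy %.1f%%, F1 %.3f\n",
              x$tp, x$fp, x$fn, x$binary_accuracy, x$f1))
  if (x$multiclass_available)
    cat(sprintf("  4-class: accuracy %.1f%%, macro F1 %.3f (over TP trials)\n",
                x$multiclass_accuracy, x$macro_f1))
  else cat("  4-class metrics not available (no true positives)\n")
  if (length(x$lags))
    cat(sprintf("  detection lag: mean %.3f s, median %.3f s\n",
                mean(x$lags), median(x$lags)))
  invisible(x)
}
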