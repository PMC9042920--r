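#' Grand-average waveforms per condition
#'
#' Averages epochs within condition; with a `subject` grouping the average
#' is taken per subject first and then across subjects (subject-weighted),
#' so unbalanced trial counts do not bias the grand average.
#'
#' @param epochs A [epoch_set()] (or trials x channels x samples array).
#' @param labels Condition labels (defaults to the epoch set's).
#' @param subject Optional subject id per trial.
#' @return A named list of channels x samples mean waveforms (uV).
#' @export
grand_average <- function(epochs, labels = NULL, subject = NULL) {
  d <- if (inherits(epochs, "pep_epochs")) epochs$data else epochs
  labels <- labels %||% epochs$labels
  labels <- as.factor(labels)
  out <- list()
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (!length(idx)) next
    if (is.null(subject)) {
      out[[cl]] <- apply(d[idx, , , drop = FALSE], c(2, 3), mean)
    } else {
      subs <- unique(subject[idx])
      acc <- 0
      for (s in subs)
        acc <- acc + apply(d[idx[subject[idx] == s], , , drop = FALSE],
                           c(2, 3), mean)
      out[[cl]] <- acc / length(subs)
    }
  }
  out
}

#' Signed r-squared discriminability map between two classes
#'
#' Per (channel, sample): the point-biserial correlation r between the
#' amplitude and class membership, returned as `sign(r) * r^2`. Positive
#' values mean larger amplitude in class A.
#'
#' @param a,b Epoch arrays (trials x channels x samples) or [epoch_set()]s
#'   of the two classes.
#' @return A channels x samples matrix in [-1, 1].
#' @export
signed_r2 <- function(a, b) {
  A <- if (inherits(a, "pep_epochs")) a$data else a
  B <- if (inherits(b, "pep_epochs")) b$data else b
  na <- dim(A)[1]; nb <- dim(B)[1]
  if (na < 2 || nb < 2) stopf("need >= 2 epochs per class")
  y <- c(rep(1, na), rep(0, nb))
  nc <- dim(A)[2]; ns <- dim(A)[3]
  X <- rbind(matrix(A, na, nc * ns), matrix(B, nb, nc * ns))
  xm <- colMeans(X)
  xc <- t(X) - xm
  yc <- y - mean(y)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(sum(yc^2))
  r <- as.numeric(xc %*% yc) / (sx * sy)
  r[!is.finite(r)] <- 0
  matrix(sign(r) * r^2, nc, ns)
}

#' Per-trial mean amplitude over a time interval
#'
#' Includes exactly the samples whose post-onset time falls inside the
#' closed interval `[start, end]` (sample-snapped).
#'
#' @param epochs A [epoch_set()].
#' @param interval `c(start, end)` in seconds post-onset.
#' @return Trials x channels matrix of interval means (uV).
#' @export
interval_means <- function(epochs, interval) {
  idx <- interval_samples(interval, epochs$rate, epochs$pre,
                          dim(epochs$data)[3])
  apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
}

# samples (1-based within epoch) whose post-onset time lies in
# [start, end]; onset is at epoch sample pre + 1 (time 0), so post-onset
# sample k has time k/rate. [0.5, 0.63] s at 64 Hz covers post-onset
# samples 32..40 inclusive.
#' @noRd
interval_samples <- function(interval, rate, pre, len) {
  s0 <- ceiling(interval[1] * rate - 1e-9)
  s1 <- floor(interval[2] * rate + 1e-9)
  if (s1 < s0) stopf("interval narrower than one sample")
  idx <- (pre + 1 + s0):(pre + 1 + s1)
  idx <- idx[idx >= 1 & idx <= len]
  if (!length(idx)) stopf("interval outside the epoch")
  idx
}

#' Default analysis intervals for the angle and direction contrasts
#'
#' The fourth angle window, [0.50, 0.63] s, and the direction windows
#' [0.15, 0.17], [0.42, 0.56] and [0.80, 1.00] s follow the windows in
#' which the two contrasts show significant effects; the remaining windows
#' (N1/P2 region) are reconstructions with configurable bounds.
#'
#' @return A list with `angle` and `direction`, each a named list of
#'   `c(start, end)` windows (4 per contrast).
#' @export
default_intervals <- function() {
  list(
    angle = list(n1 = c(0.08, 0.15), p2 = c(0.15, 0.20),
                 early_late = c(0.32, 0.50), late = c(0.50, 0.63)),
    direction = list(n1 = c(0.08, 0.15), p2 = c(0.15, 0.17),
                     mid = c(0.42, 0.56), late = c(0.80, 1.00)))
}

#' Interval-based one-sided Wilcoxon rank-sum tests with Bonferroni
#' correction
#'
#' For every channel and interval, compares the per-trial interval means of
#' the two conditions with a one-sided Wilcoxon rank-sum test. The test
#' direction per interval is taken from the sign of the grand-average
#' difference at the channel where that difference is largest in magnitude
#' (the dominant lobe); on average-referenced data the channel-pooled mean
#' difference is identically near zero and cannot define a direction.
#' P-values are Bonferroni-adjusted with family size `n_comparisons`
#' (63 channels x 4 intervals = 252).
#'
#' @param a,b [epoch_set()]s of the two conditions (>= 5 trials each).
#' @param intervals Named list of `c(start, end)` windows (4 by default).
#' @param alpha Significance level after correction.
#' @param n_comparisons Bonferroni family size.
#' @return A data.frame of class `pep_stats` with one row per
#'   (channel, interval): statistic, raw and adjusted p-values,
#'   significance flag and test direction.
#' @export
wilcoxon_interval_test <- function(a, b, intervals, alpha = 0.05,
                                   n_comparisons = 252) {
  if (dim(a$data)[1] < 5 || dim(b$data)[1] < 5)
    stopf("need >= 5 trials per condition")
  nc <- dim(a$data)[2]
  rows <- list()
  for (iv in names(intervals)) {
    ma <- interval_means(a, intervals[[iv]])
    mb <- interval_means(b, intervals[[iv]])
    dch <- colMeans(ma) - colMeans(mb)
    direction <- if (dch[which.max(abs(dch))] >= 0) "greater" else "less"
    for (ch in seq_len(nc)) {
      wt <- suppressWarnings(
        wilcox.test(ma[, ch], mb[, ch], alternative = direction,
                    exact = FALSE, correct = TRUE))
      p_adj <- min(1, n_comparisons * wt$p.value)
      rows[[length(rows) + 1]] <- data.frame(
        channel = ch, interval = iv, statistic = unname(wt$statistic),
        p = wt$p.value, p_adj = p_adj,
        significant = p_adj < alpha, direction = direction,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pep_stats", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "n_comparisons") <- n_comparisons
  out
}
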