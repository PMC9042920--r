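#' Estimate the detection time lag on the tuning block
#'
#' The time lag of a trial is the difference between the asynchronous
#' detection time and the true perturbation onset; the subject-specific lag
#' is the arithmetic mean over all matched (true-positive) trials of the
#' tuning block.
#'
#' @param detections Detection times in seconds (e.g. from
#'   [stream_classify()]).
#' @param onsets True perturbation onset times in seconds.
#' @param match_window Maximum lag for a detection to count as matched, s.
#' @return A list of class `pep_lag` with `lags` (per matched trial),
#'   `mean` (s) and the match counts.
#' @export
estimate_time_lag <- function(detections, onsets, match_window = 2) {
  m <- match_detections(detections, onsets, match_window)
  if (m$tp == 0)
    stopf("no true-positive detections; cannot calibrate the time lag")
  structure(list(lags = m$lags, mean = mean(m$lags), tp = m$tp,
                 fp = m$fp, fn = m$fn),
            class = "pep_lag")
}

#' @export
print.pep_lag <- function(x, ...) {
  cat(sprintf("<time lag> mean %.3f s over %d matched trials (FP %d, FN %d)\n",
              x$mean, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Extract a lag-compensated epoch around a detection
#'
#' Shifts the epoch anchor back by the mean lag so that the multiclass
#' stage sees an epoch aligned to the estimated perturbation onset, with
#' the standard 4 + 64 sample geometry.
#'
#' @param x A [continuous_eeg()] object at 64 Hz.
#' @param detection_time Detection time in seconds (end of the detecting
#'   window).
#' @param mean_lag Mean lag in seconds.
#' @param pre,post Epoch geometry in samples.
#' @return A channels x samples matrix, or `NULL` when the shifted epoch
#'   falls outside the recording (the skip is signalled via attribute).
#' @export
lag_shifted_epoch <- function(x, detection_time, mean_lag, pre = 4L,
                              post = 64L) {
  x <- as_continuous_eeg(x)
  anchor <- round((detection_time - mean_lag) * x$rate) + 1L
  if (anchor - pre < 1 || anchor + post - 1 > ncol(x$data)) return(NULL)
  x$data[, (anchor - pre):(anchor + post - 1), drop = FALSE]
}
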