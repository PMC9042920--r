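#' Detect bad channels by neighbor correlation
#'
#' A channel is flagged bad when its maximum absolute Pearson correlation
#' with its spatial neighbors falls below the threshold (75% in the default
#' chain). Correlations are computed on the supplied (band-pass filtered,
#' 64 Hz) data; using the maximum makes the rule robust to one bad neighbor.
#'
#' @param x A [continuous_eeg()] object.
#' @param montage Montage data.frame matching the channels of `x`.
#' @param threshold Correlation threshold (default 0.75).
#' @param neighbors Optional precomputed [channel_neighbors()] list.
#' @return Logical bad-channel mask.
#' @export
detect_bad_channels <- function(x, montage, threshold = 0.75,
                                neighbors = NULL) {
  x <- as_continuous_eeg(x)
  if (nrow(x$data) != nrow(montage))
    stopf("montage does not match channel count")
  if (nrow(x$data) < 2) stopf("need at least 2 channels")
  neighbors <- neighbors %||% channel_neighbors(montage)
  C <- suppressWarnings(cor(t(x$data)))
  C[is.na(C)] <- 0
  vapply(seq_len(nrow(x$data)), function(i)
    max(abs(C[i, neighbors[[i]]])) < threshold, logical(1))
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean over good channels from every
#' channel. After CAR the mean over good channels is zero and pairwise
#' channel differences are unchanged.
#'
#' @param x A [continuous_eeg()] object; its `bad` mask is excluded from the
#'   average.
#' @export
apply_car <- function(x) {
  x <- as_continuous_eeg(x)
  good <- !x$bad
  if (!any(good)) stopf("no good channels for the reference")
  ref <- colMeans(x$data[good, , drop = FALSE])
  x$data <- sweep(x$data, 2, ref)
  x
}

#' Interpolate bad channels from their neighbors
#'
#' Inverse-distance-weighted reconstruction from the nearest good channels;
#' the weights are positive and sum to one, good channels are untouched.
#'
#' @param x A [continuous_eeg()] object with a `bad` mask.
#' @param montage Montage data.frame.
#' @param k Number of good channels used per reconstruction.
#' @export
interpolate_channels <- function(x, montage, k = 8) {
  x <- as_continuous_eeg(x)
  if (!any(x$bad)) return(x)
  good <- which(!x$bad)
  if (length(good) < 3) stopf("need at least 3 good channels")
  D <- montage_distances(montage)
  for (b in which(x$bad)) {
    d <- D[b, good]
    sel <- good[order(d)][seq_len(min(k, length(good)))]
    w <- 1 / pmax(D[b, sel], 1e-6)^2
    w <- w / sum(w)
    x$data[b, ] <- as.numeric(w %*% x$data[sel, , drop = FALSE])
  }
  x
}

#' Detect perturbation onsets from accelerometer data
#'
#' High-passes each axis, takes the vector magnitude, and reports rising-edge
#' threshold crossings separated by at least `min_sep` seconds. The default
#' threshold is `median + 10 * MAD` of the magnitude, a robust rule that
#' clears both the sensor noise floor and the gentle standard movements while
#' perturbation ramps exceed it by an order of magnitude.
#'
#' @param accel 3 x samples accelerometer matrix, m/s^2.
#' @param rate Accelerometer rate, Hz.
#' @param threshold Absolute threshold in m/s^2, or `NULL` for the robust
#'   default.
#' @param hp_cutoff High-pass cutoff, Hz.
#' @param min_sep Minimum separation between onsets, seconds.
#' @param eeg_rate Rate of the EEG clock the onsets are mapped to, Hz.
#' @return A data.frame with `time` (s) and `sample` (1-based index on the
#'   `eeg_rate` clock).
#' @export
detect_onsets <- function(accel, rate = 50, threshold = NULL,
                          hp_cutoff = 0.5, min_sep = 5, eeg_rate = 64) {
  if (!is.matrix(accel)) accel <- matrix(accel, nrow = 1)
  sos <- butter_sos(2, hp_cutoff, rate, "high")
  hp <- t(apply(accel, 1, function(a) sos_filter(a, sos)$y))
  mag <- sqrt(colSums(hp^2))
  if (is.null(threshold)) {
    threshold <- median(mag) + 10 * mad(mag)
    if (threshold <= quantile(mag, 0.9))
      warnf("onset threshold at the noise floor; expect spurious onsets")
  }
  above <- mag >= threshold
  cross <- which(above & !c(FALSE, above[-length(above)]))
  keep <- integer(0)
  last <- -Inf
  for (i in cross) {
    if ((i - last) / rate >= min_sep) {
      keep <- c(keep, i)
      last <- i
    }
  }
  times <- (keep - 1) / rate
  data.frame(time = times, sample = round(times * eeg_rate) + 1L)
}

#' Extract perturbation and rest epochs
#'
#' Perturbation epochs cover [-0.06, 1] s around each onset, realized at
#' 64 Hz as 4 pre-onset plus 64 post-onset samples (68 samples, 1.0625 s).
#' Rest epochs use the identical geometry anchored 7 s (448 samples) before
#' the onset, i.e. the [-7.06, -6] s interval. Epochs that would cross the
#' recording edges are dropped.
#'
#' @param x A [continuous_eeg()] object at 64 Hz.
#' @param onsets Onset sample indices (64 Hz clock, 1-based).
#' @param labels Condition label per onset (`left5`, ...).
#' @param rest Also extract a rest epoch per onset (default `TRUE`).
#' @param pre,post Epoch geometry in samples.
#' @param rest_shift Rest anchor shift in samples (7 s x 64 Hz = 448).
#' @param block Optional block id per onset.
#' @return A [epoch_set()]; skipped onsets are reported via attribute
#'   `"skipped"`.
#' @export
extract_epochs <- function(x, onsets, labels, rest = TRUE, pre = 4L,
                           post = 64L, rest_shift = 448L, block = NULL) {
  x <- as_continuous_eeg(x)
  n <- ncol(x$data)
  len <- pre + post
  anchors <- c(onsets, if (rest) onsets - rest_shift)
  labs <- c(as.character(labels),
            if (rest) rep("rest", length(onsets)))
  blks <- rep(block %||% rep(NA_integer_, length(onsets)),
              if (rest) 2 else 1)
  ok <- anchors - pre >= 1 & anchors + post - 1 <= n
  skipped <- which(!ok)
  anchors <- anchors[ok]; labs <- labs[ok]; blks <- blks[ok]
  dat <- array(0, c(length(anchors), nrow(x$data), len))
  for (i in seq_along(anchors))
    dat[i, , ] <- x$data[, (anchors[i] - pre):(anchors[i] + post - 1)]
  out <- epoch_set(dat, labs, anchors, x$rate, pre, blocks = blks)
  attr(out, "skipped") <- skipped
  out
}

# excess kurtosis per vector
#' @noRd
kurt <- function(v) {
  m <- mean(v); s2 <- mean((v - m)^2)
  if (s2 <= 0) return(0)
  mean((v - m)^4) / s2^2 - 3
}

#' Statistical epoch rejection
#'
#' Marks an epoch rejected when (a) any sample exceeds the amplitude bound,
#' (b) its whole-epoch joint log-probability (under a Gaussian fit pooled
#' across epochs, summed over channels) deviates more than `z_limit` SDs
#' from the across-epoch mean, or (c) a per-channel kurtosis deviates more
#' than `z_limit` SDs across epochs. The per-channel sample kurtosis is
#' variance-stabilized with `log(excess + 3)` before z-scoring: the raw
#' estimator is strongly right-skewed at 68 samples, which would otherwise
#' make a nominal 4 SD bound fire on a few percent of perfectly clean
#' epochs per channel and, over 63 channels, reject a large fraction of
#' clean data. The first matching reason is recorded.
#'
#' @param epochs A [epoch_set()].
#' @param amp_limit Amplitude bound in uV (default 150).
#' @param z_limit SD bound for the distribution criteria (default 4).
#' @return The epoch set with `kept` and `reason` updated.
#' @export
reject_epochs <- function(epochs, amp_limit = 150, z_limit = 4) {
  d <- epochs$data
  nt <- dim(d)[1]; nc <- dim(d)[2]
  if (nt < 10) stopf("need at least 10 epochs for distribution estimates")
  amp_bad <- apply(abs(d), 1, max) > amp_limit
  mu <- apply(d, 2, mean)                    # per-channel pooled mean
  sdv <- pmax(apply(d, 2, sd), 1e-12)
  logp <- matrix(0, nt, nc)                  # per epoch x channel
  for (c in seq_len(nc))
    logp[, c] <- rowSums(dnorm(d[, c, ], mu[c], sdv[c], log = TRUE))
  glob <- as.numeric(scale(rowSums(logp)))
  glob[is.nan(glob)] <- 0
  jp_bad <- abs(glob) > z_limit
  km <- matrix(0, nt, nc)
  for (c in seq_len(nc))
    km[, c] <- apply(d[, c, , drop = FALSE], 1, kurt)
  kz <- scale(log(pmax(km + 3, 1e-6)))
  kz[is.nan(kz)] <- 0
  ku_bad <- apply(abs(kz), 1, max) > z_limit
  reason <- rep("", nt)
  reason[ku_bad] <- "kurtosis"
  reason[jp_bad] <- "jointprob"
  reason[amp_bad] <- "amplitude"
  epochs$kept <- reason == ""
  epochs$reason <- reason
  epochs
}

#' Fit the subject-specific preprocessing state on calibration blocks
#'
#' Runs the causal chain (notch, band-pass, downsample) on the calibration
#' blocks, detects bad channels there, fits the HEAR artifact-correction
#' state, and derives the accelerometer onset threshold. The state is then
#' applied unchanged to tuning and validation blocks, mirroring an online
#' system calibrated once.
#'
#' @param rec A [recording()].
#' @param calibration_blocks Block numbers used for fitting.
#' @param notch_freq Line frequency, Hz.
#' @param band Pass band, Hz.
#' @param order Butterworth order.
#' @param target_rate Decimation target, Hz.
#' @return An object of class `pep_prep`.
#' @export
fit_preprocessor <- function(rec, calibration_blocks = 1:4,
                             notch_freq = 50, band = c(1, 28), order = 4,
                             target_rate = 64) {
  stage1 <- lapply(calibration_blocks, function(b)
    prep_stage1(recording_block(rec, b), notch_freq, band, order,
                target_rate))
  calib <- continuous_eeg(do.call(cbind, lapply(stage1, `[[`, "data")),
                          target_rate, stage1[[1]]$channels)
  bad <- detect_bad_channels(calib, rec$montage)
  calib$bad <- bad
  ref <- interpolate_channels(apply_car(calib), rec$montage)
  hear <- hear_fit(ref, rec$montage)
  mags <- lapply(calibration_blocks, function(b) {
    acc <- recording_block(rec, b)$accel
    sos <- butter_sos(2, 0.5, rec$accel_rate, "high")
    hp <- t(apply(acc, 1, function(a) sos_filter(a, sos)$y))
    sqrt(colSums(hp^2))
  })
  mag <- unlist(mags)
  structure(list(bad = bad, hear = hear,
                 accel_threshold = median(mag) + 10 * mad(mag),
                 notch_freq = notch_freq, band = band, order = order,
                 target_rate = target_rate,
                 calibration_blocks = calibration_blocks,
                 montage = rec$montage),
            class = "pep_prep")
}

#' @noRd
prep_stage1 <- function(blockrec, notch_freq, band, order, target_rate) {
  x <- continuous_eeg(blockrec$eeg, blockrec$eeg_rate, blockrec$montage$name)
  x <- notch_filter(x, notch_freq)
  x <- bandpass_causal(x, band, order)
  downsample(x, target_rate)
}

#' Apply the causal preprocessing chain to one block
#'
#' Chain order: notch, band-pass, downsample, bad-channel masking, common
#' average reference over good channels, interpolation of bad channels, HEAR
#' correction. This is the online-safe entry point: it contains no epoch
#' rejection stage (rejection exists only in the offline epoch path, see
#' [reject_epochs()]).
#'
#' @param prep A `pep_prep` state from [fit_preprocessor()].
#' @param rec A [recording()].
#' @param block Block number to process.
#' @return A list with `eeg` (a 64 Hz [continuous_eeg()]), `onsets`
#'   (detected accelerometer onsets, 64 Hz clock), and `truth` (ground-truth
#'   target markers of the block mapped to the 64 Hz clock).
#' @export
preprocess_block <- function(prep, rec, block) {
  br <- recording_block(rec, block)
  x <- prep_stage1(br, prep$notch_freq, prep$band, prep$order,
                   prep$target_rate)
  x$bad <- prep$bad
  x <- interpolate_channels(apply_car(x), prep$montage)
  x <- hear_apply(x, prep$hear)
  ons <- detect_onsets(br$accel, br$accel_rate, prep$accel_threshold,
                       eeg_rate = prep$target_rate)
  tg <- br$markers[br$markers$kind == "target", , drop = FALSE]
  truth <- data.frame(
    sample = floor((tg$sample - 1) / (br$eeg_rate / prep$target_rate)) + 1L,
    time = (tg$sample - 1) / br$eeg_rate,
    label = paste0(tg$direction, tg$angle))
  list(eeg = x, onsets = ons, truth = truth)
}
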