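#' Continuous multichannel EEG container
#'
#' @param data Channels-by-samples numeric matrix (microvolts).
#' @param rate Sampling rate in Hz.
#' @param channels Channel names (defaults to rownames of `data`).
#' @param bad Logical bad-channel mask (default all good).
#' @return An object of class `pep_cont`.
#' @export
continuous_eeg <- function(data, rate, channels = NULL, bad = NULL) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  channels <- channels %||% rownames(data) %||%
    paste0("ch", seq_len(nrow(data)))
  bad <- bad %||% rep(FALSE, nrow(data))
  stopifnot(length(channels) == nrow(data), length(bad) == nrow(data))
  structure(list(data = data, rate = rate, channels = channels, bad = bad),
            class = "pep_cont")
}

#' @noRd
as_continuous_eeg <- function(x) {
  if (inherits(x, "pep_cont")) return(x)
  stopf("expected a continuous_eeg object")
}

#' @export
print.pep_cont <- function(x, ...) {
  cat(sprintf("<continuous EEG> %d channels x %d samples @ %g Hz (%.1f s), %d bad\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              sum(x$bad)))
  invisible(x)
}

#' Multirate recording container
#'
#' Holds one simulated session: EEG at 512 Hz, 3-axis accelerometer at 50 Hz,
#' ground-truth event markers and the montage. `markers$sample` indexes the
#' EEG clock (1-based); `blocks` gives the first EEG sample of each block.
#'
#' @param eeg Channels-by-samples matrix, microvolts.
#' @param accel 3-by-samples matrix, m/s^2.
#' @param markers Data.frame with columns `sample`, `block`, `onset_time`
#'   (seconds from block start), `kind`, `direction`, `angle`.
#' @param montage Montage data.frame ([standard_montage()]).
#' @param eeg_rate,accel_rate Sampling rates in Hz.
#' @param blocks Integer vector of block start samples (EEG clock).
#' @param meta Optional list of provenance fields (seed, config).
#' @return An object of class `pep_recording`.
#' @export
recording <- function(eeg, accel, markers, montage, eeg_rate = 512,
                      accel_rate = 50, blocks = 1L, meta = list()) {
  stopifnot(is.matrix(eeg), is.matrix(accel), nrow(accel) == 3)
  if (nrow(eeg) != nrow(montage))
    stopf("eeg has %d channels but montage %d", nrow(eeg), nrow(montage))
  if (ncol(accel) != ceiling(ncol(eeg) * accel_rate / eeg_rate))
    stopf("accelerometer length inconsistent with EEG length")
  if (any(markers$sample < 1 | markers$sample > ncol(eeg)))
    stopf("marker sample indices outside recording")
  structure(list(eeg = eeg, accel = accel, markers = markers,
                 montage = montage, eeg_rate = eeg_rate,
                 accel_rate = accel_rate, blocks = as.integer(blocks),
                 meta = meta),
            class = "pep_recording")
}

#' @export
print.pep_recording <- function(x, ...) {
  tg <- sum(x$markers$kind == "target")
  cat(sprintf("<recording> %d ch x %.1f s @ %g Hz | %d blocks | %d targets, %d standards\n",
              nrow(x$eeg), ncol(x$eeg) / x$eeg_rate, x$eeg_rate,
              length(x$blocks), tg, nrow(x$markers) - tg))
  invisible(x)
}

#' Extract one block of a recording
#'
#' @param rec A [recording()].
#' @param block Block number.
#' @return A `pep_recording` covering only that block; marker samples are
#'   re-indexed to the block.
#' @export
recording_block <- function(rec, block) {
  nb <- length(rec$blocks)
  if (block < 1 || block > nb) stopf("block %d out of range", block)
  from <- rec$blocks[block]
  to <- if (block < nb) rec$blocks[block + 1] - 1L else ncol(rec$eeg)
  afrom <- floor((from - 1) * rec$accel_rate / rec$eeg_rate) + 1
  ato <- ceiling((to - from + 1) * rec$accel_rate / rec$eeg_rate) + afrom - 1
  ato <- min(ato, ncol(rec$accel))
  mk <- rec$markers[rec$markers$sample >= from & rec$markers$sample <= to, ,
                    drop = FALSE]
  mk$sample <- mk$sample - from + 1L
  acc <- rec$accel[, afrom:ato, drop = FALSE]
  # pad accel so the ceil-length invariant holds for the slice
  need <- ceiling((to - from + 1) * rec$accel_rate / rec$eeg_rate)
  if (ncol(acc) < need)
    acc <- cbind(acc, matrix(0, 3, need - ncol(acc)))
  recording(rec$eeg[, from:to, drop = FALSE], acc, mk, rec$montage,
            rec$eeg_rate, rec$accel_rate, blocks = 1L, meta = rec$meta)
}

#' Epoch container
#'
#' @param data Trials x channels x samples array (microvolts, 64 Hz).
#' @param labels Factor of condition labels (`rest`, `left5`, `left10`,
#'   `right5`, `right10`).
#' @param onsets Onset sample indices on the epoch clock's source recording
#'   (64 Hz, 1-based).
#' @param rate Sampling rate (64 Hz).
#' @param pre Number of pre-onset samples (4).
#' @param kept Logical mask of retained epochs.
#' @param reason Character rejection reason per epoch ("" if kept).
#' @param blocks Optional source-block id per epoch.
#' @return An object of class `pep_epochs`.
#' @export
epoch_set <- function(data, labels, onsets, rate = 64, pre = 4L,
                      kept = NULL, reason = NULL, blocks = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[1] == length(labels))
  n <- dim(data)[1]
  structure(list(data = data, labels = factor(labels), onsets = onsets,
                 rate = rate, pre = as.integer(pre),
                 kept = kept %||% rep(TRUE, n),
                 reason = reason %||% rep("", n),
                 blocks = blocks %||% rep(NA_integer_, n)),
            class = "pep_epochs")
}

#' @export
print.pep_epochs <- function(x, ...) {
  cat(sprintf("<epochs> %d trials x %d ch x %d samples @ %g Hz; kept %d/%d\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate,
              sum(x$kept), length(x$kept)))
  print(table(x$labels))
  invisible(x)
}

#' Subset an epoch set
#' @param x A [epoch_set()].
#' @param i Trial indices or logical mask.
#' @export
epochs_subset <- function(x, i) {
  epoch_set(x$data[i, , , drop = FALSE], x$labels[i], x$onsets[i], x$rate,
            x$pre, x$kept[i], x$reason[i], x$blocks[i])
}

#' Write a recording to a lossless native container
#'
#' Serializes the full recording (arrays, markers, montage, rates, metadata)
#' to a single file; `read_recording()` restores it bit-for-bit.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @export
write_recording <- function(rec, path) {
  saveRDS(unclass(rec), path, version = 3)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  x <- readRDS(path)
  recording(x$eeg, x$accel, x$markers, x$montage, x$eeg_rate, x$accel_rate,
            x$blocks, x$meta)
}
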