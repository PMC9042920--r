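# Minimal EDF+ (continuous) writer/reader for the simulated recordings:
# EEG channels at 512 Hz, 3 accelerometer channels at 50 Hz, and one
# annotation channel carrying the ground-truth movement markers as
# time-stamped annotation lists (TALs). Samples are quantized to 16 bits
# over a symmetric physical range; round trips are exact up to the
# quantization step.

#' @noRd
pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  sprintf(paste0("%-", width, "s"), x)
}

#' @noRd
num_field <- function(x, width) pad_field(format(x, digits = 8), width)

#' Write a recording to an EDF+ file
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param phys_range Physical range for the EEG channels, uV (symmetric).
#' @param accel_range Physical range for the accelerometer channels, m/s^2.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, phys_range = NULL, accel_range = NULL) {
  eeg <- rec$eeg; acc <- rec$accel
  phys_range <- phys_range %||% max(1e-6, max(abs(eeg)))
  accel_range <- accel_range %||% max(1e-6, max(abs(acc)))
  n_rec <- ceiling(ncol(eeg) / rec$eeg_rate)
  ns <- nrow(eeg) + nrow(acc) + 1L
  anno_len <- 120L                      # bytes per record / 2 = int samples
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field("X X X X", 80))
  wr(pad_field("Startdate 01-JAN-2026 X X X", 80))
  wr("01.01.26"); wr("00.00.00")
  wr(num_field(256 * (ns + 1), 8))
  wr(pad_field("EDF+C", 44))
  wr(num_field(n_rec, 8))
  wr(num_field(1, 8))
  wr(num_field(ns, 4))
  labels <- c(paste("EEG", rec$montage$name),
              paste("Accel", c("X", "Y", "Z")), "EDF Annotations")
  spr <- c(rep(rec$eeg_rate, nrow(eeg)), rep(rec$accel_rate, nrow(acc)),
           anno_len)
  pmin_ <- c(rep(-phys_range, nrow(eeg)), rep(-accel_range, nrow(acc)), -1)
  pmax_ <- c(rep(phys_range, nrow(eeg)), rep(accel_range, nrow(acc)), 1)
  for (l in labels) wr(pad_field(l, 16))
  for (i in seq_len(ns)) wr(pad_field("", 80))
  for (i in seq_len(ns)) wr(pad_field(c(rep("uV", nrow(eeg)),
                                        rep("m/s^2", nrow(acc)), "")[i], 8))
  for (v in pmin_) wr(num_field(v, 8))
  for (v in pmax_) wr(num_field(v, 8))
  for (i in seq_len(ns)) wr(num_field(-32768, 8))
  for (i in seq_len(ns)) wr(num_field(32767, 8))
  for (i in seq_len(ns)) wr(pad_field("", 80))
  for (v in spr) wr(num_field(v, 8))
  for (i in seq_len(ns)) wr(pad_field("", 32))
  # same affine convention the reader inverts: [-pr, pr] -> [-32768, 32767]
  digitize <- function(x, pr)
    as.integer(pmax(-32768, pmin(32767,
      round((x + pr) / (2 * pr) * 65535 - 32768))))
  mk <- rec$markers
  mk_time <- (mk$sample - 1) / rec$eeg_rate
  for (r in seq_len(n_rec)) {
    t0 <- r - 1
    i_e <- (t0 * rec$eeg_rate + 1):(t0 * rec$eeg_rate + rec$eeg_rate)
    i_a <- (t0 * rec$accel_rate + 1):(t0 * rec$accel_rate + rec$accel_rate)
    for (ch in seq_len(nrow(eeg))) {
      v <- rep(0, rec$eeg_rate)
      ok <- i_e <= ncol(eeg)
      v[ok] <- eeg[ch, i_e[ok]]
      writeBin(digitize(v, phys_range), con, size = 2, endian = "little")
    }
    for (ch in 1:3) {
      v <- rep(0, rec$accel_rate)
      ok <- i_a <= ncol(acc)
      v[ok] <- acc[ch, i_a[ok]]
      writeBin(digitize(v, accel_range), con, size = 2, endian = "little")
    }
    tal <- sprintf("+%d\x14\x14", t0)
    sel <- which(mk_time >= t0 & mk_time < t0 + 1)
    for (i in sel)
      tal <- paste0(tal, sprintf("+%.6f\x15%g\x14%s/%s/%g\x14",
                                 mk_time[i], 0, mk$kind[i],
                                 mk$direction[i], mk$angle[i]))
    raw_tal <- c(charToRaw(tal), as.raw(0))
    buf <- raw(2 * anno_len)
    buf[seq_along(raw_tal)] <- raw_tal
    writeBin(buf, con)
  }
  invisible(path)
}

#' Read an EDF+ file written by [write_edf()]
#'
#' @param path EDF+ file path.
#' @param montage Montage to attach (defaults to [standard_montage()]).
#' @return A [recording()]; the signal length is the padded whole-second
#'   length of the file.
#' @export
read_edf <- function(path, montage = standard_montage()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8)
  as.numeric(rd(8))                      # header bytes
  rd(44)
  n_rec <- as.numeric(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.numeric(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  is_anno <- labels == "EDF Annotations"
  sigs <- lapply(seq_len(ns), function(i)
    if (is_anno[i]) NULL else matrix(0, 1, n_rec * spr[i]))
  tal_raw <- raw(0)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (is_anno[i]) {
        tal_raw <- c(tal_raw, readBin(con, "raw", 2 * spr[i]))
      } else {
        d <- readBin(con, "integer", spr[i], size = 2, endian = "little")
        v <- (d - dmin_[i]) / (dmax_[i] - dmin_[i]) *
          (pmax_[i] - pmin_[i]) + pmin_[i]
        sigs[[i]][1, ((r - 1) * spr[i] + 1):(r * spr[i])] <- v
      }
    }
  }
  eeg_idx <- which(startsWith(labels, "EEG"))
  acc_idx <- which(startsWith(labels, "Accel"))
  eeg_rate <- spr[eeg_idx[1]] / rec_dur
  accel_rate <- spr[acc_idx[1]] / rec_dur
  eeg <- do.call(rbind, sigs[eeg_idx])
  acc <- do.call(rbind, sigs[acc_idx])
  rownames(eeg) <- sub("^EEG ", "", labels[eeg_idx])
  txt <- rawToChar(tal_raw[tal_raw != as.raw(0)], multiple = FALSE)
  pieces <- strsplit(txt, "\x14", fixed = TRUE)[[1]]
  markers <- list()
  i <- 1
  while (i <= length(pieces)) {
    p <- pieces[i]
    if (grepl("\x15", p)) {
      onset <- as.numeric(sub("\x15.*", "", p))
      ann <- if (i + 1 <= length(pieces)) pieces[i + 1] else ""
      f <- strsplit(ann, "/", fixed = TRUE)[[1]]
      if (length(f) == 3)
        markers[[length(markers) + 1]] <- data.frame(
          sample = round(onset * eeg_rate) + 1L, block = 1L,
          onset_time = onset, kind = f[1], direction = f[2],
          angle = as.numeric(f[3]), stringsAsFactors = FALSE)
      i <- i + 2
    } else i <- i + 1
  }
  markers <- if (length(markers)) do.call(rbind, markers) else
    data.frame(sample = integer(), block = integer(),
               onset_time = numeric(), kind = character(),
               direction = character(), angle = numeric())
  # pad the accelerometer to the ceil-length invariant
  need <- ceiling(ncol(eeg) * accel_rate / eeg_rate)
  if (ncol(acc) < need) acc <- cbind(acc, matrix(0, 3, need - ncol(acc)))
  recording(eeg, acc[, seq_len(need), drop = FALSE], markers,
            montage[match(rownames(eeg), montage$name), ],
            eeg_rate, accel_rate, blocks = 1L)
}
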