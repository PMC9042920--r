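#' Background EEG noise parameters
#'
#' The background is a sum of spatially mixed 1/f ("pink") sources projected
#' through random smooth head maps, an occipital 10 Hz rhythm with a slowly
#' varying envelope, and white sensor noise.
#'
#' @param rms Target mean per-channel RMS of the pink background, uV.
#' @param alpha_amp Amplitude of the 10 Hz occipital rhythm, uV (0 disables).
#' @param sensor_sd White sensor-noise SD, uV.
#' @param n_sources Number of pink-noise cortical sources.
#' @export
noise_params <- function(rms = 10, alpha_amp = 3, sensor_sd = 1,
                         n_sources = 32) {
  list(rms = rms, alpha_amp = alpha_amp, sensor_sd = sensor_sd,
       n_sources = n_sources)
}

# 1/f^exponent (power) noise via spectral shaping; `n` samples at `rate`
# Hz. The default exponent and low-frequency floor put a realistic share
# of the total power below 1 Hz (electrode drift and slow potentials),
# which the causal 1 Hz high-pass of the analysis chain removes.
#' @noRd
pink_noise <- function(n, rate, f_floor = 0.05, exponent = 2) {
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, seq_len(n - 1)) * rate / n
  f <- pmin(f, rate - f)                     # two-sided frequency axis
  shape <- pmax(f, f_floor)^(-exponent / 2)
  shape[1] <- 0                              # no DC
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x / sd(x)
}

# channels x samples background noise for one block
#' @noRd
synth_background <- function(n, montage, noise, rate) {
  nc <- nrow(montage)
  out <- matrix(0, nc, n)
  if (noise$rms > 0) {
    radius <- sqrt(sum(montage[1, c("x", "y", "z")]^2))
    centers <- matrix(rnorm(3 * noise$n_sources), ncol = 3)
    centers <- radius * centers / sqrt(rowSums(centers^2))
    centers[, 3] <- abs(centers[, 3])        # upper hemisphere
    A <- sapply(seq_len(noise$n_sources), function(s)
      sample(c(-1, 1), 1) * scalp_map(montage, centers[s, ], 50))
    S <- sapply(seq_len(noise$n_sources), function(s) pink_noise(n, rate))
    out <- A %*% t(S)
    out <- out * noise$rms / mean(sqrt(rowMeans(out^2)))
  }
  if (noise$alpha_amp > 0) {
    env <- 1 + 0.5 * sin(2 * pi * 0.2 * seq_len(n) / rate +
                           runif(1, 0, 2 * pi))
    osc <- sin(2 * pi * 10 * seq_len(n) / rate + runif(1, 0, 2 * pi))
    out <- out + outer(scalp_map(montage, scalp_point(-65, 0), 50),
                       noise$alpha_amp * env * osc)
  }
  if (noise$sensor_sd > 0)
    out <- out + matrix(rnorm(nc * n, 0, noise$sensor_sd), nc, n)
  out
}

#' Synthesize a continuous cockpit-EEG recording for a schedule
#'
#' Generates background noise block by block, plants the condition-specific
#' PEP template after every perturbation onset (and, optionally, a scaled
#' response after standards), simulates the accelerometer through
#' [synth_kinematics()], and assembles everything into a [recording()] with
#' ground-truth markers.
#'
#' @param schedule A `pep_schedule`.
#' @param template A [pep_template_spec()].
#' @param noise A [noise_params()].
#' @param kin [kinematics_params()].
#' @param montage Montage data.frame.
#' @param eeg_rate,accel_rate Sampling rates, Hz.
#' @param seed Integer seed; the same seed reproduces the recording exactly.
#' @return A [recording()].
#' @export
synth_eeg <- function(schedule, template = pep_template_spec(),
                      noise = noise_params(), kin = kinematics_params(),
                      montage = standard_montage(), eeg_rate = 512,
                      accel_rate = 50, seed = 1L) {
  kin_out <- synth_kinematics(schedule, kin, eeg_rate, accel_rate,
                              seed = seed + 1000L)
  blocks <- sort(unique(schedule$block))
  n_total <- round(sum(kin_out$durations) * eeg_rate)
  conds <- unique(schedule[schedule$kind == "target", c("direction", "angle")])
  tmpl <- list()
  for (i in seq_len(nrow(conds)))
    tmpl[[paste(conds$direction[i], conds$angle[i])]] <-
      pep_template_epoch(template, conds$direction[i], conds$angle[i],
                         montage, eeg_rate)
  std_tmpl <- if (template$standard_amp != 0)
    lapply(stats::setNames(c("left", "right"), c("left", "right")),
           function(d) pep_template_epoch(template, d, 1.5, montage,
                                          eeg_rate))
  else NULL
  eeg <- matrix(0, nrow(montage), n_total)
  markers <- list()
  with_seed(seed, {
    for (bi in seq_along(blocks)) {
      b <- blocks[bi]
      from <- kin_out$block_starts[bi]
      nb <- round(kin_out$durations[bi] * eeg_rate)
      bg <- synth_background(nb, montage, noise, eeg_rate)
      ev <- schedule[schedule$block == b, ]
      for (i in seq_len(nrow(ev))) {
        s0 <- round(ev$onset_time[i] * eeg_rate) + 1
        tm <- if (ev$kind[i] == "target")
          tmpl[[paste(ev$direction[i], ev$angle[i])]]
        else std_tmpl[[ev$direction[i]]]
        if (!is.null(tm)) {
          len <- min(ncol(tm), nb - s0 + 1)
          if (len > 0)
            bg[, s0:(s0 + len - 1)] <- bg[, s0:(s0 + len - 1)] +
              tm[, seq_len(len)]
        }
        markers[[length(markers) + 1]] <- data.frame(
          sample = from + s0 - 1L, block = b,
          onset_time = ev$onset_time[i], kind = ev$kind[i],
          direction = ev$direction[i], angle = ev$angle[i],
          stringsAsFactors = FALSE)
      }
      eeg[, from:(from + nb - 1)] <- bg
    }
  })
  rownames(eeg) <- montage$name
  markers <- do.call(rbind, markers)
  recording(eeg, kin_out$accel, markers, montage, eeg_rate, accel_rate,
            blocks = kin_out$block_starts,
            meta = list(seed = seed, template = template, noise = noise))
}

#' Convenience wrapper: schedule + kinematics + EEG for one synthetic subject
#'
#' @param config A [paradigm_config()]; its `seed` drives the schedule.
#' @inheritParams synth_eeg
#' @export
simulate_subject <- function(config = paradigm_config(),
                             template = pep_template_spec(),
                             noise = noise_params(),
                             kin = kinematics_params(),
                             montage = standard_montage(),
                             seed = config$seed) {
  schedule <- generate_schedule(config)
  synth_eeg(schedule, template, noise, kin, montage, seed = seed)
}

#' Inject synthetic artifacts into a recording
#'
#' Adds channel pops (step offsets), slow drifts (linear ramps), and
#' high-amplitude transient bursts at caller-specified locations; the
#' locations are returned so rejection and correction stages can be tested
#' against ground truth.
#'
#' @param rec A [recording()].
#' @param pops Data.frame with columns `channel`, `time` (s), `duration`
#'   (s), `amplitude` (uV); or `NULL`.
#' @param drifts Data.frame with columns `channel`, `time`, `duration`,
#'   `slope` (uV/s); or `NULL`.
#' @param bursts Data.frame with columns `time`, `duration`, `amplitude`
#'   (uV, applied to all channels as filtered noise); or `NULL`.
#' @param seed Seed for the burst noise.
#' @return A list with `recording` (modified) and `log` (data.frame of the
#'   injected artifacts).
#' @export
inject_artifacts <- function(rec, pops = NULL, drifts = NULL, bursts = NULL,
                             seed = 1L) {
  eeg <- rec$eeg
  n <- ncol(eeg)
  log <- list()
  span <- function(time, duration) {
    i0 <- max(1L, round(time * rec$eeg_rate) + 1L)
    i1 <- min(n, i0 + round(duration * rec$eeg_rate) - 1L)
    if (i1 < i0) NULL else i0:i1
  }
  for (i in seq_len(NROW(pops))) {
    idx <- span(pops$time[i], pops$duration[i])
    if (is.null(idx)) next
    eeg[pops$channel[i], idx] <- eeg[pops$channel[i], idx] +
      pops$amplitude[i]
    log[[length(log) + 1]] <- data.frame(type = "pop",
      channel = pops$channel[i], from = idx[1], to = idx[length(idx)])
  }
  for (i in seq_len(NROW(drifts))) {
    idx <- span(drifts$time[i], drifts$duration[i])
    if (is.null(idx)) next
    ramp <- drifts$slope[i] * (seq_along(idx) - 1) / rec$eeg_rate
    eeg[drifts$channel[i], idx] <- eeg[drifts$channel[i], idx] + ramp
    log[[length(log) + 1]] <- data.frame(type = "drift",
      channel = drifts$channel[i], from = idx[1], to = idx[length(idx)])
  }
  with_seed(seed, {
    for (i in seq_len(NROW(bursts))) {
      idx <- span(bursts$time[i], bursts$duration[i])
      if (is.null(idx)) next
      eeg[, idx] <- eeg[, idx] + matrix(
        rnorm(nrow(eeg) * length(idx), 0, bursts$amplitude[i]),
        nrow(eeg))
      log[[length(log) + 1]] <- data.frame(type = "burst", channel = NA,
        from = idx[1], to = idx[length(idx)])
    }
  })
  rec$eeg <- eeg
  list(recording = rec,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(type = character(), channel = integer(),
                    from = integer(), to = integer()))
}
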