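#' Design a causal Butterworth filter as second-order sections
#'
#' Computes the poles of the analog Butterworth prototype, applies the
#' low-pass/high-pass/band-pass frequency transform with bilinear-transform
#' prewarping, and pairs poles into second-order sections (SOS). SOS cascades
#' keep the order-4 band-pass (8 poles) numerically well conditioned at EEG
#' band edges that sit far below Nyquist.
#'
#' @param n Filter order (of the analog prototype; a band-pass of order `n`
#'   has `2n` poles).
#' @param freq Cutoff frequency in Hz (scalar for `"low"`/`"high"`, length-2
#'   band for `"pass"`). These are the -3 dB points.
#' @param fs Sampling rate in Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @return A numeric matrix with one row per section and columns
#'   `b0 b1 b2 a0 a1 a2` (`a0 = 1`).
#' @examples
#' sos <- butter_sos(4, c(1, 28), fs = 512, type = "pass")
#' abs(sos_freqz(sos, c(1, 28), fs = 512))  # ~ 1/sqrt(2) at the edges
#' @export
butter_sos <- function(n, freq, fs, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (any(freq <= 0) || any(freq >= fs / 2))
    stopf("cutoff frequencies must lie strictly inside (0, fs/2)")
  if (type == "pass" && (length(freq) != 2 || diff(freq) <= 0))
    stopf("band-pass needs an increasing length-2 band")
  W <- 2 * fs * tan(pi * freq / fs)          # prewarped analog frequencies
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # prototype poles, |p| = 1
  pa <- switch(type,
    low  = W * p,
    high = W / p,
    pass = {
      B <- W[2] - W[1]; W0 <- sqrt(W[1] * W[2])
      term <- p * B / 2
      c(term + sqrt(term^2 - W0^2), term - sqrt(term^2 - W0^2))
    })
  pd <- (2 * fs + pa) / (2 * fs - pa)        # bilinear transform
  bz <- switch(type, low = c(1, 2, 1), high = c(1, -2, 1), pass = c(1, 0, -1))
  tol <- 1e-9
  cplx <- pd[Im(pd) > tol]
  real <- sort(Re(pd[abs(Im(pd)) <= tol]))
  sec <- lapply(cplx, function(q) c(bz, 1, -2 * Re(q), abs(q)^2))
  if (length(real)) {
    if (length(real) %% 2 == 0) {
      for (i in seq(1, length(real), by = 2))
        sec <- c(sec, list(c(bz, 1, -(real[i] + real[i + 1]),
                             real[i] * real[i + 1])))
    } else {
      bz1 <- switch(type, low = c(1, 1, 0), high = c(1, -1, 0),
                    pass = c(1, 0, -1))
      for (r in real) sec <- c(sec, list(c(bz1, 1, -r, 0)))
    }
  }
  sos <- do.call(rbind, sec)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  fref <- switch(type, low = 0, high = fs / 2,
                 pass = fs / pi * atan(sqrt(prod(W)) / (2 * fs)))
  g <- abs(sos_freqz(sos, fref, fs))
  sos[1, 1:3] <- sos[1, 1:3] / g
  sos
}

#' Design a second-order IIR notch filter
#'
#' Standard constrained biquad notch: unit gain away from the notch, a true
#' zero on the unit circle at the notch frequency.
#'
#' @param freq Notch frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param q Quality factor; bandwidth is roughly `freq / q` Hz.
#' @return A 1 x 6 SOS matrix.
#' @export
notch_sos <- function(freq, fs, q = 35) {
  if (freq >= fs / 2) stopf("notch frequency must be below Nyquist")
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  sos <- matrix(c(1, -2 * cos(w0), 1, 1 + alpha, -2 * cos(w0), 1 - alpha),
                nrow = 1)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

#' Frequency response of an SOS cascade
#'
#' @param sos SOS matrix as returned by [butter_sos()].
#' @param f Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Complex response values, one per frequency.
#' @export
sos_freqz <- function(sos, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  H <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * z + sos[s, 3] * z^2
    den <- sos[s, 4] + sos[s, 5] * z + sos[s, 6] * z^2
    H <- H * num / den
  }
  unname(H)
}

#' Apply an SOS filter causally to a signal matrix
#'
#' Filters each row (channel) with a cascade of second-order sections in a
#' single causal pass. Explicit filter state makes chunked streaming and
#' whole-record processing bit-compatible.
#'
#' @param x Numeric vector or channels-by-samples matrix.
#' @param sos SOS matrix.
#' @param zi Optional state: `n_sections x 2` matrix per channel (a list for
#'   matrix input), e.g. from a previous call's `zf`.
#' @return A list with `y` (filtered data, same shape as `x`) and `zf`
#'   (final state, usable as `zi` for the next chunk).
#' @export
sos_filter <- function(x, sos, zi = NULL) {
  zero <- function() matrix(0, nrow(sos), 2)
  if (is.matrix(x)) {
    nc <- nrow(x)
    if (is.null(zi)) zi <- replicate(nc, zero(), simplify = FALSE)
    y <- x
    zf <- vector("list", nc)
    for (ch in seq_len(nc)) {
      r <- sosfilt_cpp(sos, x[ch, ], zi[[ch]])
      y[ch, ] <- r$y
      zf[[ch]] <- r$zf
    }
    list(y = y, zf = zf)
  } else {
    r <- sosfilt_cpp(sos, x, zi %||% zero())
    list(y = r$y, zf = r$zf)
  }
}

#' Remove power-line interference with a causal notch filter
#'
#' @param x A [continuous_eeg()] object.
#' @param freq Line frequency in Hz (default 50).
#' @param q Notch quality factor.
#' @param state Optional streaming state from a previous call.
#' @return The filtered object; with `state` supplied (even as `TRUE`), the
#'   final filter state is attached as attribute `"state"`.
#' @export
notch_filter <- function(x, freq = 50, q = 35, state = NULL) {
  x <- as_continuous_eeg(x)
  if (freq >= x$rate / 2) stopf("notch frequency %g >= Nyquist", freq)
  sos <- notch_sos(freq, x$rate, q)
  apply_sos_stage(x, sos, state)
}

#' Causal Butterworth band-pass filter
#'
#' Single forward pass (no zero-phase filtering), matching an online system
#' where future samples are unavailable.
#'
#' @param x A [continuous_eeg()] object.
#' @param band Length-2 pass band in Hz (default `c(1, 28)`).
#' @param order Butterworth prototype order (default 4).
#' @param state Optional streaming state.
#' @export
bandpass_causal <- function(x, band = c(1, 28), order = 4, state = NULL) {
  x <- as_continuous_eeg(x)
  if (length(band) != 2 || band[1] <= 0 || band[2] >= x$rate / 2 ||
      diff(band) <= 0)
    stopf("band must be increasing and inside (0, rate/2)")
  sos <- butter_sos(order, band, x$rate, "pass")
  apply_sos_stage(x, sos, state)
}

# shared stage plumbing: run SOS over the container, carry streaming state
#' @noRd
apply_sos_stage <- function(x, sos, state) {
  zi <- if (is.list(state)) state$zf else NULL
  r <- sos_filter(x$data, sos, zi)
  x$data <- r$y
  if (!is.null(state)) attr(x, "state") <- list(zf = r$zf)
  x
}

#' Decimate a recording to a lower rate with causal anti-alias filtering
#'
#' Applies a causal order-8 Butterworth low-pass at 80% of the target Nyquist
#' frequency, then keeps every `rate/target`-th sample (the first sample is
#' retained, so sample `k` of the output is sample `1 + (k-1)*factor` of the
#' input).
#'
#' @param x A [continuous_eeg()] object.
#' @param target Target rate in Hz; the input rate must be an integer
#'   multiple (512 -> 64 gives factor 8).
#' @param state Optional streaming state.
#' @export
downsample <- function(x, target = 64, state = NULL) {
  x <- as_continuous_eeg(x)
  factor <- x$rate / target
  if (factor != round(factor) || factor < 1)
    stopf("rate %g is not an integer multiple of target %g", x$rate, target)
  factor <- as.integer(factor)
  if (factor > 1L) {
    sos <- butter_sos(8, 0.8 * target / 2, x$rate, "low")
    zi <- if (is.list(state)) state$zf else NULL
    r <- sos_filter(x$data, sos, zi)
    phase <- if (is.list(state)) state$phase %||% 0L else 0L
    first <- ((factor - phase) %% factor) + 1L
    idx <- seq(first, ncol(r$y), by = factor)
    newphase <- (phase + ncol(r$y)) %% factor
    x$data <- r$y[, idx, drop = FALSE]
    if (!is.null(state))
      attr(x, "state") <- list(zf = r$zf, phase = newphase)
  }
  x$rate <- target
  x
}
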