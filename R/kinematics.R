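#' Kinematic parameters of the glider simulation
#'
#' Movements use trapezoidal (constant-acceleration) angular profiles.
#' Perturbations ramp to the target angle in `ramp_time` (split equally into
#' acceleration and deceleration), hold for `hold_time`, and return slowly
#' over `return_time`; standards tilt out and back over `standard_time`.
#' The accelerometer measures the tangential linear acceleration of a point
#' at `arm_radius` meters from the tilt axis, plus Gaussian sensor noise.
#'
#' @param arm_radius Lever arm of the accelerometer in meters.
#' @param noise_sd Per-axis accelerometer noise SD, m/s^2.
#' @param axis_gain Fraction of the tangential acceleration coupled into
#'   each of the 3 sensor axes (the tilt-tangential axis dominates).
#' @export
kinematics_params <- function(arm_radius = 0.25, noise_sd = 0.05,
                              axis_gain = c(0.2, 1, 0.1)) {
  list(arm_radius = arm_radius, noise_sd = noise_sd, axis_gain = axis_gain)
}

# Piecewise-constant angular acceleration (deg/s^2) for one block, sampled
# at `rate`. Trapezoid out-phase: +A for T/2 then -A for T/2 reaches the
# angle with zero end velocity; A = 4 * angle / T^2.
#' @noRd
block_alpha <- function(events, config, duration, rate) {
  n <- ceiling(duration * rate)
  alpha <- numeric(n)
  # drift-free discrete trapezoid: equal-length accelerate/decelerate
  # segments scaled so the discrete double integral hits the angle exactly
  move <- function(t0, angle, T) {
    nh <- max(1L, round(T / 2 * rate))
    seg <- c(rep(1, nh), rep(-1, nh))
    th_end <- tail(cumsum(cumsum(seg) / rate) / rate, 1)
    A <- angle / th_end
    i0 <- floor(t0 * rate) + 1
    i1 <- min(n, i0 + 2 * nh - 1)
    if (i1 >= i0)
      alpha[i0:i1] <<- alpha[i0:i1] + A * seg[seq_len(i1 - i0 + 1)]
  }
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    sgn <- if (ev$direction == "left") -1 else 1
    if (ev$kind == "target") {
      move(ev$onset_time, sgn * ev$angle, config$ramp_time)
      t_ret <- ev$onset_time + config$ramp_time + config$hold_time
      move(t_ret, -sgn * ev$angle, config$return_time)
    } else {
      half <- config$standard_time / 2
      move(ev$onset_time, sgn * ev$angle, half)
      move(ev$onset_time + half, -sgn * ev$angle, half)
    }
  }
  alpha
}

#' Simulate glider kinematics and accelerometer traces for a schedule
#'
#' @param schedule A `pep_schedule` (see [generate_schedule()]).
#' @param params [kinematics_params()].
#' @param eeg_rate Rate of the roll-angle trace, Hz (EEG clock).
#' @param accel_rate Accelerometer rate, Hz.
#' @param pad Extra seconds appended after the last movement of each block.
#' @param seed Seed for the sensor noise (`NULL` for noise-free).
#' @return A list with per-block vectors/matrices: `roll` (degrees, at
#'   `eeg_rate`), `accel` (3 x samples, m/s^2, at `accel_rate`),
#'   `durations` (s), and `block_starts` (first EEG sample of each block in
#'   the concatenated trace).
#' @export
synth_kinematics <- function(schedule, params = kinematics_params(),
                             eeg_rate = 512, accel_rate = 50, pad = 1.5,
                             seed = NULL) {
  config <- attr(schedule, "config") %||% paradigm_config()
  blocks <- sort(unique(schedule$block))
  if (!length(blocks)) blocks <- 1L   # eventless schedule: one quiet block
  rolls <- list(); accels <- list(); durs <- numeric(0)
  for (b in blocks) {
    ev <- schedule[schedule$block == b, ]
    if (nrow(ev)) {
      ends <- ev$onset_time + ifelse(ev$kind == "target",
        config$ramp_time + config$hold_time + config$return_time,
        config$standard_time)
      if (any(diff(ev$onset_time) < 0))
        stopf("block %d: unsorted events", b)
      if (any(ev$onset_time[-1] < ends[-length(ends)] - 1e-9))
        stopf("block %d: overlapping movement segments", b)
      dur <- ceiling(max(ends) + pad)
    } else dur <- ceiling(pad)
    alpha <- block_alpha(ev, config, dur, eeg_rate)
    roll_vel <- cumsum(alpha) / eeg_rate
    rolls[[length(rolls) + 1]] <- cumsum(roll_vel) / eeg_rate
    # tangential acceleration in m/s^2 at the accelerometer rate
    na <- ceiling(dur * accel_rate)
    idx <- pmin(length(alpha),
                floor((seq_len(na) - 1) * eeg_rate / accel_rate) + 1)
    tang <- params$arm_radius * alpha[idx] * pi / 180
    acc <- outer(params$axis_gain, tang)
    accels[[length(accels) + 1]] <- acc
    durs <- c(durs, dur)
  }
  roll <- unlist(rolls)
  accel <- do.call(cbind, accels)
  if (!is.null(seed))
    accel <- accel + with_seed(seed,
      matrix(rnorm(length(accel), 0, params$noise_sd), nrow = 3))
  starts <- cumsum(c(1, head(durs, -1) * eeg_rate))
  list(roll = roll, accel = accel, durations = durs,
       block_starts = as.integer(starts))
}
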