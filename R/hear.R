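#' Fit the high-variance electrode artifact removal (HEAR) state
#'
#' HEAR monitors a causal exponentially smoothed estimate of each channel's
#' variance and compares it with the variance observed on artifact-light
#' calibration data. Channels whose variance ratio exceeds the lower bound
#' are progressively blended toward a neighbor-weighted estimate; above the
#' upper bound they are replaced entirely.
#'
#' @param calibration A [continuous_eeg()] object (artifact-light).
#' @param montage Montage data.frame.
#' @param tau Smoothing time constant, seconds.
#' @param theta Variance-ratio bounds `c(theta_low, theta_high)` on the
#'   running-SD / calibration-SD score.
#' @param neighbors Optional [channel_neighbors()] list.
#' @return An object of class `pep_hear`.
#' @export
hear_fit <- function(calibration, montage, tau = 0.25, theta = c(2, 5),
                     neighbors = NULL) {
  calibration <- as_continuous_eeg(calibration)
  if (theta[1] >= theta[2]) stopf("theta_low must be below theta_high")
  csd <- apply(calibration$data, 1, sd)
  if (any(csd <= 0)) stopf("zero calibration variance on some channel")
  neighbors <- neighbors %||% channel_neighbors(montage)
  D <- montage_distances(montage)
  nc <- nrow(calibration$data)
  W <- matrix(0, nc, nc)
  for (i in seq_len(nc)) {
    w <- 1 / pmax(D[i, neighbors[[i]]], 1e-6)
    W[i, neighbors[[i]]] <- w / sum(w)
  }
  structure(list(calib_sd = csd, tau = tau, theta = theta, weights = W,
                 rate = calibration$rate),
            class = "pep_hear")
}

#' Apply HEAR correction to continuous data
#'
#' Fully causal: the running variance at sample t uses samples up to t only.
#' The neighbor estimate excludes channels that are themselves flagged
#' (blending weight above 0.5) at that sample; if no usable neighbor
#' remains, the sample passes through unchanged (with a warning).
#'
#' @param x A [continuous_eeg()] object at the state's rate.
#' @param state A `pep_hear` from [hear_fit()].
#' @param run Optional running-variance vector from a previous chunk (for
#'   streaming); when supplied, the final state is attached as attribute
#'   `"state"` of the result.
#' @return The corrected object.
#' @export
hear_apply <- function(x, state, run = NULL) {
  x <- as_continuous_eeg(x)
  alpha <- 1 / (state$tau * x$rate)
  X <- x$data
  nc <- nrow(X); n <- ncol(X)
  v0 <- if (is.list(run)) run$v else state$calib_sd^2
  V <- matrix(0, nc, n)
  for (ch in seq_len(nc)) {
    V[ch, ] <- stats::filter(alpha * X[ch, ]^2, 1 - alpha,
                             method = "recursive",
                             init = v0[ch])
  }
  score <- sqrt(V) / state$calib_sd
  P <- (score - state$theta[1]) / (state$theta[2] - state$theta[1])
  P[P < 0] <- 0
  P[P > 1] <- 1
  if (any(P > 0)) {
    U <- (P <= 0.5) * 1
    num <- state$weights %*% (X * U)
    den <- state$weights %*% U
    est <- X                       # fallback: pass through
    usable <- den > 1e-9
    est[usable] <- num[usable] / den[usable]
    if (any(P > 0 & !usable))
      warnf("HEAR: all neighbors flagged for some samples; passing through")
    x$data <- (1 - P) * X + P * est
  }
  if (!is.null(run))
    attr(x, "state") <- list(v = V[, n])
  x
}
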