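#' Perturbation-evoked potential template specification
#'
#' Defines the deterministic PEP waveform planted after every perturbation
#' onset. Components are Gaussian-windowed bumps in time with smooth scalp
#' weight maps:
#' \itemize{
#'   \item N1: frontocentral, negative, identical for all four perturbation
#'     conditions.
#'   \item P2: positive, lateralized toward the hemisphere of the
#'     perturbation direction (right map is the mirror of the left map).
#'   \item Late angle component: central, inside 0.50-0.63 s, with both
#'     amplitude and duration increasing with the tilt angle (the larger
#'     perturbation lasts longer and evokes a stronger sustained response).
#'   \item Late direction components: frontocentral, around 0.42-0.56 s and
#'     0.80-1.00 s, sign depending on direction.
#' }
#' Amplitudes are in microvolts; default values give a realistic single-trial
#' signal-to-noise ratio against the default 10 uV RMS background.
#'
#' @param n1_lat,n1_sigma,n1_amp N1 latency (s), temporal width (s),
#'   amplitude (uV).
#' @param p2_lat,p2_sigma,p2_amp P2 parameters; the P2 peak falls in the
#'   120-200 ms range.
#' @param late_angle_amp Named amplitudes (uV) of the central late component
#'   for the `"5"` and `"10"` degree conditions.
#' @param late_dir_amp Absolute amplitude (uV) of the direction-signed late
#'   frontocentral components (positive for right, negative for left).
#' @param standard_amp Amplitude scale of the response to standard 1.5-degree
#'   movements (0 = none, the default).
#' @param map_sigma Spatial Gaussian width of the scalp maps, mm.
#' @return A list of class `pep_template`.
#' @export
pep_template_spec <- function(n1_lat = 0.10, n1_sigma = 0.03, n1_amp = -8,
                              p2_lat = 0.16, p2_sigma = 0.03, p2_amp = 5,
                              late_angle_amp = c("5" = -2, "10" = 4),
                              late_dir_amp = 2.5,
                              standard_amp = 0, map_sigma = 45) {
  structure(list(n1_lat = n1_lat, n1_sigma = n1_sigma, n1_amp = n1_amp,
                 p2_lat = p2_lat, p2_sigma = p2_sigma, p2_amp = p2_amp,
                 late_angle_amp = late_angle_amp,
                 late_angle_lat = 0.565,
                 late_angle_sigma = c("5" = 0.04, "10" = 0.06),
                 late_dir_lat = c(0.49, 0.90),
                 late_dir_sigma = c(0.035, 0.05),
                 late_dir_amp = late_dir_amp,
                 standard_amp = standard_amp, map_sigma = map_sigma),
            class = "pep_template")
}

#' Evaluate the PEP template for one condition
#'
#' @param template A [pep_template_spec()].
#' @param direction `"left"` or `"right"`.
#' @param angle Tilt angle in degrees (5 or 10; 1.5 selects the standard
#'   response scaled by `standard_amp`).
#' @param montage Montage data.frame.
#' @param rate Sampling rate of the returned waveform, Hz.
#' @param duration Post-onset duration covered, seconds.
#' @return A channels x samples matrix (uV); sample 1 is the onset sample.
#' @export
pep_template_epoch <- function(template, direction, angle,
                               montage = standard_montage(), rate = 512,
                               duration = 1) {
  t <- seq(0, duration, by = 1 / rate)
  bump <- function(lat, sigma) exp(-(t - lat)^2 / (2 * sigma^2))
  mirror <- function(center) center * c(-1, 1, 1)
  fc <- scalp_point(18, 0)          # frontocentral (FCz neighborhood)
  cz <- scalp_point(0, 0)           # vertex
  p2_right <- scalp_point(6, 38)    # right centro-lateral focus
  sgn <- if (direction == "left") -1 else 1
  p2_center <- if (direction == "right") p2_right else mirror(p2_right)
  # component maps are shown/planted in average reference (zero mean over
  # the montage): physically, scalp potentials of a dipolar source have a
  # return path, and the recordings are CAR-referenced downstream
  avg_ref_map <- function(center) {
    m <- scalp_map(montage, center, template$map_sigma)
    m <- m - mean(m)
    m / max(abs(m))   # component amplitude = peak-channel amplitude
  }
  maps <- list(n1 = avg_ref_map(fc),
               p2 = avg_ref_map(p2_center),
               la = avg_ref_map(cz),
               ld = avg_ref_map(fc))
  out <- outer(maps$n1, template$n1_amp * bump(template$n1_lat,
                                               template$n1_sigma)) +
    outer(maps$p2, template$p2_amp * bump(template$p2_lat,
                                          template$p2_sigma))
  if (as.character(angle) %in% names(template$late_angle_amp)) {
    amp_a <- template$late_angle_amp[[as.character(angle)]]
    sig_a <- template$late_angle_sigma[[as.character(angle)]]
    out <- out + outer(maps$la, amp_a * bump(template$late_angle_lat,
                                             sig_a))
    for (j in seq_along(template$late_dir_lat))
      out <- out + outer(maps$ld,
        sgn * template$late_dir_amp * bump(template$late_dir_lat[j],
                                           template$late_dir_sigma[j]))
  } else {
    out <- out * template$standard_amp
  }
  rownames(out) <- montage$name
  out
}
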