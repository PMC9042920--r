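# 63-channel scalp montage on a spherical head model.
#
# Electrode positions follow the extended 10-10/10-5 layout: the outer
# circumferential ring sits 18 degrees above the ear-nasion plane, midline
# electrodes step in 18-degree increments from the vertex, and lateral
# electrodes are placed by great-circle interpolation between the midline
# electrode of a row and the ring electrode terminating that row. FT9/FT10,
# TP9/TP10 and PO9/PO10 lie on the ear-level circle. This reproduces the
# neighbor structure of a 63-channel actiCAP-style cap (reference CPz-free,
# i.e. CPz is a recorded channel here).

#' Standard 63-channel montage
#'
#' @param radius Head radius in mm (default 87.5).
#' @return A data.frame with columns `name`, `x`, `y`, `z` (mm; x right,
#'   y anterior, z up).
#' @examples
#' m <- standard_montage()
#' nrow(m)  # 63
#' @export
standard_montage <- function(radius = 87.5) {
  d2r <- pi / 180
  ring_incl <- 72 * d2r
  pt <- function(incl, az) c(sin(incl) * sin(az), sin(incl) * cos(az),
                             cos(incl))
  midline <- function(ap) pt(abs(ap) * d2r, if (ap >= 0) 0 else pi)
  ringpt <- function(az_deg, side, incl = ring_incl)
    pt(incl, side * az_deg * d2r)
  slerp <- function(a, b, f) {
    om <- acos(max(-1, min(1, sum(a * b))))
    if (om < 1e-12) return(a)
    (sin((1 - f) * om) * a + sin(f * om) * b) / sin(om)
  }
  rows <- list(
    # row name, midline AP angle (deg, + anterior), ring azimuth (deg from
    # nasion), odd/even columns present (steps of 1/4 toward the ring)
    Fp = list(ap = 72, az = 18, cols = c(4)),           # Fp1/Fp2 on the ring
    AF = list(ap = 54, az = 36, cols = c(2, 4)),        # AF3/4, AF7/8
    F  = list(ap = 36, az = 54, cols = c(1, 2, 3, 4)),  # F1..F8 + Fz
    FC = list(ap = 18, az = 72, cols = c(1, 2, 3, 4)),  # FC1..FT8
    C  = list(ap = 0,  az = 90, cols = c(1, 2, 3, 4)),  # C1..T8 + Cz
    CP = list(ap = -18, az = 108, cols = c(1, 2, 3, 4)),
    P  = list(ap = -36, az = 126, cols = c(1, 2, 3, 4)),
    PO = list(ap = -54, az = 144, cols = c(2, 4)),      # PO3/4, PO7/8
    O  = list(ap = -72, az = 162, cols = c(4))          # O1/O2 on the ring
  )
  colname <- function(row, step, side) {
    lateral <- list(
      F  = c("F1", "F3", "F5", "F7"),  FC = c("FC1", "FC3", "FC5", "FT7"),
      C  = c("C1", "C3", "C5", "T7"),  CP = c("CP1", "CP3", "CP5", "TP7"),
      P  = c("P1", "P3", "P5", "P7"),  PO = c(NA, "PO3", NA, "PO7"),
      AF = c(NA, "AF3", NA, "AF7"),    Fp = c(NA, NA, NA, "Fp1"),
      O  = c(NA, NA, NA, "O1"))
    nm <- lateral[[row]][step]
    if (side > 0 && !is.na(nm)) # right homologue: odd digit -> next even
      nm <- chartr("1357", "2468", nm)
    nm
  }
  names_out <- character(0); coords <- NULL
  add <- function(nm, v) {
    names_out <<- c(names_out, nm)
    coords <<- rbind(coords, v)
  }
  for (rn in names(rows)) {
    r <- rows[[rn]]
    mid <- midline(r$ap)
    if (rn %in% c("F", "FC", "C", "CP", "P", "O")) {
      zlab <- c(F = "Fz", FC = "FCz", C = "Cz", CP = "CPz", P = "Pz",
                O = "Oz")[rn]
      if (zlab != "FCz") add(zlab, mid)   # FCz omitted (63-channel cap)
    }
    for (side in c(-1, 1)) {
      ring <- ringpt(r$az, side)
      for (step in r$cols) {
        nm <- colname(rn, step, side)
        if (is.na(nm)) next
        add(nm, slerp(mid, ring, step / 4))
      }
    }
  }
  # ear-level electrodes (inclination 90 degrees)
  for (side in c(-1, 1)) {
    add(if (side < 0) "FT9" else "FT10", pt(pi / 2, side * 72 * d2r))
    add(if (side < 0) "TP9" else "TP10", pt(pi / 2, side * 108 * d2r))
    add(if (side < 0) "PO9" else "PO10", pt(pi / 2, side * 144 * d2r))
  }
  out <- data.frame(name = names_out,
                    x = radius * coords[, 1],
                    y = radius * coords[, 2],
                    z = radius * coords[, 3])
  rownames(out) <- NULL
  out
}

#' Read a montage from a tab-separated file
#'
#' The expected format is four named columns `name`, `x`, `y`, `z`
#' (positions in mm). The default montage ships as
#' `system.file("extdata", "montage_10_5.tsv", package = "pepasync")`.
#'
#' @param path Path to the TSV file.
#' @return A montage data.frame as from [standard_montage()].
#' @export
read_montage <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "x", "y", "z") %in% names(m)))
    stopf("montage file must have columns name, x, y, z")
  m[, c("name", "x", "y", "z")]
}

#' Spatial neighbors of each channel
#'
#' Neighborhoods are used by the bad-channel detector and the HEAR artifact
#' corrector: channels within `radius` mm, with at least `min_n` and at most
#' `max_n` nearest channels.
#'
#' @param montage Montage data.frame from [standard_montage()].
#' @param radius Neighborhood radius in mm.
#' @param min_n,max_n Bounds on the neighbor count.
#' @return A list (one integer vector of neighbor indices per channel).
#' @export
channel_neighbors <- function(montage, radius = 40, min_n = 3, max_n = 8) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  n <- nrow(pos)
  D <- as.matrix(stats::dist(pos))
  lapply(seq_len(n), function(i) {
    d <- D[i, ]; d[i] <- Inf
    ord <- order(d)
    k <- sum(d <= radius)
    k <- max(min_n, min(max_n, k))
    ord[seq_len(k)]
  })
}

#' @noRd
montage_distances <- function(montage) {
  as.matrix(stats::dist(as.matrix(montage[, c("x", "y", "z")])))
}

# Smooth scalp weight map: Gaussian in 3-D electrode distance around a
# center point given in montage coordinates (mm).
#' @noRd
scalp_map <- function(montage, center, sigma = 40) {
  pos <- as.matrix(montage[, c("x", "y", "z")])
  d2 <- colSums((t(pos) - center)^2)
  exp(-d2 / (2 * sigma^2))
}

# Named scalp locations (virtual points allowed, e.g. FCz) used by the PEP
# template: AP angle (deg) and lateral azimuth (deg, + right) on the sphere.
#' @noRd
scalp_point <- function(ap, az = 0, radius = 87.5) {
  d2r <- pi / 180
  incl <- sqrt((ap * d2r)^2 + (az * d2r)^2)  # small-angle great-circle combo
  phi <- atan2(az, if (ap == 0 && az == 0) 1 else ap)
  # direction: rotate from vertex toward (anterior if ap>0) and laterally
  v <- c(sin(incl) * sin(phi), sin(incl) * cos(phi), cos(incl))
  radius * v
}
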