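#' Oddball tilt paradigm configuration
#'
#' Defaults reproduce the study design: 6 blocks of 40 perturbations (10
#' repetitions of each direction x angle condition), 6-10 standard 1.5-degree
#' movements between consecutive perturbations, inter-perturbation intervals
#' of 9-15 s, a 2 s hold at the tilted position, and at most 2 successive
#' perturbations with identical direction and angle.
#'
#' @param n_blocks Number of experimental blocks.
#' @param reps_per_condition Repetitions of each (direction, angle) pair per
#'   block.
#' @param target_angles Perturbation tilt angles in degrees.
#' @param directions Movement directions.
#' @param standard_angle Standard (small movement) angle in degrees.
#' @param standards_between Allowed range of standard-movement counts between
#'   consecutive perturbations.
#' @param isi_range Inter-perturbation interval range in seconds.
#' @param hold_time Hold duration at the tilted position, seconds.
#' @param ramp_time Perturbation ramp duration, seconds.
#' @param return_time Slow return duration, seconds.
#' @param standard_time Total standard movement duration (out and back),
#'   seconds.
#' @param max_run_length Maximum number of successive identical-condition
#'   perturbations.
#' @param seed Integer seed for schedule generation.
#' @return A list of class `pep_paradigm`.
#' @export
paradigm_config <- function(n_blocks = 6, reps_per_condition = 10,
                            target_angles = c(5, 10),
                            directions = c("left", "right"),
                            standard_angle = 1.5,
                            standards_between = c(6, 10),
                            isi_range = c(9, 15), hold_time = 2,
                            ramp_time = 0.2, return_time = 1,
                            standard_time = 0.8, max_run_length = 2,
                            seed = 1L) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              reps_per_condition = as.integer(reps_per_condition),
              target_angles = target_angles, directions = directions,
              standard_angle = standard_angle,
              standards_between = as.integer(standards_between),
              isi_range = isi_range, hold_time = hold_time,
              ramp_time = ramp_time, return_time = return_time,
              standard_time = standard_time,
              max_run_length = as.integer(max_run_length),
              seed = as.integer(seed))
  cfg$targets_per_block <- cfg$reps_per_condition *
    length(target_angles) * length(directions)
  class(cfg) <- "pep_paradigm"
  cfg
}

# longest run of identical values
#' @noRd
max_run <- function(x) {
  if (!length(x)) return(0L)
  max(rle(x)$lengths)
}

#' Generate a randomized oddball event schedule
#'
#' Per block, target conditions are shuffled subject to the maximum-run
#' constraint, inter-perturbation intervals are drawn uniformly from the ISI
#' range, and the standard movements in each gap are placed in jittered,
#' non-overlapping slots. The number of standards per gap is drawn uniformly
#' from the configured range, truncated to what physically fits inside the
#' drawn interval given the movement durations.
#'
#' @param config A [paradigm_config()].
#' @return A data.frame of class `pep_schedule` with columns `block`,
#'   `onset_time` (s from block start), `kind` (`standard`/`target`),
#'   `direction`, `angle`; the config is attached as attribute `"config"`.
#' @export
generate_schedule <- function(config = paradigm_config()) {
  conds <- expand.grid(direction = config$directions,
                       angle = config$target_angles,
                       stringsAsFactors = FALSE)
  if (config$targets_per_block !=
      config$reps_per_condition * nrow(conds))
    stopf("targets_per_block is not reps x conditions")
  footprint <- config$ramp_time + config$hold_time + config$return_time
  slot <- config$standard_time + 0.05
  margin <- 0.3
  with_seed(config$seed, {
    blocks <- lapply(seq_len(config$n_blocks), function(b) {
      key <- rep(paste(conds$direction, conds$angle),
                 each = config$reps_per_condition)
      ok <- FALSE
      for (try in 1:1000) {
        ord <- sample(length(key))
        if (max_run(key[ord]) <= config$max_run_length) { ok <- TRUE; break }
      }
      if (!ok) stopf("could not satisfy run-length constraint")
      key <- key[ord]
      dirs <- rep(conds$direction, each = config$reps_per_condition)[ord]
      angs <- rep(conds$angle, each = config$reps_per_condition)[ord]
      nt <- length(key)
      isi <- runif(nt, config$isi_range[1], config$isi_range[2])
      onsets <- cumsum(isi)
      ev <- data.frame(block = b, onset_time = onsets, kind = "target",
                       direction = dirs, angle = angs,
                       stringsAsFactors = FALSE)
      # standards inside each gap (including the lead-in before target 1)
      std <- list()
      for (g in seq_len(nt)) {
        lo <- if (g == 1) 0.5 else onsets[g - 1] + footprint + margin
        hi <- onsets[g] - margin - config$standard_time
        span <- hi - lo + config$standard_time
        m_max <- min(config$standards_between[2], floor(span / slot))
        m_min <- min(config$standards_between[1], m_max)
        m <- if (m_max >= m_min && m_max >= 1) {
          cand <- seq(m_min, m_max)
          cand[sample.int(length(cand), 1)]
        } else 0L
        if (m < 1) next
        bounds <- seq(lo, hi + config$standard_time,
                      length.out = m + 1)
        starts <- bounds[-(m + 1)] +
          runif(m, 0, pmax(0, diff(bounds) - config$standard_time))
        std[[g]] <- data.frame(block = b, onset_time = starts,
                               kind = "standard",
                               direction = sample(config$directions, m,
                                                  replace = TRUE),
                               angle = config$standard_angle,
                               stringsAsFactors = FALSE)
      }
      out <- rbind(ev, do.call(rbind, std))
      out[order(out$onset_time), ]
    })
  })
  sched <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(block = integer(), onset_time = numeric(),
               kind = character(), direction = character(),
               angle = numeric(), stringsAsFactors = FALSE)
  rownames(sched) <- NULL
  class(sched) <- c("pep_schedule", "data.frame")
  attr(sched, "config") <- config
  sched
}

#' Check the invariants of a generated schedule
#'
#' Verifies per-block condition counts, the ISI bounds, strict ordering, the
#' run-length constraint and the standard/target angle correspondence.
#'
#' @param schedule A `pep_schedule`.
#' @return `TRUE` invisibly; errors describe any violated invariant.
#' @export
validate_schedule <- function(schedule) {
  config <- attr(schedule, "config")
  for (b in unique(schedule$block)) {
    sb <- schedule[schedule$block == b, ]
    if (is.unsorted(sb$onset_time, strictly = TRUE))
      stopf("block %d: onsets not strictly increasing", b)
    tg <- sb[sb$kind == "target", ]
    tab <- table(tg$direction, tg$angle)
    if (any(tab != config$reps_per_condition))
      stopf("block %d: unbalanced condition counts", b)
    isi <- diff(tg$onset_time)
    if (length(isi) && (min(isi) < config$isi_range[1] - 1e-9 ||
                        max(isi) > config$isi_range[2] + 1e-9))
      stopf("block %d: ISI outside range", b)
    if (max_run(paste(tg$direction, tg$angle)) > config$max_run_length)
      stopf("block %d: run-length constraint violated", b)
    if (any((sb$kind == "standard") != (sb$angle == config$standard_angle)))
      stopf("block %d: standard/angle mismatch", b)
  }
  invisible(TRUE)
}
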