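make_sched <- function(df, config = paradigm_config()) {
  class(df) <- c("pep_schedule", "data.frame")
  attr(df, "config") <- config
  df
}

test_that("a perturbation reaches its angle and holds for 2 s", {
  s <- make_sched(data.frame(block = 1, onset_time = 10, kind = "target",
                             direction = "right", angle = 10,
                             stringsAsFactors = FALSE))
  k <- synth_kinematics(s)
  cfg <- paradigm_config()
  hold <- k$roll[round((10 + cfg$ramp_time + 0.01) * 512):
                   round((10 + cfg$ramp_time + cfg$hold_time - 0.01) * 512)]
  expect_true(all(abs(hold - 10) < 1e-6))
  expect_lt(abs(tail(k$roll, 1)), 1e-6)        # returns to balance
})

test_that("noise-free accelerometer is zero without events", {
  s <- make_sched(data.frame(block = integer(), onset_time = numeric(),
                             kind = character(), direction = character(),
                             angle = numeric(), stringsAsFactors = FALSE))
  k <- synth_kinematics(s, seed = NULL)
  expect_identical(max(abs(k$accel)), 0)
})

test_that("target peak acceleration exceeds any standard peak", {
  s <- make_sched(data.frame(block = 1,
                             onset_time = c(10, 20),
                             kind = c("standard", "target"),
                             direction = c("left", "right"),
                             angle = c(1.5, 5), stringsAsFactors = FALSE))
  k <- synth_kinematics(s, seed = NULL)
  mag <- sqrt(colSums(k$accel^2))
  std_peak <- max(mag[(9 * 50):(12 * 50)])
  tgt_peak <- max(mag[(19 * 50):(21 * 50)])
  expect_gt(tgt_peak, 5 * std_peak)
})

test_that("overlapping movements raise a schedule error", {
  s <- make_sched(data.frame(block = 1, onset_time = c(10, 10.5),
                             kind = c("target", "target"),
                             direction = c("left", "right"),
                             angle = c(5, 10), stringsAsFactors = FALSE))
  expect_error(synth_kinematics(s), "overlap")
})

test_that("onset detection recovers every perturbation within 40 ms", {
  rec <- fx_recording()
  sched <- generate_schedule(paradigm_config(n_blocks = 2,
                                             reps_per_condition = 3,
                                             seed = 7))
  for (b in 1:2) {
    br <- recording_block(rec, b)
    ons <- detect_onsets(br$accel, br$accel_rate)
    tg <- br$markers[br$markers$kind == "target", ]
    expect_identical(nrow(ons), nrow(tg))
    err <- ons$time - (tg$sample - 1) / br$eeg_rate
    expect_lt(max(abs(err)), 0.040)
  }
})

test_that("marker samples align with the accelerometer ramp within one 50 Hz sample", {
  rec <- fx_recording()
  br <- recording_block(rec, 1)
  tg <- br$markers[br$markers$kind == "target", ]
  mag <- sqrt(colSums(br$accel^2))
  noise_ceiling <- quantile(mag, 0.95) * 2
  for (i in seq_len(nrow(tg))) {
    t_marker <- (tg$sample[i] - 1) / br$eeg_rate
    a0 <- floor(t_marker * br$accel_rate) + 1
    # the ramp must have started by one accelerometer sample after the marker
    expect_gt(max(mag[a0:(a0 + 2)]), noise_ceiling)
    expect_lt(max(mag[(a0 - 3):(a0 - 1)]), noise_ceiling)
  }
})

test_that("detected onsets respect the 5 s minimum separation", {
  set.seed(8)
  acc <- matrix(rnorm(3 * 500, 0, 0.01), 3)
  acc[2, c(100, 120, 400)] <- 5                 # bursts 0.4 s apart then 5.6 s
  ons <- detect_onsets(acc, 50, threshold = 1)
  expect_identical(nrow(ons), 2L)
  expect_gte(min(diff(ons$time)), 5)
})
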