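# Shared fixtures, built once per test run and cached in this environment.
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# Small two-block recording at default SNR (schedule seeds fixed).
fx_recording <- function() fx_get("recording", function() {
  simulate_subject(paradigm_config(n_blocks = 2, reps_per_condition = 3,
                                   seed = 7), seed = 11)
})

fx_prep <- function() fx_get("prep", function() {
  fit_preprocessor(fx_recording(), calibration_blocks = 1:2)
})

# Onset-aligned high-SNR epochs built directly from the template (epoch
# geometry 4 + 64 samples at 64 Hz), bypassing the continuous simulation;
# used by classifier-level tests.
fx_template_epochs <- function(n_per_class = 20, noise_sd = 1, seed = 5,
                               include_rest = TRUE) {
  montage <- standard_montage()
  spec <- pep_template_spec()
  conds <- expand.grid(direction = c("left", "right"), angle = c(5, 10),
                       stringsAsFactors = FALSE)
  tmpl <- lapply(seq_len(nrow(conds)), function(i) {
    tm <- pep_template_epoch(spec, conds$direction[i], conds$angle[i],
                             montage, rate = 64)
    cbind(matrix(0, nrow(tm), 4), tm[, 1:64])
  })
  labels <- rep(paste0(conds$direction, conds$angle), each = n_per_class)
  if (include_rest) labels <- c(labels, rep("rest", n_per_class))
  n <- length(labels)
  dat <- array(0, c(n, 63, 68))
  set.seed(seed)
  for (i in seq_len(n)) {
    base <- matrix(rnorm(63 * 68, 0, noise_sd), 63, 68)
    ci <- match(labels[i], paste0(conds$direction, conds$angle))
    if (!is.na(ci)) base <- base + tmpl[[ci]]
    dat[i, , ] <- base
  }
  epoch_set(dat, labels, onsets = seq_len(n) * 500L, rate = 64, pre = 4L)
}

fx_hisnr_epochs <- function() fx_get("hisnr", function() fx_template_epochs())

# Decoder trained on the high-SNR template epochs.
fx_decoder <- function() fx_get("decoder", function() {
  pep_decoder(fx_hisnr_epochs(), k_s = 4, k_t = 4, fisher_k = 100,
              cost = 10, seed = 3)
})

# Full end-to-end run of one synthetic subject at default SNR
# (6 blocks x 24 perturbations; blocks 1-4 calibrate, 5 tunes, 6
# validates). The intermediate objects are kept so several suites can
# probe the same run.
fx_e2e <- function() fx_get("e2e", function() {
  cfg <- pipeline_config(
    paradigm = paradigm_config(n_blocks = 6, reps_per_condition = 6,
                               seed = 1), seed = 1)
  rec <- simulate_subject(cfg$paradigm, cfg$template, cfg$noise, cfg$kin,
                          seed = cfg$seed)
  prep <- fit_preprocessor(rec, cfg$partitions$calibration)
  sets <- list()
  for (b in cfg$partitions$calibration) {
    pb <- preprocess_block(prep, rec, b)
    lab <- pepasync:::label_onsets(pb$onsets, pb$truth, 64)
    ok <- !is.na(lab)
    sets[[length(sets) + 1]] <-
      extract_epochs(pb$eeg, pb$onsets$sample[ok], lab[ok],
                     block = rep(b, sum(ok)))
  }
  epochs <- reject_epochs(pepasync:::epochs_bind(sets))
  decoder <- pep_decoder(epochs_subset(epochs, epochs$kept), seed = 1)
  pt <- preprocess_block(prep, rec, cfg$partitions$tuning)
  opt <- optimize_threshold(decoder, pt$eeg, pt$truth$time)
  det <- stream_classify(decoder, pt$eeg, threshold = opt$threshold,
                         label = FALSE)
  lag <- estimate_time_lag(det$time, pt$truth$time)
  decoder <- tune_decoder(decoder, opt$threshold, lag$mean,
                          cfg$partitions$tuning)
  pv <- preprocess_block(prep, rec, cfg$partitions$validation)
  result <- validate_async(decoder, pv$eeg, pv$truth,
                           validation_block = cfg$partitions$validation)
  list(cfg = cfg, prep = prep, epochs = epochs, decoder = decoder,
       tuning = pt, opt = opt, lag = lag, validation_block = pv,
       result = result)
})
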