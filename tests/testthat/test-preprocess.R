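test_that("a white-noise channel in a smooth recording is flagged bad", {
  m <- standard_montage()
  set.seed(21)
  src <- matrix(rnorm(8 * 2000), 8)
  mix <- sapply(1:8, function(i)
    pepasync:::scalp_map(m, unlist(m[sample(63, 1), c("x", "y", "z")]), 60))
  dat <- mix %*% src + matrix(rnorm(63 * 2000, 0, 0.05), 63)
  dat[17, ] <- rnorm(2000)                  # independent noise channel
  bad <- detect_bad_channels(continuous_eeg(dat, 64), m)
  expect_true(bad[17])
  expect_lt(sum(bad), 5)
})

test_that("identical channels are never flagged and clean recordings have none", {
  m <- standard_montage()
  dat <- matrix(rep(rnorm(500), each = 63), 63, byrow = FALSE)
  expect_true(all(!detect_bad_channels(continuous_eeg(dat, 64), m)))
  expect_identical(sum(fx_prep()$bad), 0L)
})

test_that("CAR zeroes the good-channel mean and preserves channel differences", {
  set.seed(2)
  x <- continuous_eeg(matrix(rnorm(63 * 200), 63), 64)
  x$bad[5] <- TRUE
  y <- apply_car(x)
  expect_lt(max(abs(colMeans(y$data[!y$bad, ]))), 1e-9)
  expect_equal(y$data[2, ] - y$data[3, ], x$data[2, ] - x$data[3, ],
               tolerance = 1e-9)
  same <- continuous_eeg(matrix(rep(rnorm(100), each = 4), 4), 64)
  expect_lt(max(abs(apply_car(same)$data)), 1e-12)
})

test_that("interpolation reconstructs a linear field and uses convex weights", {
  m <- standard_montage()
  field <- 0.02 * m$y + 0.01 * m$x           # linearly varying over scalp
  x <- continuous_eeg(matrix(rep(field, 50), 63), 64)
  x$bad[10] <- TRUE
  y <- interpolate_channels(x, m)
  err <- abs(y$data[10, 1] - field[10])
  expect_lt(err, 0.1 * diff(range(field)))
  expect_equal(y$data[-10, ], x$data[-10, ])  # good channels untouched
  expect_identical(interpolate_channels(continuous_eeg(x$data, 64), m)$data,
                   x$data)                    # no bad channels: identity
})

test_that("epoch geometry follows the 4 + 64 sample convention", {
  x <- continuous_eeg(matrix(seq_len(2 * 4000), 2, byrow = TRUE), 64)
  ep <- extract_epochs(x, onsets = 1000L, labels = "left5")
  expect_identical(dim(ep$data), c(2L, 2L, 68L))
  expect_equal(ep$data[1, 1, ], 996:1063)       # perturbation epoch
  expect_equal(ep$data[2, 1, ], 996:1063 - 448) # rest epoch 7 s earlier
  # onsets near the edges are skipped and logged
  ep2 <- extract_epochs(x, onsets = c(3L, 1000L, 3999L), labels =
                          c("left5", "left5", "left5"), rest = FALSE)
  expect_identical(dim(ep2$data)[1], 1L)
  expect_identical(attr(ep2, "skipped"), c(1L, 3L))
  # n onsets away from edges give n perturbation + n rest epochs
  ep3 <- extract_epochs(x, onsets = c(600L, 1200L, 1800L),
                        labels = rep("right10", 3))
  expect_identical(dim(ep3$data)[1], 6L)
  expect_identical(sum(ep3$labels == "rest"), 3L)
})

test_that("epoch rejection flags amplitude violations with the right reason", {
  set.seed(4)
  dat <- array(rnorm(40 * 3 * 68), c(40, 3, 68))
  dat[7, 2, 30] <- 500
  ep <- epoch_set(dat, rep(c("left5", "rest"), 20), seq_len(40), 64, 4)
  out <- reject_epochs(ep)
  expect_false(out$kept[7])
  expect_identical(out$reason[7], "amplitude")
})

test_that("identical-distribution Gaussian epochs pass the statistical criteria", {
  set.seed(11)
  frac <- replicate(5, {
    dat <- array(rnorm(60 * 4 * 68), c(60, 4, 68))
    ep <- epoch_set(dat, rep("rest", 60), seq_len(60), 64, 4)
    mean(!reject_epochs(ep)$kept)
  })
  expect_lt(mean(frac), 0.05)   # about the false-positive rate of a 4 SD rule
})

test_that("clean simulated recordings lose fewer than 19% of trials", {
  rec <- fx_recording()
  prep <- fx_prep()
  sets <- list()
  for (b in 1:2) {
    pb <- preprocess_block(prep, rec, b)
    lab <- pepasync:::label_onsets(pb$onsets, pb$truth, 64)
    sets[[b]] <- extract_epochs(pb$eeg, pb$onsets$sample, lab,
                                block = rep(b, nrow(pb$onsets)))
  }
  ep <- reject_epochs(pepasync:::epochs_bind(sets))
  expect_lt(mean(!ep$kept), 0.19)
})

test_that("the online preprocessing entry point exposes no rejection stage", {
  out <- preprocess_block(fx_prep(), fx_recording(), 2)
  expect_named(out, c("eeg", "onsets", "truth"))
  expect_null(out$kept)
  expect_false(any(grepl("reject", names(out))))
  # and the continuous output has full length (no samples dropped)
  br <- recording_block(fx_recording(), 2)
  expect_identical(ncol(out$eeg$data), ncol(br$eeg) %/% 8L)
})
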