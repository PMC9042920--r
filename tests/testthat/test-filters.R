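test_that("band-pass design hits the -3 dB edges and matches an independent design", {
  sos <- butter_sos(4, c(1, 28), 512, "pass")
  edges <- 20 * log10(abs(sos_freqz(sos, c(1, 28), 512)))
  expect_true(all(abs(edges - (-3.0103)) < 0.5))
  bt <- signal::butter(4, c(1, 28) / 256, "pass")
  f <- c(0.5, 1, 2, 5, 10, 20, 28, 30, 50, 100)
  w <- exp(1i * pi * f / 256)
  href <- abs(vapply(w, function(z)
    sum(bt$b * z^(0:(length(bt$b) - 1))) /
      sum(bt$a * z^(0:(length(bt$a) - 1))), complex(1)))
  expect_lt(max(abs(abs(sos_freqz(sos, f, 512)) - href)), 1e-4)
})

test_that("causal filtering has zero pre-impulse response and no zero-phase pass", {
  sos <- butter_sos(4, c(1, 28), 512, "pass")
  x <- numeric(256); x[100] <- 1
  y <- sos_filter(x, sos)$y
  expect_identical(max(abs(y[1:99])), 0)
  expect_gt(max(abs(y[100:256])), 0)
})

test_that("notch filter suppresses 50 Hz and passes 10 Hz", {
  sos <- notch_sos(50, 512)
  expect_equal(abs(sos_freqz(sos, 50, 512)), 0, tolerance = 1e-12)
  expect_gt(abs(sos_freqz(sos, 10, 512)), 0.99)
  t <- seq(0, 4, by = 1 / 512)
  x <- continuous_eeg(matrix(sin(2 * pi * 50 * t), 1), 512)
  y <- notch_filter(x, 50)
  settled <- y$data[1, 1537:length(t)]          # after 3 s settling
  expect_lt(sqrt(mean(settled^2)) / sqrt(0.5), 0.05)
  z <- notch_filter(continuous_eeg(matrix(0, 1, 100), 512))
  expect_identical(max(abs(z$data)), 0)
  expect_error(notch_filter(x, 300), "Nyquist")
})

test_that("band-pass removes DC and rejects invalid bands", {
  x <- continuous_eeg(matrix(5, 1, 2048), 512)
  y <- bandpass_causal(x)
  expect_lt(max(abs(y$data[1, 1500:2048])), 0.05)
  expect_error(bandpass_causal(x, band = c(28, 1)), "band")
  expect_error(bandpass_causal(x, band = c(0, 28)), "band")
})

test_that("downsampling decimates by 8 with a causal anti-alias filter", {
  x <- continuous_eeg(matrix(rnorm(5120), 1), 512)
  y <- downsample(x, 64)
  expect_identical(ncol(y$data), 640L)
  expect_identical(y$rate, 64)
  # one 64 Hz sample step is exactly 15.625 ms
  expect_equal(1 / y$rate * 1000, 15.625)
  # a 5 Hz tone survives with < 2% amplitude change
  t <- seq(0, 20 - 1 / 512, by = 1 / 512)
  s <- continuous_eeg(matrix(sin(2 * pi * 5 * t), 1), 512)
  d <- downsample(s, 64)$data[1, ]
  d <- d[200:length(d)]                          # skip the transient
  expect_lt(abs(max(d) - 1), 0.02)
  expect_error(downsample(continuous_eeg(matrix(0, 1, 10), 512), 60),
               "integer multiple")
})

test_that("SOS filtering is streaming-equivalent and downsample carries phase", {
  sos <- butter_sos(4, c(1, 28), 512, "pass")
  x <- matrix(rnorm(3 * 1000), 3)
  whole <- sos_filter(x, sos)$y
  a <- sos_filter(x[, 1:333, drop = FALSE], sos)
  b <- sos_filter(x[, 334:1000, drop = FALSE], sos, a$zf)
  expect_equal(cbind(a$y, b$y), whole, tolerance = 1e-12)
  xc <- continuous_eeg(matrix(rnorm(4096), 1), 512)
  whole_d <- downsample(xc, 64)$data
  c1 <- continuous_eeg(xc$data[, 1:1000, drop = FALSE], 512)
  c2 <- continuous_eeg(xc$data[, 1001:4096, drop = FALSE], 512)
  d1 <- downsample(c1, 64, state = TRUE)
  d2 <- downsample(c2, 64, state = attr(d1, "state"))
  expect_equal(cbind(d1$data, d2$data), whole_d, tolerance = 1e-12)
})
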