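test_that("grand averages reduce correctly, including subject weighting", {
  dat <- array(rnorm(6 * 2 * 10), c(6, 2, 10))
  ep <- epoch_set(dat, rep("left5", 6), 1:6, 64, 4)
  single <- epochs_subset(ep, 1)
  expect_equal(grand_average(single)$left5, dat[1, , ])
  # unbalanced subjects: subject-weighted differs from trial-pooled
  subj <- c(1, 1, 1, 1, 1, 2)
  ga_w <- grand_average(ep, subject = subj)$left5
  ga_p <- grand_average(ep)$left5
  manual <- (apply(dat[1:5, , ], c(2, 3), mean) + dat[6, , ]) / 2
  expect_equal(ga_w, manual)
  expect_gt(max(abs(ga_w - ga_p)), 1e-9)
})

test_that("signed r2 has the right extremes, antisymmetry and affine invariance", {
  dat_a <- array(1, c(4, 2, 5))
  dat_b <- array(-1, c(4, 2, 5))
  expect_equal(signed_r2(dat_a, dat_b), matrix(1, 2, 5))
  expect_equal(signed_r2(dat_b, dat_a), matrix(-1, 2, 5))
  set.seed(12)
  a <- array(rnorm(30 * 2 * 5), c(30, 2, 5))
  b <- array(rnorm(30 * 2 * 5), c(30, 2, 5))
  r <- signed_r2(a, b)
  expect_lt(max(abs(r)), 0.3)                  # identical distributions: ~0
  expect_equal(signed_r2(b, a), -r, tolerance = 1e-12)
  expect_equal(signed_r2(a * 3 + 2, b * 3 + 2), r, tolerance = 1e-12)
})

test_that("interval means use the sample-snapping convention", {
  dat <- array(0, c(1, 1, 68))
  dat[1, 1, ] <- seq_len(68)
  ep <- epoch_set(dat, "left5", 1L, 64, 4)
  # [0.5, 0.63] s at 64 Hz covers post-onset samples 32..40
  idx <- pepasync:::interval_samples(c(0.5, 0.63), 64, 4, 68)
  expect_identical(idx, (4 + 1 + 32):(4 + 1 + 40))
  expect_equal(interval_means(ep, c(0.5, 0.63))[1, 1], mean(37:45))
  # a single-sample interval returns that sample
  expect_equal(interval_means(ep, c(10 / 64, 10 / 64))[1, 1], 15)
  # constant epochs give the constant
  cst <- epoch_set(array(7, c(2, 3, 68)), c("a", "b"), 1:2, 64, 4)
  expect_true(all(interval_means(cst, c(0.1, 0.9)) == 7))
})

test_that("Wilcoxon interval tests report the Bonferroni family of 252", {
  set.seed(3)
  dat <- array(rnorm(2 * 12 * 63 * 68), c(24, 63, 68))
  a <- epoch_set(dat[1:12, , ], rep("right10", 12), 1:12, 64, 4)
  b <- epoch_set(dat[13:24, , ], rep("right5", 12), 13:24, 64, 4)
  res <- wilcoxon_interval_test(a, b, default_intervals()$angle)
  expect_identical(nrow(res), 252L)
  expect_identical(attr(res, "n_comparisons"), 252)
  expect_equal(res$p_adj, pmin(1, 252 * res$p), tolerance = 1e-12)
  expect_identical(res$significant, res$p_adj < 0.05)
  # the printed example: raw p of 1e-4 adjusts to 0.0252, significant
  expect_lt(252 * 1e-4, 0.05)
  # identical trial sets: nothing significant
  same <- wilcoxon_interval_test(a, a, default_intervals()$angle)
  expect_false(any(same$significant))
  expect_error(wilcoxon_interval_test(epochs_subset(a, 1:3), b,
                                      default_intervals()$angle),
               "trials")
})

test_that("a planted central offset is recovered in the late angle window", {
  m <- standard_montage()
  target <- which(m$name %in% c("C1", "Cz", "C2"))
  hits <- replicate(3, {
    seed <- sample.int(1e6, 1)
    set.seed(seed)
    n <- 60
    base <- array(rnorm(2 * n * 63 * 68, 0, 2), c(2 * n, 63, 68))
    idx <- pepasync:::interval_samples(c(0.5, 0.63), 64, 4, 68)
    base[1:n, target, idx] <- base[1:n, target, idx] + 3
    a <- epoch_set(base[1:n, , ], rep("right10", n), 1:n, 64, 4)
    b <- epoch_set(base[(n + 1):(2 * n), , ], rep("right5", n),
                   1:n, 64, 4)
    res <- wilcoxon_interval_test(a, b, default_intervals()$angle)
    flagged <- res$channel[res$significant & res$interval == "late"]
    identical(sort(flagged), sort(target)) &&
      !any(res$significant & res$interval != "late")
  })
  expect_gte(sum(hits), 2)
})
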