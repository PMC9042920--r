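# exhaustive maximum-matching oracle for small instances
max_matching_tp <- function(detections, onsets, window = 2) {
  feas <- lapply(detections, function(d)
    which(d - onsets > 0 & d - onsets <= window))
  best <- 0
  recurse <- function(i, used, tp) {
    if (tp + (length(detections) - i + 1) <= best) return()
    if (i > length(detections)) { best <<- max(best, tp); return() }
    recurse(i + 1, used, tp)                    # leave detection i as FP
    for (j in setdiff(feas[[i]], used))
      recurse(i + 1, c(used, j), tp + 1)
  }
  recurse(1, integer(0), 0)
  best
}

test_that("greedy matching attains the maximum TP count on random instances", {
  set.seed(17)
  for (rep in 1:500) {
    n_on <- sample(0:5, 1)
    n_det <- sample(0:6, 1)
    onsets <- sort(runif(n_on, 0, 30))
    detections <- sort(runif(n_det, 0, 32))
    m <- match_detections(detections, onsets)
    expect_identical(m$tp, as.integer(max_matching_tp(detections, onsets)))
    expect_identical(m$tp + m$fp, n_det)
    expect_identical(m$tp + m$fn, n_on)
  }
})

test_that("matching handles the boundary cases of the spec", {
  onsets <- c(10, 20, 30)
  exact <- match_detections(onsets + 0.5, onsets)
  expect_identical(c(exact$tp, exact$fp, exact$fn), c(3L, 0L, 0L))
  lone <- match_detections(15, c(10, 20))     # 5 s from the first onset
  expect_identical(c(lone$tp, lone$fp), c(0L, 1L))
  # boundary: exactly 2 s counts, 0 s does not
  expect_identical(match_detections(12, 10)$tp, 1L)
  expect_identical(match_detections(10, 10)$tp, 0L)
})

test_that("precision, recall and F1 follow the printed formulas", {
  out <- f1_from_counts(2, 1, 1)
  expect_equal(out$precision, 2 / 3)
  expect_equal(out$recall, 2 / 3)
  expect_equal(out$f1, 4 / 6)
  expect_equal(f1_from_counts(5, 0, 0)$f1, 1)
  expect_equal(suppressWarnings(f1_from_counts(0, 3, 2))$f1, 0)
  expect_warning(f1_from_counts(0, 0, 2), "precision")
  expect_error(f1_from_counts(-1, 0, 0), "non-negative")
})

test_that("sliding windows cover every step and respect the refractory period", {
  dec <- fx_decoder()
  set.seed(5)
  x <- continuous_eeg(matrix(rnorm(63 * 3840), 63), 64)   # 60 s block
  p <- pepasync:::stream_probabilities(dec, x)
  expect_identical(sum(is.finite(p)), 3840L - 68L + 1L)   # 3773 positions
  # threshold 1: no detections at all
  expect_identical(nrow(stream_classify(dec, x, threshold = 1,
                                        label = FALSE)), 0L)
  # low threshold: detections exist and consecutive gaps are >= 2 s
  det <- stream_classify(dec, x, threshold = 0.05, label = FALSE)
  expect_gt(nrow(det), 1)
  expect_gte(min(diff(det$time)), 2)
  expect_error(stream_classify(dec, continuous_eeg(matrix(0, 63, 10), 64),
                               threshold = 0.5), "shorter")
})

test_that("the refractory scan emits the first eligible crossing after each detection", {
  p <- rep(0, 1000)
  p[c(100, 150, 228, 300, 500)] <- 0.9
  idx <- pepasync:::refractory_scan_cpp(p, 0.5, 128L, 67L)
  expect_identical(idx, c(100L, 228L, 500L))
})

test_that("threshold optimization returns the F1-argmax with high-threshold ties", {
  opt <- fx_e2e()$opt
  expect_gte(opt$f1, max(opt$table$f1) - 1e-12)
  ties <- opt$table$threshold[opt$table$f1 == max(opt$table$f1)]
  expect_equal(opt$threshold, max(ties))
})

test_that("validation marginal confusion matrices are consistent", {
  e <- fx_e2e()
  v <- e$result
  expect_identical(v$tp + v$fn, nrow(e$validation_block$truth))
  ang <- v$confusion_angle
  expect_identical(ang["5", "5"],
                   v$confusion["left5", "left5"] +
                     v$confusion["left5", "right5"] +
                     v$confusion["right5", "left5"] +
                     v$confusion["right5", "right5"])
  expect_identical(sum(v$confusion_direction), sum(v$confusion))
  expect_equal(v$macro_f1, mean(v$per_class_f1))
})
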