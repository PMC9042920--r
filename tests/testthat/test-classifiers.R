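test_that("normalizer z-scores its training data and nothing else", {
  set.seed(14)
  tr <- matrix(rnorm(50 * 4, mean = 3, sd = 2), 50)
  nm <- fit_normalizer(tr)
  z <- apply_normalizer(nm, tr)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_equal(apply(z, 2, sd), rep(1, 4), tolerance = 1e-9)
  # shifted held-out data keeps its shift (no leakage of test statistics)
  te <- tr + 5
  expect_gt(min(colMeans(apply_normalizer(nm, te))), 1)
  # constant feature maps to zero with a warning
  tr2 <- cbind(tr, 7)
  expect_warning(nm2 <- fit_normalizer(tr2), "constant")
  expect_identical(unique(apply_normalizer(nm2, tr2)[, 5]), 0)
})

test_that("RBF-SVM separates clusters, calibrates probabilities, beats linear on XOR", {
  set.seed(3)
  a <- matrix(rnorm(40 * 2, 3), 40)
  b <- matrix(rnorm(40 * 2, -3), 40)
  f <- rbind(a, b)
  lab <- factor(rep(c("pep", "rest"), each = 40))
  m <- train_svm(f, lab, probability = TRUE, seed = 1)
  expect_identical(unname(mean(predict(m, f) == lab)), 1)
  p <- predict(m, f, type = "prob")
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unname(rowSums(p)), rep(1, 80), tolerance = 1e-12)
  expect_gt(mean(p[1:40, "pep"]), 0.9)
  expect_lt(mean(p[41:80, "pep"]), 0.1)
  expect_error(train_svm(f, factor(rep("pep", 80))), "two classes")
  # XOR pattern: RBF succeeds where a linear machine cannot
  n <- 50
  xa <- rbind(matrix(rnorm(n, 2, 0.4), n / 2),
              matrix(rnorm(n, -2, 0.4), n / 2))
  xa <- cbind(xa, rbind(matrix(rnorm(n, 2, 0.4), n / 2),
                        matrix(rnorm(n, -2, 0.4), n / 2))[, 1])
  xb <- cbind(c(rnorm(n / 2, 2, 0.4), rnorm(n / 2, -2, 0.4)),
              c(rnorm(n / 2, -2, 0.4), rnorm(n / 2, 2, 0.4)))
  X <- rbind(xa[, 1:2], xb)
  y <- factor(rep(c("a", "b"), each = n))
  rbf <- train_svm(X, y, cost = 10, seed = 1)
  expect_gt(mean(predict(rbf, X) == y), 0.9)
  lin <- e1071::svm(X, y, kernel = "linear", scale = FALSE)
  expect_lte(mean(predict(lin, X) == y), 0.6)
})

test_that("hyper-parameter search picks from the grid via the shared CV protocol", {
  set.seed(8)
  f <- rbind(matrix(rnorm(30 * 3, 1.5), 30), matrix(rnorm(30 * 3, -1.5), 30))
  lab <- factor(rep(c("x", "y"), each = 30))
  m <- train_svm(f, lab, cost = c(0.1, 1), gamma = c(0.1, 0.5),
                 folds = 3, reps = 2, seed = 4)
  expect_true(m$cost %in% c(0.1, 1))
  expect_identical(nrow(m$cv), 4L)
  # deterministic given the seed
  m2 <- train_svm(f, lab, cost = c(0.1, 1), gamma = c(0.1, 0.5),
                  folds = 3, reps = 2, seed = 4)
  expect_identical(m$cv, m2$cv)
})

test_that("hierarchical prediction gates the second stage on the threshold", {
  dec <- fx_decoder()
  ep <- fx_hisnr_epochs()
  # threshold 1.0: nothing is ever detected, stage 2 never runs
  pr <- predict(dec, ep, threshold = 1.0)
  expect_true(all(pr == "rest"))
  expect_identical(attr(pr, "stage2_calls"), 0L)
  # a planted left-10 epoch at high SNR is detected and labeled left10
  i <- which(ep$labels == "left10")[1]
  one <- predict(dec, ep$data[i, , ], threshold = 0.5)
  expect_identical(as.character(one), "left10")
  expect_identical(attr(one, "stage2_calls"), 1L)
  # epochs below threshold stay rest even when stage 2 runs for others
  pr2 <- predict(dec, ep, threshold = 0.5)
  expect_identical(attr(pr2, "stage2_calls"), sum(pr2 != "rest"))
  expect_gt(mean(pr2[ep$labels != "rest"] == ep$labels[ep$labels != "rest"]),
            0.9)
  expect_error(predict(dec, ep), "threshold")
})

test_that("decoder fits are reproducible and carry provenance", {
  ep <- fx_hisnr_epochs()
  d1 <- pep_decoder(ep, k_s = 4, k_t = 4, fisher_k = 50, cost = 10,
                    seed = 3)
  d2 <- pep_decoder(ep, k_s = 4, k_t = 4, fisher_k = 50, cost = 10,
                    seed = 3)
  expect_identical(d1$svm_bin$platt, d2$svm_bin$platt)
  expect_identical(d1$bcsp$W, d2$bcsp$W)
  expect_identical(d1$fisher$selected, d2$fisher$selected)
  expect_identical(d1$classes, c("left10", "left5", "right10", "right5"))
  # tuning provenance: a calibration block cannot tune the threshold
  d1$provenance$calibration_blocks <- 1:4
  expect_error(tune_decoder(d1, 0.9, 0.8, block = 2), "calibration")
  d3 <- tune_decoder(d1, 0.9, 0.8, block = 5)
  expect_identical(d3$provenance$tuning_block, 5)
  expect_error(tune_decoder(d1, 0.9, 3.5, block = 5), "lag")
})
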