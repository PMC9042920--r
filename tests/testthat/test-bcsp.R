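planted_fixture <- function(seed = 42, ch = 8, ns = 30, n = 20, gain = 3) {
  set.seed(seed)
  dir <- rnorm(ch); dir <- dir / sqrt(sum(dir^2))
  mk <- function(g) {
    a <- array(rnorm(n * ch * ns), c(n, ch, ns))
    for (i in seq_len(n)) a[i, , ] <- a[i, , ] + g * dir %o% rnorm(ns)
    a
  }
  list(dir = dir, x1 = mk(gain), x2 = mk(0))
}

test_that("spatial-only BCSP equals a brute-force generalized eigendecomposition", {
  fx <- planted_fixture()
  m <- fit_bcsp(fx$x1, fx$x2, k_s = 4, k_t = 4, max_iter = 0, shrink = 0)
  C1 <- pepasync:::cov_spatial(fx$x1, diag(30))
  C2 <- pepasync:::cov_spatial(fx$x2, diag(30))
  oracle <- sort(Re(eigen(solve(C1 + C2, C1))$values), decreasing = TRUE)
  expect_equal(sort(m$values_spatial, decreasing = TRUE), oracle,
               tolerance = 1e-6)
  # filters are generalized-eigenvector normalized: w' (C1+C2) w = 1
  norms <- diag(t(m$W) %*% (C1 + C2) %*% m$W)
  expect_equal(unname(norms), rep(1, 4), tolerance = 1e-9)
})

test_that("the top spatial filter recovers a planted discriminative direction", {
  fx <- planted_fixture(n = 40)
  m <- fit_bcsp(fx$x1, fx$x2, k_s = 4, k_t = 4, max_iter = 0)
  w <- m$W[, 1]
  cosine <- abs(sum(w * fx$dir)) / sqrt(sum(w^2))
  expect_gt(cosine, 0.99)
})

test_that("identical classes give eigenvalues of one half", {
  fx <- planted_fixture()
  m <- fit_bcsp(fx$x1, fx$x1, k_s = 4, k_t = 4, max_iter = 0, shrink = 0)
  expect_equal(m$values_spatial, rep(0.5, 8), tolerance = 1e-6)
})

test_that("the alternating objective is non-decreasing", {
  for (seed in c(1, 2, 3)) {
    fx <- planted_fixture(seed = seed, n = 30, gain = 1.5)
    m <- fit_bcsp(fx$x1, fx$x2, k_s = 4, k_t = 4, max_iter = 10)
    expect_true(all(diff(m$objective) >= -1e-9))
  }
})

test_that("feature transform satisfies its algebraic identities", {
  fx <- planted_fixture()
  m <- fit_bcsp(fx$x1, fx$x2, k_s = 4, k_t = 4)
  ep <- fx$x1[1, , ]
  f <- bcsp_transform(m, ep)
  expect_identical(length(f), 4L + 4L)
  expect_true(all(f > 0))
  # zero epoch -> zero features; quadratic scaling
  expect_identical(bcsp_transform(m, ep * 0), rep(0, 8))
  expect_equal(bcsp_transform(m, 2 * ep), 4 * f, tolerance = 1e-9)
  # spatial and temporal parts share the same total energy
  expect_equal(sum(f[1:4]), sum(f[5:8]), tolerance = 1e-9)
  expect_error(bcsp_transform(m, ep[1:3, ]), "dimensions")
})

test_that("filter-count selection honors its contract", {
  ep <- fx_hisnr_epochs()
  lab <- factor(ifelse(ep$labels == "rest", "rest", "pep"))
  bin <- epoch_set(ep$data, lab, ep$onsets, ep$rate, ep$pre)
  one <- select_filters_cv(bin, grid = data.frame(k_s = 4, k_t = 2),
                           folds = 4, reps = 1, seed = 2)
  expect_identical(one$k_s, 4)
  expect_identical(one$k_t, 2)
  sel <- select_filters_cv(bin, grid = expand.grid(k_s = c(2, 4),
                                                   k_t = 2),
                           folds = 4, reps = 2, seed = 2)
  expect_gte(sel$k_s, 2)
  expect_gt(max(sel$cv$mean), 0.95)       # high-SNR fixture separates well
  expect_error(select_filters_cv(bin, grid = data.frame()[0, ]), "grid")
})

test_that("permuted labels give chance-level selection accuracy", {
  ep <- fx_hisnr_epochs()
  lab <- factor(ifelse(ep$labels == "rest", "rest", "pep"))
  n_pep <- sum(lab == "pep")
  set.seed(77)
  # balanced binary subset, then permuted labels
  idx <- c(which(lab == "pep")[1:20], which(lab == "rest"))
  perm <- epoch_set(ep$data[idx, , ], sample(lab[idx]), ep$onsets[idx],
                    ep$rate, ep$pre)
  out <- select_filters_cv(perm, grid = data.frame(k_s = 4, k_t = 2),
                           folds = 4, reps = 2, seed = 3)
  expect_gte(out$cv$mean, 0.40)
  expect_lte(out$cv$mean, 0.60)
})
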