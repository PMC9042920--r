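#' Flatten an epoch into amplitude features
#'
#' Takes the amplitude of every channel at every time point, channel-major:
#' feature `(t - 1) * n_channels + c` is channel `c` at sample `t`. A
#' standard 63 x 68 epoch yields 4284 features.
#'
#' @param epoch Channels x samples matrix, or a (trials, channels, samples)
#'   array / [epoch_set()] for a feature matrix.
#' @return A numeric vector (or trials x features matrix).
#' @export
amplitude_features <- function(epoch) {
  if (inherits(epoch, "pep_epochs")) epoch <- epoch$data
  if (is.matrix(epoch)) return(as.numeric(epoch))
  matrix(epoch, dim(epoch)[1], dim(epoch)[2] * dim(epoch)[3])
}

#' Restore an amplitude-feature vector to epoch shape
#'
#' @param v Feature vector from [amplitude_features()].
#' @param channels Number of channels.
#' @export
amplitude_unflatten <- function(v, channels) {
  matrix(v, channels, length(v) / channels)
}

#' Fisher scores of features for a multi-class contrast
#'
#' Per feature j: `sum_c n_c (mu_cj - mu_j)^2 / sum_c n_c s2_cj` —
#' between-class over within-class scatter, with `s2` the per-class
#' maximum-likelihood variance. A feature with zero within-class scatter but
#' nonzero between-class scatter gets an `Inf` sentinel (ranked first); a
#' feature with no scatter at all scores 0.
#'
#' @param features Trials x features matrix.
#' @param labels Class labels (>= 2 epochs per class).
#' @return Numeric score vector (>= 0).
#' @export
fisher_scores <- function(features, labels) {
  labels <- as.factor(labels)
  if (any(table(labels) < 2)) stopf("need >= 2 epochs per class")
  mu <- colMeans(features)
  num <- 0; den <- 0
  for (cl in levels(labels)) {
    idx <- labels == cl
    n_c <- sum(idx)
    mu_c <- colMeans(features[idx, , drop = FALSE])
    s2_c <- colMeans(features[idx, , drop = FALSE]^2) - mu_c^2
    num <- num + n_c * (mu_c - mu)^2
    den <- den + n_c * pmax(s2_c, 0)
  }
  score <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  if (any(is.infinite(score)))
    warnf("%d features have zero within-class variance",
          sum(is.infinite(score)))
  score
}

#' Select the top-k features by Fisher score
#'
#' Deterministic: score ties are broken by the lower feature index.
#'
#' @param scores Vector from [fisher_scores()].
#' @param k Number of features to keep.
#' @return Integer indices of the selected features (sorted by rank).
#' @export
fisher_select <- function(scores, k) {
  if (k > length(scores)) stopf("k exceeds feature count")
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Select the Fisher feature count by repeated cross-validation
#'
#' Same protocol as [select_filters_cv()]: stratified `reps x folds` CV of
#' the full chain (Fisher selection, z-normalization, RBF-SVM) refit per
#' fold; scoring is 4-class accuracy; ties go to the smallest k.
#'
#' @param features Trials x features matrix (calibration data only).
#' @param labels Class labels.
#' @param grid Candidate k values.
#' @param folds,reps,seed CV geometry and seed.
#' @param cost,gamma_scale SVM hyper-parameters used inside the selection.
#' @return A list with `k` and the CV table `cv`.
#' @export
select_k_cv <- function(features, labels, grid = c(25, 50, 100, 200, 400),
                        folds = 10, reps = 10, seed = 1L, cost = 1,
                        gamma_scale = 1) {
  if (!length(grid)) stopf("empty grid")
  labels <- as.factor(labels)
  fold_ids <- cv_fold_ids(labels, folds, reps, seed)
  acc <- matrix(NA_real_, length(grid), folds * reps)
  for (g in seq_along(grid)) {
    i <- 0
    for (r in seq_len(reps)) for (f in seq_len(folds)) {
      i <- i + 1
      tr <- fold_ids[[r]] != f
      sc <- fisher_scores(features[tr, , drop = FALSE], labels[tr])
      sel <- fisher_select(sc, grid[g])
      nm <- fit_normalizer(features[tr, sel, drop = FALSE])
      sv <- e1071::svm(apply_normalizer(nm, features[tr, sel, drop = FALSE]),
                       labels[tr], type = "C-classification",
                       kernel = "radial", cost = cost,
                       gamma = gamma_scale / length(sel), scale = FALSE)
      pr <- predict(sv, apply_normalizer(nm,
                                         features[!tr, sel, drop = FALSE]))
      acc[g, i] <- mean(pr == labels[!tr])
    }
  }
  mean_acc <- rowMeans(acc)
  best <- order(-mean_acc, grid)[1]
  list(k = grid[best],
       cv = data.frame(k = grid, mean = mean_acc, sd = apply(acc, 1, sd)))
}
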