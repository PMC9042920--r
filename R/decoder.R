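#' Fit the hierarchical perturbation decoder
#'
#' The central fitting function of the package. From calibration epochs it
#' trains (i) a binary PEP-vs-rest detector — BCSP features, z-normalization
#' and a Platt-calibrated RBF-SVM — and (ii) a 4-class direction/angle model
#' — amplitude features, Fisher-score selection, z-normalization and an
#' RBF-SVM with one-vs-one voting. The asynchronous operating point
#' (probability threshold and mean time lag) is tuned afterwards on a
#' separate block with [tune_decoder()].
#'
#' @param epochs A [epoch_set()] of calibration data containing `rest` and
#'   the four perturbation conditions; rejected epochs are excluded.
#' @param k_s,k_t Number of spatial/temporal BCSP filters, or `NULL` to
#'   select them with [select_filters_cv()] over `filter_grid`.
#' @param fisher_k Number of amplitude features, or `NULL` to select with
#'   [select_k_cv()] over `k_grid`.
#' @param filter_grid,k_grid Selection grids.
#' @param cost,gamma SVM hyper-parameter grids (scalars skip the search).
#' @param folds,reps,seed Shared CV protocol (stratified, seeded).
#' @return An object of class `pep_decoder`.
#' @examples
#' \donttest{
#' rec <- simulate_subject(paradigm_config(n_blocks = 2,
#'                                         reps_per_condition = 2))
#' prep <- fit_preprocessor(rec, calibration_blocks = 1:2)
#' }
#' @export
pep_decoder <- function(epochs, k_s = 6, k_t = 4, fisher_k = 200,
                        filter_grid = expand.grid(k_s = c(2, 4, 6, 8),
                                                  k_t = c(2, 4, 6)),
                        k_grid = c(25, 50, 100, 200, 400),
                        cost = 10, gamma = NULL, folds = 10, reps = 10,
                        seed = 1L) {
  epochs <- epochs_subset(epochs, epochs$kept)
  labels <- epochs$labels
  pep_classes <- setdiff(levels(droplevels(labels)), "rest")
  if (!"rest" %in% labels || length(pep_classes) < 2)
    stopf("calibration epochs must contain rest and perturbation classes")
  is_pep <- labels != "rest"
  bin_labels <- factor(ifelse(is_pep, "pep", "rest"),
                       levels = c("pep", "rest"))
  bin_set <- epoch_set(epochs$data, bin_labels, epochs$onsets, epochs$rate,
                       epochs$pre)
  sel_filters <- NULL
  if (is.null(k_s) || is.null(k_t)) {
    sel_filters <- select_filters_cv(bin_set, filter_grid, folds, reps,
                                     seed)
    k_s <- sel_filters$k_s; k_t <- sel_filters$k_t
  }
  bcsp <- fit_bcsp(epochs$data[is_pep, , , drop = FALSE],
                   epochs$data[!is_pep, , , drop = FALSE], k_s, k_t)
  fb <- bcsp_transform(bcsp, epochs$data)
  norm_bin <- fit_normalizer(fb)
  svm_bin <- train_svm(apply_normalizer(norm_bin, fb), bin_labels,
                       cost = cost, gamma = gamma, folds = folds,
                       reps = reps, seed = seed, probability = TRUE)
  mc <- epochs_subset(epochs, is_pep)
  fm <- amplitude_features(mc)
  mc_labels <- droplevels(mc$labels)
  sel_k <- NULL
  if (is.null(fisher_k)) {
    sel_k <- select_k_cv(fm, mc_labels, k_grid, folds, reps, seed)
    fisher_k <- sel_k$k
  }
  scores <- fisher_scores(fm, mc_labels)
  sel <- fisher_select(scores, fisher_k)
  norm_mc <- fit_normalizer(fm[, sel, drop = FALSE])
  svm_mc <- train_svm(apply_normalizer(norm_mc, fm[, sel, drop = FALSE]),
                      mc_labels, cost = cost, gamma = gamma, folds = folds,
                      reps = reps, seed = seed)
  structure(list(bcsp = bcsp, norm_bin = norm_bin, svm_bin = svm_bin,
                 fisher = list(scores = scores, selected = sel,
                               k = fisher_k),
                 norm_mc = norm_mc, svm_mc = svm_mc,
                 classes = levels(mc_labels),
                 pre = epochs$pre, len = dim(epochs$data)[3],
                 rate = epochs$rate,
                 threshold = NA_real_, lag = NA_real_,
                 selection = list(filters = sel_filters, k = sel_k),
                 provenance = list(
                   calibration_blocks = sort(unique(epochs$blocks)),
                   tuning_block = NA_integer_, seed = seed)),
            class = "pep_decoder")
}

#' Binary PEP probability of onset-aligned epochs
#'
#' @param decoder A `pep_decoder`.
#' @param epoch Channels x samples matrix, array or [epoch_set()].
#' @return Probability (vector) of the PEP class.
#' @export
pep_probability <- function(decoder, epoch) {
  f <- bcsp_transform(decoder$bcsp, epoch)
  if (!is.matrix(f)) f <- matrix(f, nrow = 1)
  predict(decoder$svm_bin, apply_normalizer(decoder$norm_bin, f),
          type = "prob")[, "pep"]
}

#' Multiclass direction/angle label of onset-aligned epochs
#'
#' @inheritParams pep_probability
#' @return Factor of predicted labels.
#' @export
pep_expression <- function(decoder, epoch) {
  f <- amplitude_features(epoch)
  if (!is.matrix(f)) f <- matrix(f, nrow = 1)
  f <- f[, decoder$fisher$selected, drop = FALSE]
  predict(decoder$svm_mc, apply_normalizer(decoder$norm_mc, f))
}

#' Hierarchical prediction for onset-aligned epochs
#'
#' Runs the binary detector; only epochs whose PEP probability reaches the
#' threshold are passed to the 4-class stage, all others are labeled
#' `rest`. The number of second-stage invocations is attached as attribute
#' `"stage2_calls"`.
#'
#' @param object A `pep_decoder`.
#' @param newdata Epochs (matrix, array or [epoch_set()]).
#' @param threshold Detection probability threshold; defaults to the tuned
#'   one.
#' @param ... Unused.
#' @return Factor with levels `rest` plus the four perturbation classes.
#' @export
predict.pep_decoder <- function(object, newdata, threshold = NULL, ...) {
  threshold <- threshold %||% object$threshold
  if (is.na(threshold))
    stopf("decoder has no threshold; tune it or pass `threshold`")
  p <- pep_probability(object, newdata)
  out <- rep("rest", length(p))
  hit <- p >= threshold
  calls <- 0L
  if (any(hit)) {
    if (inherits(newdata, "pep_epochs")) newdata <- newdata$data
    if (is.matrix(newdata)) newdata <- array(newdata, c(1, dim(newdata)))
    out[hit] <- as.character(pep_expression(object,
      newdata[hit, , , drop = FALSE]))
    calls <- sum(hit)
  }
  structure(factor(out, levels = c("rest", object$classes)),
            stage2_calls = calls)
}

#' Freeze the asynchronous operating point of a decoder
#'
#' @param decoder A `pep_decoder`.
#' @param threshold Probability threshold from [optimize_threshold()].
#' @param lag Mean time lag (s) from [estimate_time_lag()].
#' @param block Tuning block id (recorded as provenance; must not be a
#'   calibration block).
#' @export
tune_decoder <- function(decoder, threshold, lag, block = NA_integer_) {
  if (!is.na(block) &&
      block %in% decoder$provenance$calibration_blocks)
    stopf("tuning block %d was used for calibration", block)
  if (lag <= 0 || lag > 2)
    stopf("mean lag %.3f s outside the plausible (0, 2] s range", lag)
  decoder$threshold <- threshold
  decoder$lag <- lag
  decoder$provenance$tuning_block <- block
  decoder
}

#' @export
print.pep_decoder <- function(x, ...) {
  cat("<hierarchical PEP decoder>\n")
  cat(sprintf("  binary: BCSP %d spatial x %d temporal filters + RBF-SVM (cost %g)\n",
              ncol(x$bcsp$W), ncol(x$bcsp$V), x$svm_bin$cost))
  cat(sprintf("  multiclass: %d Fisher-selected amplitude features, classes %s\n",
              x$fisher$k, paste(x$classes, collapse = "/")))
  cat(sprintf("  operating point: threshold %s, lag %s\n",
              if (is.na(x$threshold)) "untuned" else
                sprintf("%.3f", x$threshold),
              if (is.na(x$lag)) "untuned" else
                sprintf("%.3f s", x$lag)))
  invisible(x)
}

#' @export
summary.pep_decoder <- function(object, ...) {
  print(object)
  cat(sprintf("  calibration blocks: %s; tuning block: %s; seed %d\n",
              paste(object$provenance$calibration_blocks, collapse = ","),
              object$provenance$tuning_block, object$provenance$seed))
  cat(sprintf("  spatial eigenvalue range: %.3f .. %.3f\n",
              min(object$bcsp$values_spatial),
              max(object$bcsp$values_spatial)))
  invisible(object)
}
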