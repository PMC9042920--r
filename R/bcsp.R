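# Bilinear common spatial patterns for the PEP-vs-rest contrast.
#
# Classical CSP finds spatial filters w maximizing the class-wise variance
# ratio through the generalized eigenproblem C1 w = lambda (C1 + C2) w.
# The bilinear variant learns paired spatial (W) and temporal (V) filters by
# alternating two such eigenproblems: with V fixed, the spatial problem is
# solved on class-mean covariances of the temporally filtered epochs (XV);
# with W fixed, the temporal problem is solved on (W'X)'(W'X). Filters are
# taken in pairs from both ends of the eigenvalue spectrum.

# class-mean spatial covariance of temporally filtered epochs:
# (1/n) sum_i X_i G X_i' with G = V V', epochs as (n, ch, s) array
#' @noRd
cov_spatial <- function(A, G) {
  dm <- dim(A); n <- dm[1]; ch <- dm[2]; s <- dm[3]
  Bf <- matrix(A, n * ch, s) %*% G
  MA <- matrix(aperm(A, c(1, 3, 2)), n * s, ch)
  MB <- matrix(aperm(array(Bf, c(n, ch, s)), c(1, 3, 2)), n * s, ch)
  crossprod(MA, MB) / n
}

# class-mean temporal covariance of spatially filtered epochs:
# (1/n) sum_i X_i' H X_i with H = W W'
#' @noRd
cov_temporal <- function(A, H) {
  dm <- dim(A); n <- dm[1]; ch <- dm[2]; s <- dm[3]
  At <- aperm(A, c(1, 3, 2))                 # (n, s, ch)
  Bf <- matrix(At, n * s, ch) %*% H          # (n*s) x ch
  MA <- matrix(A, n * ch, s)
  MB <- matrix(aperm(array(Bf, c(n, s, ch)), c(1, 3, 2)), n * ch, s)
  crossprod(MA, MB) / n
}

# generalized symmetric eigenproblem C1 u = lambda (C1 + C2) u via whitening;
# columns of the returned filters satisfy u' (C1 + C2) u = 1
#' @noRd
csp_eig <- function(C1, C2, shrink = 1e-4) {
  Cs <- C1 + C2
  Cs <- Cs + diag(shrink * sum(diag(Cs)) / nrow(Cs), nrow(Cs))
  e <- eigen(Cs, symmetric = TRUE)
  ev <- pmax(e$values, max(e$values) * 1e-12)
  P <- e$vectors %*% (t(e$vectors) / sqrt(ev))
  S <- P %*% C1 %*% t(P)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  list(filters = t(P) %*% es$vectors, values = es$values)
}

#' @noRd
pair_select <- function(n, k) {
  if (k > n) stopf("cannot select %d filters from %d", k, n)
  c(seq_len(ceiling(k / 2)), seq(n - floor(k / 2) + 1, length.out =
                                   floor(k / 2)))
}

#' Fit a bilinear common spatial pattern model
#'
#' @param x1,x2 Epochs of the two classes as (trials, channels, samples)
#'   arrays, or a [epoch_set()] each.
#' @param k_s,k_t Number of spatial and temporal filters (taken half from
#'   each end of the spectrum; even values recommended).
#' @param max_iter Maximum alternating iterations; `0` fits classical
#'   (spatial-only) CSP with the temporal filter fixed at identity.
#' @param tol Relative objective-change convergence tolerance.
#' @param shrink Covariance shrinkage coefficient (times mean eigenvalue).
#' @return An object of class `pep_bcsp` with spatial filters `W`
#'   (channels x k_s), temporal filters `V` (samples x k_t, or identity),
#'   the eigenvalue sets, and the per-iteration objective trace.
#' @examples
#' a <- array(rnorm(20 * 8 * 30), c(20, 8, 30))
#' b <- array(rnorm(20 * 8 * 30), c(20, 8, 30))
#' m <- fit_bcsp(a, b, k_s = 4, k_t = 2)
#' @export
fit_bcsp <- function(x1, x2, k_s = 6, k_t = 4, max_iter = 10, tol = 1e-6,
                     shrink = 1e-4) {
  A1 <- if (inherits(x1, "pep_epochs")) x1$data else x1
  A2 <- if (inherits(x2, "pep_epochs")) x2$data else x2
  ch <- dim(A1)[2]; ns <- dim(A1)[3]
  if (dim(A1)[1] < 2 || dim(A2)[1] < 2) stopf("need >= 2 epochs per class")
  if (k_s > ch || k_t > ns) stopf("more filters requested than dimensions")
  objective <- function(vals, k)
    sum(pmax(vals[pair_select(length(vals), k)],
             1 - vals[pair_select(length(vals), k)]))
  V <- diag(ns)
  spat <- function(V) {
    G <- tcrossprod(V)
    csp_eig(cov_spatial(A1, G), cov_spatial(A2, G), shrink)
  }
  e <- spat(V)
  W <- e$filters[, pair_select(ncol(e$filters), k_s), drop = FALSE]
  vals_s <- e$values
  obj <- objective(vals_s, k_s)
  trace <- obj
  vals_t <- NULL
  if (max_iter > 0) {
    for (it in seq_len(max_iter)) {
      H <- tcrossprod(W)
      et <- csp_eig(cov_temporal(A1, H), cov_temporal(A2, H), shrink)
      Vn <- et$filters[, pair_select(ncol(et$filters), k_t), drop = FALSE]
      en <- spat(Vn)
      obj_new <- objective(en$values, k_s)
      if (obj_new < obj - 1e-12) break   # treat decrease as converged
      V <- Vn; vals_t <- et$values
      W <- en$filters[, pair_select(ncol(en$filters), k_s), drop = FALSE]
      vals_s <- en$values
      trace <- c(trace, obj_new)
      if (abs(obj_new - obj) < tol * max(1, abs(obj))) { obj <- obj_new; break }
      obj <- obj_new
    }
    if (length(trace) == max_iter + 1 &&
        abs(trace[length(trace)] - trace[length(trace) - 1]) >=
          tol * max(1, abs(obj)))
      warnf("BCSP alternation did not converge in %d iterations", max_iter)
  }
  structure(list(W = W, V = V, k_s = as.integer(k_s),
                 k_t = as.integer(if (max_iter > 0) k_t else ns),
                 values_spatial = vals_s, values_temporal = vals_t,
                 objective = trace),
            class = "pep_bcsp")
}

#' @export
print.pep_bcsp <- function(x, ...) {
  cat(sprintf("<BCSP> %d spatial x %d temporal filters; objective %.4f (%d iterations)\n",
              ncol(x$W), ncol(x$V), tail(x$objective, 1),
              length(x$objective)))
  invisible(x)
}

#' Extract BCSP covariance-diagonal features
#'
#' For an epoch X, computes `S = W' X V` and returns the spatial covariance
#' diagonal `diag(S S')` followed by the temporal diagonal `diag(S' S)`.
#'
#' @param model A `pep_bcsp`.
#' @param epoch A channels x samples matrix, a (trials, channels, samples)
#'   array, or a [epoch_set()].
#' @param log Apply `log` to the (positive) features.
#' @return A feature vector, or a trials x features matrix for multiple
#'   epochs.
#' @export
bcsp_transform <- function(model, epoch, log = FALSE) {
  one <- function(X) {
    if (nrow(X) != nrow(model$W) || ncol(X) != nrow(model$V))
      stopf("epoch dimensions do not match the model")
    S <- crossprod(model$W, X) %*% model$V
    f <- c(rowSums(S^2), colSums(S^2))
    if (log) log(pmax(f, 1e-300)) else f
  }
  if (inherits(epoch, "pep_epochs")) epoch <- epoch$data
  if (is.matrix(epoch)) return(one(epoch))
  t(apply(epoch, 1, one))
}

#' Select the number of BCSP filters by repeated cross-validation
#'
#' For every grid point, runs stratified `reps x folds` cross-validation of
#' the full chain (BCSP fit, feature extraction, z-normalization, RBF-SVM),
#' refit inside each training fold, and returns the grid point with the
#' highest mean accuracy. Ties go to the smallest `k_s + k_t`, then the
#' smallest `k_s`.
#'
#' @param epochs A binary-labeled [epoch_set()] (calibration data only).
#' @param grid Data.frame with columns `k_s`, `k_t` (default the cross of
#'   `k_s` in 2,4,6,8 and `k_t` in 2,4,6).
#' @param folds,reps CV geometry (10 x 10 by default).
#' @param seed Fold seed.
#' @param cost,gamma_scale SVM hyper-parameters used inside the selection.
#' @return A list with `k_s`, `k_t` and the CV table (`cv`).
#' @export
select_filters_cv <- function(epochs, grid = expand.grid(k_s = c(2, 4, 6, 8),
                                                         k_t = c(2, 4, 6)),
                              folds = 10, reps = 10, seed = 1L,
                              cost = 1, gamma_scale = 1) {
  if (!nrow(grid)) stopf("empty grid")
  labels <- droplevels(epochs$labels)
  if (nlevels(labels) != 2) stopf("binary labels required")
  fold_ids <- cv_fold_ids(labels, folds, reps, seed)
  acc <- matrix(NA_real_, nrow(grid), folds * reps)
  for (g in seq_len(nrow(grid))) {
    k <- 0
    for (r in seq_len(reps)) for (f in seq_len(folds)) {
      k <- k + 1
      tr <- fold_ids[[r]] != f
      acc[g, k] <- chain_accuracy_bcsp(epochs, labels, tr,
                                       grid$k_s[g], grid$k_t[g],
                                       cost, gamma_scale)
    }
  }
  mean_acc <- rowMeans(acc)
  ord <- order(-mean_acc, grid$k_s + grid$k_t, grid$k_s)
  best <- ord[1]
  list(k_s = grid$k_s[best], k_t = grid$k_t[best],
       cv = data.frame(grid, mean = mean_acc, sd = apply(acc, 1, sd)))
}

# one train/test evaluation of the binary chain (leak-free: everything is
# fitted on the training fold only)
#' @noRd
chain_accuracy_bcsp <- function(epochs, labels, tr, k_s, k_t, cost,
                                gamma_scale) {
  lv <- levels(labels)
  m <- fit_bcsp(epochs$data[tr & labels == lv[1], , , drop = FALSE],
                epochs$data[tr & labels == lv[2], , , drop = FALSE],
                k_s, k_t)
  ftr <- bcsp_transform(m, epochs$data[tr, , , drop = FALSE])
  fte <- bcsp_transform(m, epochs$data[!tr, , , drop = FALSE])
  nm <- fit_normalizer(ftr)
  sv <- e1071::svm(apply_normalizer(nm, ftr), labels[tr],
                   type = "C-classification", kernel = "radial",
                   cost = cost, gamma = gamma_scale / ncol(ftr),
                   scale = FALSE)
  mean(predict(sv, apply_normalizer(nm, fte)) == labels[!tr])
}
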