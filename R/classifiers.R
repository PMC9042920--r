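#' Feature z-normalization fitted on training data
#'
#' @param features Trials x features training matrix.
#' @return A `pep_norm` with per-feature means and SDs. Zero-SD (constant)
#'   features are mapped to 0 with a warning.
#' @export
fit_normalizer <- function(features) {
  mu <- colMeans(features)
  s <- apply(features, 2, sd)
  if (any(s == 0 | is.na(s))) {
    warnf("%d constant features mapped to 0", sum(s == 0 | is.na(s)))
    s[s == 0 | is.na(s)] <- Inf   # (x - mu)/Inf = 0
  }
  structure(list(mean = mu, sd = s), class = "pep_norm")
}

#' @rdname fit_normalizer
#' @param norm A `pep_norm`.
#' @param features Matrix (or vector) to normalize.
#' @export
apply_normalizer <- function(norm, features) {
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  t((t(features) - norm$mean) / norm$sd)
}

# Platt-style sigmoid calibration: p(class1 | d) = 1/(1 + exp(a*d + b)),
# fitted by logistic regression on out-of-fold SVM decision values so the
# calibration never sees its own training outputs.
#' @noRd
platt_fit <- function(dv, y01) {
  fit <- suppressWarnings(glm(y01 ~ dv, family = binomial()))
  coef(fit)
}

# calibrated probabilities stay strictly inside (0, 1) so the boundary
# thresholds 0 and 1 behave as never/always-reject
#' @noRd
platt_apply <- function(cf, dv) {
  p <- 1 / (1 + exp(-(cf[1] + cf[2] * dv)))
  pmin(1 - 1e-12, pmax(1e-12, p))
}

#' Train an RBF-SVM with optional hyper-parameter search and probability
#' calibration
#'
#' Hyper-parameters are selected by the shared stratified repeated-CV
#' protocol when a grid with more than one point is supplied. For binary
#' problems a Platt-style sigmoid is fitted on out-of-fold decision values
#' (`calib_folds`-fold), giving reproducible class probabilities.
#' Multiclass prediction uses the one-vs-one majority vote of the
#' underlying machine.
#'
#' @param features Trials x features matrix (already normalized).
#' @param labels Class labels.
#' @param cost,gamma Candidate grids; `gamma = NULL` uses `1/n_features`.
#'   Grids with several values trigger CV selection.
#' @param folds,reps,seed CV protocol for the hyper-parameter search.
#' @param probability Fit the Platt calibration (binary only).
#' @param calib_folds Folds for the out-of-fold decision values.
#' @return A `pep_svm` wrapping the fitted machine, the chosen
#'   hyper-parameters and the calibration coefficients.
#' @export
train_svm <- function(features, labels, cost = 1, gamma = NULL,
                      folds = 10, reps = 10, seed = 1L,
                      probability = FALSE, calib_folds = 5) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stopf("need at least two classes")
  gamma <- gamma %||% (1 / ncol(features))
  grid <- expand.grid(cost = cost, gamma = gamma)
  cv <- NULL
  if (nrow(grid) > 1) {
    fold_ids <- cv_fold_ids(labels, folds, reps, seed)
    acc <- sapply(seq_len(nrow(grid)), function(g) {
      a <- numeric(0)
      for (r in seq_len(reps)) for (f in seq_len(folds)) {
        tr <- fold_ids[[r]] != f
        sv <- e1071::svm(features[tr, , drop = FALSE], labels[tr],
                         type = "C-classification", kernel = "radial",
                         cost = grid$cost[g], gamma = grid$gamma[g],
                         scale = FALSE)
        a <- c(a, mean(predict(sv, features[!tr, , drop = FALSE]) ==
                         labels[!tr]))
      }
      mean(a)
    })
    best <- order(-acc, grid$cost, grid$gamma)[1]
    cv <- data.frame(grid, accuracy = acc)
    grid <- grid[best, , drop = FALSE]
  }
  fit <- e1071::svm(features, labels, type = "C-classification",
                    kernel = "radial", cost = grid$cost[1],
                    gamma = grid$gamma[1], scale = FALSE)
  platt <- NULL
  if (probability) {
    if (nlevels(labels) != 2)
      stopf("probability calibration implemented for binary problems")
    ids <- cv_fold_ids(labels, calib_folds, 1L, seed + 1L)[[1]]
    dv <- numeric(length(labels))
    for (f in seq_len(calib_folds)) {
      tr <- ids != f
      m <- e1071::svm(features[tr, , drop = FALSE], labels[tr],
                      type = "C-classification", kernel = "radial",
                      cost = grid$cost[1], gamma = grid$gamma[1],
                      scale = FALSE)
      dv[!tr] <- decision_values(m, features[!tr, , drop = FALSE],
                                 levels(labels))
    }
    platt <- platt_fit(dv, as.numeric(labels == levels(labels)[1]))
  }
  structure(list(fit = fit, cost = grid$cost[1], gamma = grid$gamma[1],
                 levels = levels(labels), platt = platt, cv = cv),
            class = "pep_svm")
}

# decision value oriented so positive favors `lev[1]`
#' @noRd
decision_values <- function(fit, features, lev) {
  dv <- attr(predict(fit, features, decision.values = TRUE),
             "decision.values")
  cn <- colnames(dv)[1]
  d <- as.numeric(dv[, 1])
  if (!startsWith(cn, lev[1])) d <- -d
  d
}

#' @export
predict.pep_svm <- function(object, newdata, type = c("class", "prob"),
                            ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (type == "class") return(predict(object$fit, newdata))
  if (is.null(object$platt))
    stopf("model was trained without probability calibration")
  d <- decision_values(object$fit, newdata, object$levels)
  p1 <- platt_apply(object$platt, d)
  out <- cbind(p1, 1 - p1)
  colnames(out) <- object$levels
  out
}

#' @export
print.pep_svm <- function(x, ...) {
  cat(sprintf("<RBF-SVM> %d classes, cost %g, gamma %g, %d SVs%s\n",
              length(x$levels), x$cost, x$gamma, x$fit$tot.nSV,
              if (!is.null(x$platt)) ", Platt-calibrated" else ""))
  invisible(x)
}
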