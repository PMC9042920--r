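#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' @noRd
stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Stratified fold assignment shared by every cross-validated selection
# (filters, feature count, SVM hyper-parameters): `reps` repetitions of
# `folds`-fold CV, stratified by class, deterministic given `seed`.
#' @noRd
cv_fold_ids <- function(labels, folds = 10L, reps = 10L, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  with_seed(seed, {
    lapply(seq_len(reps), function(r) {
      id <- integer(n)
      for (cl in levels(labels)) {
        idx <- which(labels == cl)
        id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
      id
    })
  })
}
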