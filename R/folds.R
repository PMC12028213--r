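#' Cross-validation fold plan
#'
#' Builds the shared fold assignments for repeated stratified k-fold
#' cross-validation.  Every selector x classifier pair consumes the identical
#' plan, so performance differences cannot come from fold luck.  Folds are
#' stratified by label and equally sized within one lesion.
#'
#' @param labels Factor or vector of class labels (stratification key),
#'   length n.
#' @param k Number of folds (default 5).
#' @param repetitions Number of repetitions (default 100).
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: list with `folds` (n x repetitions
#'   integer matrix of fold ids 1..k), `k`, `repetitions`, `seed`.
#' @export
make_fold_plan <- function(labels, k = 5L, repetitions = 100L, seed = 1L) {
  n <- length(labels)
  k <- as.integer(k)
  if (n < k) stop("need at least k samples")
  labels <- as.factor(labels)
  small <- table(labels) < k
  if (any(small))
    warning("class(es) ", paste(names(which(small)), collapse = ", "),
            " have fewer than k members; stratification is best-effort")
  old <- .Random.seed_save(seed)
  on.exit(.Random.seed_restore(old))
  folds <- matrix(NA_integer_, n, repetitions)
  for (r in seq_len(repetitions)) {
    cursor <- sample.int(k, 1L)
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      for (i in idx) {
        folds[i, r] <- cursor
        cursor <- cursor %% k + 1L
      }
    }
  }
  structure(list(folds = folds, k = k, repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d samples, %d-fold x %d repetitions (seed %d)\n",
              nrow(x$folds), x$k, x$repetitions, x$seed))
  invisible(x)
}
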