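# Feature selection methods used inside the cross-validation loop.
# Selection operates on the 3-class labels (the class structure carries the
# discriminative signal); final classification downstream is binary.

# rank-based two-class AUC of one feature (Mann-Whitney), orientation
# corrected: max(auc, 1 - auc)
.auc_two_class <- function(x, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  if (length(unique(x)) == 1L) return(0.5)  # degenerate constant feature
  r <- rank(x)
  a <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(a, 1 - a)
}

# mean one-vs-one AUC of each feature over all class pairs
mean_pairwise_auc <- function(X, labels) {
  labels <- as.factor(labels)
  lv <- levels(labels)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  sapply(seq_len(ncol(X)), function(jf) {
    a <- vapply(pairs, function(pr) {
      sel <- labels %in% pr
      .auc_two_class(X[sel, jf], labels[sel] == pr[2L])
    }, numeric(1))
    mean(a, na.rm = TRUE)
  })
}

#' AUC-based univariate feature selection
#'
#' Decomposes the three-class problem into its binary subproblems, computes
#' each feature's orientation-corrected ROC AUC per pair, and keeps features
#' whose mean AUC exceeds `threshold` (strict inequality).  A constant
#' feature has AUC 0.5 by definition.
#'
#' @param X Numeric feature matrix (training rows only).
#' @param labels Class labels (>= 2 classes present).
#' @param threshold Retention threshold (default 0.8).
#' @return Character vector of selected column names (possibly empty).
#' @export
select_auc <- function(X, labels, threshold = 0.8) {
  if (length(unique(labels)) < 2L) stop("need >= 2 classes")
  a <- mean_pairwise_auc(as.matrix(X), labels)
  colnames(X)[a > threshold]
}

#' ReliefF feature selection with a permutation null
#'
#' Multi-class ReliefF weights (k nearest hits/misses, misses weighted by
#' class prior, Manhattan distance on range-scaled features, all samples
#' evaluated).  The null distribution of each feature's weight is estimated
#' by re-running ReliefF under `n_permutations` label shuffles (the
#' neighbour geometry is label-free and computed once); features whose
#' observed weight exceeds the 95th percentile of their own null are kept.
#'
#' @param X Numeric feature matrix (training rows only).
#' @param labels Class labels (>= 2 samples per class).
#' @param n_permutations Number of label shuffles (>= 20; default 500).
#' @param k Number of neighbours per class (default 10).
#' @param quantile_level Null quantile a weight must exceed (default 0.95).
#' @param seed Integer seed for the permutations.
#' @return Character vector of selected column names.
#' @export
select_relieff <- function(X, labels, n_permutations = 500L, k = 10L,
                           quantile_level = 0.95, seed = 1L) {
  if (n_permutations < 20L)
    stop("n_permutations < 20: the null percentile is unstable")
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("all labels identical")
  if (min(table(labels)) < 2L) stop("need >= 2 samples per class")
  X <- as.matrix(X)
  rng <- apply(X, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  Xs <- sweep(sweep(X, 2L, rng[1L, ]), 2L, span, "/")
  kk <- min(k, min(table(labels)) - 1L)
  res <- cpp_relieff(Xs, as.integer(labels) - 1L, nlevels(labels),
                     as.integer(kk), as.integer(n_permutations),
                     as.integer(seed))
  thr <- apply(res$null, 2L, stats::quantile, probs = quantile_level,
               names = FALSE, type = 7)
  colnames(X)[res$weights > thr]
}

#' LASSO feature selection
#'
#' L1-penalised multinomial logistic regression on standardised features;
#' the penalty is chosen by inner cross-validation and every feature with a
#' non-zero coefficient in any class is kept.  When the chosen penalty
#' shrinks everything away, the fallback is the single feature with the
#' largest coefficient-path magnitude (flagged via attribute `fallback`).
#'
#' @param X Numeric feature matrix (training rows, standardised per fold by
#'   the caller; glmnet additionally standardises internally).
#' @param labels Class labels.
#' @param nfolds Inner folds for the penalty search (default 3).
#' @param seed Integer seed (inner fold assignment).
#' @return Character vector of selected column names.
#' @export
select_lasso <- function(X, labels, nfolds = 3L, seed = 1L) {
  X <- as.matrix(X)
  labels <- droplevels(as.factor(labels))
  fam <- if (nlevels(labels) > 2L) "multinomial" else "binomial"
  old <- .Random.seed_save(seed)
  on.exit(.Random.seed_restore(old))
  # stratified inner folds keep every class represented in each inner fit;
  # small training folds still trigger benign glmnet advisories about class
  # counts per fold, expected at n ~ 35
  foldid <- make_fold_plan(labels, k = nfolds, repetitions = 1L,
                           seed = seed)$folds[, 1L]
  cv <- suppressWarnings(
    glmnet::cv.glmnet(X, labels, family = fam, alpha = 1,
                      foldid = foldid, standardize = TRUE))
  co <- glmnet::coef.glmnet(cv$glmnet.fit, s = cv$lambda.min)
  if (!is.list(co)) co <- list(co)
  nz <- unique(unlist(lapply(co, function(m)
    rownames(m)[which(as.matrix(m) != 0)])))
  nz <- setdiff(nz, "(Intercept)")
  if (length(nz) > 0L) return(nz)
  # full-shrinkage fallback: largest coefficient-path entry
  path <- glmnet::glmnet(X, labels, family = fam, alpha = 1)
  B <- if (fam == "multinomial")
    Reduce(`+`, lapply(path$beta, function(b) abs(as.matrix(b))))
  else abs(as.matrix(path$beta))
  best <- rownames(B)[which.max(apply(B, 1L, max))]
  structure(best, fallback = TRUE)
}

# inner-CV accuracy of an LDA on a candidate feature subset — the
# elimination metric for backward selection
.inner_lda_accuracy <- function(X, y, feature_idx, inner_folds) {
  correct <- 0L
  for (fo in unique(inner_folds)) {
    tr <- inner_folds != fo
    Xtr <- X[tr, feature_idx, drop = FALSE]
    keep <- apply(Xtr, 2L, function(v) stats::sd(v) > 0)
    if (!any(keep)) next
    fit <- tryCatch(
      MASS::lda(Xtr[, keep, drop = FALSE], grouping = y[tr]),
      error = function(e) NULL)
    if (is.null(fit)) next
    pr <- stats::predict(fit, X[!tr, feature_idx, drop = FALSE][, keep,
                                                                drop = FALSE])
    correct <- correct + sum(pr$class == y[!tr])
  }
  correct / length(y)
}

#' Backward feature elimination
#'
#' Greedy backward selection: starting from the candidate pool, repeatedly
#' removes the feature whose removal maximises inner-CV LDA accuracy,
#' stopping when no removal improves it.  Ties are broken by feature name
#' order, making the procedure deterministic given the fold plan.  Because
#' the greedy sweep is quadratic in pool size, the pool is first reduced to
#' the `max_pool` features with the highest mean one-vs-one AUC.
#'
#' @param X Numeric feature matrix (training rows only).
#' @param labels Class labels.
#' @param max_pool Pre-screening pool size (default 15).
#' @param inner_k Inner folds for the elimination metric (default 3).
#' @param seed Integer seed (inner fold assignment).
#' @return Character vector of selected column names (>= 1).
#' @export
select_backward <- function(X, labels, max_pool = 15L, inner_k = 3L,
                            seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) return(colnames(X))
  y <- droplevels(as.factor(labels))
  ord <- order(-mean_pairwise_auc(X, y), colnames(X))
  pool <- sort(colnames(X)[ord[seq_len(min(max_pool, ncol(X)))]])
  old <- .Random.seed_save(seed)
  on.exit(.Random.seed_restore(old))
  inner <- make_fold_plan(y, k = min(inner_k, min(table(y))),
                          repetitions = 1L, seed = seed)$folds[, 1L]
  current <- pool
  acc <- .inner_lda_accuracy(X, y, current, inner)
  # drop the feature whose removal maximises accuracy, as long as removal
  # does not decrease it (plateau removals shrink the set); stop when every
  # removal strictly hurts
  while (length(current) > 1L) {
    cand_acc <- vapply(seq_along(current), function(i)
      .inner_lda_accuracy(X, y, current[-i], inner), numeric(1))
    best <- which.max(cand_acc)  # first = name-order tie-break (sorted)
    if (cand_acc[best] < acc) break
    acc <- cand_acc[best]
    current <- current[-best]
  }
  current
}
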