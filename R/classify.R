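# Classifiers (LDA, k-NN, radial SVM, single-hidden-layer neural network)
# with grid tuning by inner cross-validation, and the nested
# selection-classification engine.

default_tuning_grids <- function() {
  list(knn = list(k = c(3L, 5L, 7L, 9L, 11L)),
       svm = list(cost = c(0.25, 0.5, 1, 2, 4)),
       nnet = expand.grid(size = c(1L, 3L, 5L), decay = c(0, 0.01, 0.1)),
       lda = NULL)
}

# fit/predict closures; X matrices are standardized upstream
.clf_fit_predict <- function(classifier, Xtr, ytr, Xte, pars, seed) {
  switch(classifier,
    lda = {
      keep <- apply(Xtr, 2L, function(v) stats::sd(v) > 0)
      if (!any(keep)) return(factor(rep(levels(ytr)[1L], nrow(Xte)),
                                    levels = levels(ytr)))
      fit <- MASS::lda(Xtr[, keep, drop = FALSE], grouping = ytr)
      stats::predict(fit, Xte[, keep, drop = FALSE])$class
    },
    knn = class::knn(Xtr, Xte, ytr, k = min(pars$k, nrow(Xtr))),
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = pars$cost,
                        scale = FALSE)
      stats::predict(fit, Xte)
    },
    nnet = {
      old <- .Random.seed_save(seed)
      on.exit(.Random.seed_restore(old))
      fit <- nnet::nnet(Xtr, nnet::class.ind(ytr), size = pars$size,
                        decay = pars$decay, maxit = 200, trace = FALSE,
                        softmax = TRUE, MaxNWts = 20000)
      pr <- stats::predict(fit, Xte)
      factor(levels(ytr)[max.col(pr, ties.method = "first")],
             levels = levels(ytr))
    },
    stop("unknown classifier ", classifier))
}

# choose grid parameters by inner k-fold accuracy (deterministic given seed)
.tune_classifier <- function(classifier, X, y, grid, inner_k = 3L, seed = 1L) {
  if (classifier == "lda" || is.null(grid)) return(NULL)
  pars_list <- if (is.data.frame(grid)) split(grid, seq_len(nrow(grid)))
  else lapply(grid[[1L]], function(v) stats::setNames(list(v), names(grid)[1L]))
  inner <- make_fold_plan(y, k = min(inner_k, min(table(y))),
                          repetitions = 1L, seed = seed)$folds[, 1L]
  accs <- vapply(pars_list, function(pars) {
    correct <- 0L
    for (fo in unique(inner)) {
      tr <- inner != fo
      if (length(unique(y[tr])) < 2L) next
      pred <- .clf_fit_predict(classifier, X[tr, , drop = FALSE], y[tr],
                               X[!tr, , drop = FALSE], as.list(pars), seed)
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  as.list(pars_list[[which.max(accs)]])
}

# standardize by training statistics; constant features pass through centred
.standardizer <- function(Xtr) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  function(X) sweep(sweep(as.matrix(X), 2L, mu), 2L, sdv, "/")
}

.run_selector <- function(selector, X, labels3, seed,
                          relieff_permutations = 500L) {
  # ReliefF and LASSO need >= 2 samples per class; a singleton class cannot
  # inform selection, so drop its rows for those fits (only reachable with
  # very small cohorts)
  if (selector %in% c("relieff", "lasso")) {
    min_n <- if (selector == "lasso") 3L else 2L
    tb <- table(labels3)
    if (any(tb < min_n)) {
      keep <- labels3 %in% names(tb)[tb >= min_n]
      X <- X[keep, , drop = FALSE]
      labels3 <- droplevels(labels3[keep])
      if (nlevels(labels3) < 2L)
        return(structure(colnames(X)[1L], fallback = TRUE))
    }
  }
  sel <- switch(selector,
    auc = {
      s <- select_auc(X, labels3)
      if (length(s) == 0L)
        s <- structure(colnames(X)[which.max(mean_pairwise_auc(X, labels3))],
                       fallback = TRUE)
      s
    },
    relieff = {
      s <- select_relieff(X, labels3, n_permutations = relieff_permutations,
                          seed = seed)
      if (length(s) == 0L) {
        rngv <- apply(X, 2L, function(v) diff(range(v)))
        s <- structure(colnames(X)[which.max(rngv > 0)], fallback = TRUE)
      }
      s
    },
    lasso = select_lasso(X, labels3, seed = seed),
    backward = select_backward(X, labels3, seed = seed),
    stop("unknown selector ", selector))
  sel
}

#' Nested cross-validated selection and classification
#'
#' For every repetition and fold of the shared [make_fold_plan()]: feature
#' selection (on the 3-class labels) and classifier tuning are performed on
#' the 4 training folds only; the held-out fold is predicted with the tuned
#' model; binary malignant-vs-benign metrics are pooled per repetition.
#' Selection and hyperparameter search never see test rows — the design
#' that removes feature-selection bias.
#'
#' @param X Feature matrix (rows = lesions) with column names.
#' @param labels3 Three-class labels (adenoma/warthin/malignant), used for
#'   selection.
#' @param labels2 Binary labels, a factor with levels `c("benign",
#'   "malignant")`; used for training and evaluation.
#' @param fold_plan A [make_fold_plan()] built on `labels2`.
#' @param selectors Subset of `c("auc", "relieff", "lasso", "backward")`.
#' @param classifiers Subset of `c("lda", "knn", "svm", "nnet")`.
#' @param relieff_permutations Label shuffles for the ReliefF null.
#' @param grids Tuning grids, see `default_tuning_grids()`.
#' @return Object of class `cv_performance`: list with `performance`
#'   (data.frame: selector, classifier, accuracy/sensitivity/specificity
#'   mean and 5th/95th percentiles over repetitions), `per_repetition`
#'   (data.frame of per-repetition pooled metrics), `selection` (data.frame:
#'   selector, feature, frequency over folds), and `skipped` (repetitions
#'   flagged for single-class training folds).
#' @export
run_nested_cv <- function(X, labels3, labels2, fold_plan,
                          selectors = c("auc", "relieff", "lasso", "backward"),
                          classifiers = c("lda", "knn", "svm", "nnet"),
                          relieff_permutations = 500L,
                          grids = default_tuning_grids()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(fold_plan$folds))
  labels2 <- as.factor(labels2)
  if (nlevels(labels2) != 2L) stop("labels2 must be binary")
  positive <- "malignant"
  if (!positive %in% levels(labels2))
    positive <- levels(labels2)[2L]
  labels3 <- as.factor(labels3)
  R <- fold_plan$repetitions
  counts <- array(0, c(length(selectors), length(classifiers), R, 4L),
                  dimnames = list(selectors, classifiers, NULL,
                                  c("tp", "tn", "fp", "fn")))
  sel_counts <- stats::setNames(
    lapply(selectors, function(s) integer(0)), selectors)
  n_folds_total <- 0L
  skipped <- integer(0)
  for (r in seq_len(R)) {
    fold_of <- fold_plan$folds[, r]
    if (any(vapply(seq_len(fold_plan$k), function(fo)
      length(unique(labels2[fold_of != fo])) < 2L, logical(1)))) {
      skipped <- c(skipped, r)
      next
    }
    for (fo in seq_len(fold_plan$k)) {
      tr <- fold_of != fo
      seed_rf <- fold_plan$seed + 1000L * r + fo
      std <- .standardizer(X[tr, , drop = FALSE])
      Xtr <- std(X[tr, , drop = FALSE])
      Xte <- std(X[!tr, , drop = FALSE])
      nzv <- apply(Xtr, 2L, function(v) stats::sd(v) > 0)
      Xtr <- Xtr[, nzv, drop = FALSE]; Xte <- Xte[, nzv, drop = FALSE]
      n_folds_total <- n_folds_total + 1L
      for (s in selectors) {
        feats <- .run_selector(s, Xtr, droplevels(labels3[tr]), seed_rf,
                               relieff_permutations)
        tb <- sel_counts[[s]]
        for (fname in feats)
          tb[fname] <- if (fname %in% names(tb)) tb[fname] + 1L else 1L
        sel_counts[[s]] <- tb
        Xtr_s <- Xtr[, feats, drop = FALSE]
        Xte_s <- Xte[, feats, drop = FALSE]
        ytr <- droplevels(labels2[tr])
        for (cl in classifiers) {
          pars <- .tune_classifier(cl, Xtr_s, ytr, grids[[cl]],
                                   seed = seed_rf)
          pred <- .clf_fit_predict(cl, Xtr_s, ytr, Xte_s, pars, seed_rf)
          truth <- labels2[!tr]
          counts[s, cl, r, "tp"] <- counts[s, cl, r, "tp"] +
            sum(pred == positive & truth == positive)
          counts[s, cl, r, "tn"] <- counts[s, cl, r, "tn"] +
            sum(pred != positive & truth != positive)
          counts[s, cl, r, "fp"] <- counts[s, cl, r, "fp"] +
            sum(pred == positive & truth != positive)
          counts[s, cl, r, "fn"] <- counts[s, cl, r, "fn"] +
            sum(pred != positive & truth == positive)
        }
      }
    }
  }
  reps_used <- setdiff(seq_len(R), skipped)
  if (length(reps_used) == 0L) stop("every repetition was skipped")
  per_rep <- do.call(rbind, lapply(selectors, function(s)
    do.call(rbind, lapply(classifiers, function(cl)
      do.call(rbind, lapply(reps_used, function(r) {
        ct <- counts[s, cl, r, ]
        data.frame(selector = s, classifier = cl, repetition = r,
                   accuracy = (ct["tp"] + ct["tn"]) / sum(ct),
                   sensitivity = ct["tp"] / (ct["tp"] + ct["fn"]),
                   specificity = ct["tn"] / (ct["tn"] + ct["fp"]),
                   row.names = NULL)
      }))))))
  summarise <- function(v) c(mean = mean(v),
                             p05 = stats::quantile(v, 0.05, names = FALSE),
                             p95 = stats::quantile(v, 0.95, names = FALSE))
  perf <- do.call(rbind, lapply(selectors, function(s)
    do.call(rbind, lapply(classifiers, function(cl) {
      d <- per_rep[per_rep$selector == s & per_rep$classifier == cl, ]
      data.frame(selector = s, classifier = cl,
                 t(c(accuracy = summarise(d$accuracy),
                     sensitivity = summarise(d$sensitivity),
                     specificity = summarise(d$specificity))),
                 row.names = NULL)
    }))))
  n_sel_folds <- length(reps_used) * fold_plan$k
  selection <- do.call(rbind, lapply(selectors, function(s) {
    tb <- sel_counts[[s]]
    if (length(tb) == 0L) return(NULL)
    data.frame(selector = s, feature = names(tb),
               frequency = as.numeric(tb) / n_sel_folds, row.names = NULL)
  }))
  structure(list(performance = perf, per_repetition = per_rep,
                 selection = selection, skipped = skipped,
                 positive = positive),
            class = "cv_performance")
}

#' @export
print.cv_performance <- function(x, ...) {
  cat("<cv_performance> mean (5th-95th pct) over repetitions\n")
  p <- x$performance
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-8s + %-4s acc %.3f (%.2f-%.2f) sens %.3f spec %.3f\n",
                p$selector[i], p$classifier[i], p$accuracy.mean[i],
                p$accuracy.p05[i], p$accuracy.p95[i],
                p$sensitivity.mean[i], p$specificity.mean[i]))
  invisible(x)
}

#' Features selected in at least a given fraction of CV iterations
#'
#' @param cv A [run_nested_cv()] result.
#' @param selector Selector name.
#' @param min_frequency Minimum selection frequency (default 0.8).
#' @return Character vector of feature names.
#' @export
frequently_selected <- function(cv, selector, min_frequency = 0.8) {
  s <- cv$selection
  s$feature[s$selector == selector & s$frequency >= min_frequency]
}

#' Demonstrate feature-selection bias on label-independent data
#'
#' Contrasts the honest nested estimate with the biased protocol that
#' selects features once on the full data set and only cross-validates the
#' classifier.  Both arms select the `n_top` features with the highest mean
#' one-vs-one AUC and use an LDA, sharing the same fold plan.  On
#' label-independent (pure noise) features the nested estimate stays at
#' chance while the non-nested one is inflated.
#'
#' @param X Feature matrix.
#' @param labels2 Binary labels.
#' @param fold_plan A [make_fold_plan()].
#' @param n_top Number of features the AUC ranking keeps (default 5).
#' @return List with `nested_accuracy`, `non_nested_accuracy` and
#'   `inflation` (their difference).
#' @export
selection_bias_demo <- function(X, labels2, fold_plan, n_top = 5L) {
  X <- as.matrix(X)
  labels2 <- as.factor(labels2)
  top_by_auc <- function(Xs, y) {
    a <- mean_pairwise_auc(Xs, y)
    colnames(Xs)[order(-a)[seq_len(min(n_top, ncol(Xs)))]]
  }
  eval_fold <- function(feats_fun, fixed_feats = NULL) {
    correct <- 0L; total <- 0L
    for (r in seq_len(fold_plan$repetitions)) {
      fold_of <- fold_plan$folds[, r]
      for (fo in seq_len(fold_plan$k)) {
        tr <- fold_of != fo
        if (length(unique(labels2[tr])) < 2L) next
        feats <- if (is.null(fixed_feats))
          feats_fun(X[tr, , drop = FALSE], labels2[tr]) else fixed_feats
        std <- .standardizer(X[tr, feats, drop = FALSE])
        pred <- .clf_fit_predict("lda", std(X[tr, feats, drop = FALSE]),
                                 droplevels(labels2[tr]),
                                 std(X[!tr, feats, drop = FALSE]), NULL, 1L)
        correct <- correct + sum(pred == labels2[!tr])
        total <- total + sum(!tr)
      }
    }
    correct / total
  }
  nested <- eval_fold(top_by_auc)
  fixed <- top_by_auc(X, labels2)
  non_nested <- eval_fold(NULL, fixed_feats = fixed)
  list(nested_accuracy = nested, non_nested_accuracy = non_nested,
       inflation = non_nested - nested)
}

#' Evaluate one selector-classifier pair under nested CV
#'
#' Convenience wrapper over [run_nested_cv()] for a single combination:
#' selection on the 3-class labels and tuning happen inside every fold of
#' the shared plan; binary malignant-vs-benign performance is pooled per
#' repetition.
#'
#' @param classifier One of `"lda"`, `"knn"`, `"svm"`, `"nnet"`.
#' @param selector One of `"auc"`, `"relieff"`, `"lasso"`, `"backward"`.
#' @param X Feature matrix with column names.
#' @param labels3 Three-class labels (selection).
#' @param labels2 Binary labels (training and evaluation).
#' @param fold_plan A [make_fold_plan()].
#' @param ... Passed to [run_nested_cv()].
#' @return List with `performance` (one-row data.frame) and `selection`
#'   (per-feature selection frequencies for this selector).
#' @export
train_and_eval <- function(classifier, selector, X, labels3, labels2,
                           fold_plan, ...) {
  cv <- run_nested_cv(X, labels3, labels2, fold_plan,
                      selectors = selector, classifiers = classifier, ...)
  list(performance = cv$performance, selection = cv$selection,
       per_repetition = cv$per_repetition, skipped = cv$skipped)
}
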