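#' Min-max rescaling fit on the training set only
#'
#' Per feature, the affine map sending the training minimum to -1 and the
#' training maximum to +1, applied unchanged to the test set (extrapolation
#' permitted, no clipping). Features constant on the training set map to 0
#' everywhere.
#'
#' @param train n_tr x M training matrix.
#' @param test n_te x M test matrix.
#' @return List with rescaled `train` and `test`.
#' @export
rescale_train_apply <- function(train, test) {
  train <- as.matrix(train); test <- as.matrix(test)
  if (nrow(train) < 2) stop("need at least 2 training rows")
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  sc <- function(x) {
    out <- sweep(sweep(x, 2, lo), 2, rng, "/") * 2 - 1
    out[, const] <- 0
    out
  }
  list(train = sc(train), test = sc(test))
}

#' Classification metrics from a confusion table
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), balanced accuracy =
#' their mean, ppv = tp/(tp+fp), npv = tn/(tn+fn), and (when decision scores
#' are supplied) the rank-statistic AUC with midrank tie handling. Empty
#' denominators yield `NA` and set the `flagged` field.
#'
#' @param tp,fn,tn,fp Confusion counts (positives = responders).
#' @param scores Optional decision values (higher = more responder-like).
#' @param truth Optional logical truth matching `scores`.
#' @return A named list (class `metric_row`).
#' @export
compute_metrics <- function(tp, fn, tn, fp, scores = NULL, truth = NULL) {
  rate <- function(num, den) if (den >= 1) num / den else NA_real_
  sens <- rate(tp, tp + fn)
  spec <- rate(tn, tn + fp)
  bal <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  auc <- if (!is.null(scores) && !is.null(truth)) rank_auc(scores, truth)
         else NA_real_
  structure(list(sensitivity = sens, specificity = spec,
                 balanced_accuracy = bal,
                 ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
                 auc = auc,
                 flagged = anyNA(c(sens, spec))),
            class = "metric_row")
}

# AUC = P(score_pos > score_neg), midranks for ties
rank_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# per-class round-robin fold assignment after class-wise shuffling;
# with 21/19 positives in 5 folds this yields folds of 8 with 4-5 positives
stratified_folds <- function(labels, k_folds) {
  labels <- as.logical(labels)
  fold <- integer(length(labels))
  at <- 0L  # cycle position carried across classes keeps fold sizes even
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- (at + seq_along(idx) - 1L) %% k_folds + 1L
    at <- at + length(idx)
  }
  fold
}

# linear SVM decision values oriented so that positive = TRUE class
svm_decision <- function(model, newdata) {
  pr <- stats::predict(model, newdata, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  d <- as.vector(dv)
  if (first != "TRUE") d <- -d
  list(pred = as.logical(as.character(pr)), score = d)
}

fit_svm <- function(x, y, cost) {
  e1071::svm(x = x, y = factor(y, levels = c(FALSE, TRUE)),
             kernel = "linear", cost = cost, scale = FALSE)
}

# fit + score; a single-class training set (possible under permuted labels)
# degenerates to the constant classifier predicting that class
fit_predict <- function(xtr, ytr, xte, cost) {
  if (length(unique(ytr)) < 2) {
    cls <- ytr[1]
    return(list(pred = rep(cls, nrow(xte)),
                score = rep(if (cls) 1 else -1, nrow(xte))))
  }
  svm_decision(fit_svm(xtr, ytr, cost), xte)
}

# one train/test evaluation: rescale on train, fit, score test
evaluate_fold <- function(features, labels, train_idx, test_idx, cost) {
  sc <- rescale_train_apply(features[train_idx, , drop = FALSE],
                            features[test_idx, , drop = FALSE])
  out <- fit_predict(sc$train, labels[train_idx], sc$test, cost)
  truth <- labels[test_idx]
  list(tp = sum(out$pred & truth), fn = sum(!out$pred & truth),
       tn = sum(!out$pred & !truth), fp = sum(out$pred & !truth),
       score = out$score, truth = truth)
}

#' Repeated stratified k-fold cross-validated linear SVM
#'
#' For each of `n_repeats` random stratified partitions into `k_folds` folds,
#' every fold serves once as the test set: features are rescaled to [-1, 1]
#' on the training folds only, a linear-kernel SVM (cost `svm_cost`) is fit
#' on the training folds, and the held-out fold is scored. Metrics are
#' computed per evaluation and averaged (with SDs) over all
#' `k_folds * n_repeats` evaluations; AUC comes from the decision values of
#' each evaluation. Deterministic under `seed`.
#'
#' @param features N x M feature matrix (rows = subjects).
#' @param labels Length-N responder flags (logical or coercible).
#' @param k_folds Folds per partition (default 5).
#' @param n_repeats Number of random partitions (default 50).
#' @param svm_cost SVM cost parameter (default 1).
#' @param seed Integer seed.
#' @param partitions Optional list of precomputed fold-id vectors (overrides
#'   `n_repeats`/`seed`), used for synchronized permutation nulls.
#' @return An object of class `icn_cv`: `evaluations` (tibble, one row per
#'   test-set evaluation), `metrics` (tibble of mean/sd per metric),
#'   `config`.
#' @export
repeated_cv <- function(features, labels, k_folds = 5, n_repeats = 50,
                        svm_cost = 1, seed = 1L, partitions = NULL) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  if (k_folds < 2) stop("k_folds must be >= 2")
  if (min(sum(labels), sum(!labels)) < k_folds) {
    stop("each class needs at least k_folds members")
  }
  if (is.null(partitions)) {
    partitions <- make_partitions(labels, k_folds, n_repeats, seed)
  }
  rows <- list()
  for (r in seq_along(partitions)) {
    fold <- partitions[[r]]
    for (f in sort(unique(fold))) {
      ev <- evaluate_fold(features, labels, which(fold != f),
                          which(fold == f), svm_cost)
      m <- compute_metrics(ev$tp, ev$fn, ev$tn, ev$fp, ev$score, ev$truth)
      rows[[length(rows) + 1]] <- tibble::tibble(
        rep = r, fold = f, n_test = length(ev$truth),
        tp = ev$tp, fn = ev$fn, tn = ev$tn, fp = ev$fp,
        sensitivity = m$sensitivity, specificity = m$specificity,
        balanced_accuracy = m$balanced_accuracy, ppv = m$ppv, npv = m$npv,
        auc = m$auc, flagged = m$flagged)
    }
  }
  evaluations <- dplyr::bind_rows(rows)
  structure(list(evaluations = evaluations,
                 metrics = summarize_evaluations(evaluations),
                 config = list(k_folds = k_folds,
                               n_repeats = length(partitions),
                               svm_cost = svm_cost, seed = seed)),
            class = "icn_cv")
}

make_partitions <- function(labels, k_folds, n_repeats, seed) {
  with_seed(seed, {
    lapply(seq_len(n_repeats), function(i) stratified_folds(labels, k_folds))
  })
}

summarize_evaluations <- function(ev) {
  long <- tidyr::pivot_longer(
    ev, c("balanced_accuracy", "auc", "sensitivity", "specificity",
          "ppv", "npv"),
    names_to = "metric", values_to = "value")
  dplyr::summarise(dplyr::group_by(long, .data$metric),
                   mean = mean(.data$value, na.rm = TRUE),
                   sd = sd(.data$value, na.rm = TRUE),
                   n_defined = sum(!is.na(.data$value)),
                   .groups = "drop")
}

#' @exportS3Method base::print
print.icn_cv <- function(x, ...) {
  ba <- dplyr::filter(x$metrics, .data$metric == "balanced_accuracy")
  cat(sprintf("<icn_cv> %d evaluations (%d x %d-fold), balanced accuracy %.3f (SD %.3f)\n",
              nrow(x$evaluations), x$config$n_repeats, x$config$k_folds,
              ba$mean, ba$sd))
  invisible(x)
}

#' @rdname repeated_cv
#' @param x An `icn_cv` object.
#' @param ... Unused.
#' @export
tidy.icn_cv <- function(x, ...) x$metrics

#' @rdname repeated_cv
#' @export
glance.icn_cv <- function(x, ...) {
  w <- tidyr::pivot_wider(x$metrics[, c("metric", "mean")],
                          names_from = "metric", values_from = "mean")
  dplyr::bind_cols(w, tibble::tibble(n_evaluations = nrow(x$evaluations),
                                     k_folds = x$config$k_folds,
                                     n_repeats = x$config$n_repeats))
}

#' Leave-one-out cross-validated linear SVM
#'
#' Each subject is held out once; metrics are computed from the pooled
#' confusion counts, so sensitivity is an integer multiple of 1/(number of
#' responders) and specificity of 1/(number of non-responders).
#'
#' @inheritParams repeated_cv
#' @return A tibble of pooled metrics (one row).
#' @export
loocv_cv <- function(features, labels, svm_cost = 1) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  n <- length(labels)
  pred <- logical(n); score <- numeric(n)
  for (i in seq_len(n)) {
    ev <- evaluate_fold(features, labels, setdiff(seq_len(n), i), i, svm_cost)
    pred[i] <- (ev$tp + ev$fp) == 1
    score[i] <- ev$score
  }
  m <- compute_metrics(sum(pred & labels), sum(!pred & labels),
                       sum(!pred & !labels), sum(pred & !labels),
                       score, labels)
  tibble::tibble(balanced_accuracy = m$balanced_accuracy, auc = m$auc,
                 sensitivity = m$sensitivity, specificity = m$specificity,
                 ppv = m$ppv, npv = m$npv, n = n)
}

# lean mean balanced accuracy over evaluations (permutation-null workhorse)
cv_balanced_accuracy <- function(features, labels, partitions, cost) {
  tot <- 0; cnt <- 0
  for (fold in partitions) {
    for (f in sort(unique(fold))) {
      ev <- evaluate_fold(features, labels, which(fold != f),
                          which(fold == f), cost)
      sens <- if (ev$tp + ev$fn >= 1) ev$tp / (ev$tp + ev$fn) else NA
      spec <- if (ev$tn + ev$fp >= 1) ev$tn / (ev$tn + ev$fp) else NA
      ba <- (sens + spec) / 2
      if (!is.na(ba)) { tot <- tot + ba; cnt <- cnt + 1 }
    }
  }
  tot / cnt
}

#' Single-voxel ablation benchmark
#'
#' Inside every cross-validation training fold the feature with the largest
#' absolute two-sample t-statistic is selected (training data only), the SVM
#' is fit and tested on that single feature. The comparison against the
#' full-feature model quantifies the multivariate advantage; selection never
#' touches the test fold.
#'
#' @inheritParams repeated_cv
#' @return An `icn_cv` object; `evaluations` gains a `feature` column naming
#'   the selected feature per evaluation.
#' @export
single_voxel_ablation <- function(features, labels, k_folds = 5,
                                  n_repeats = 50, svm_cost = 1, seed = 1L,
                                  partitions = NULL) {
  features <- as.matrix(features)
  labels <- as.logical(labels)
  if (ncol(features) < 2) stop("need at least 2 features to select from")
  if (is.null(partitions)) {
    partitions <- make_partitions(labels, k_folds, n_repeats, seed)
  }
  rows <- list()
  for (r in seq_along(partitions)) {
    fold <- partitions[[r]]
    for (f in sort(unique(fold))) {
      tr <- which(fold != f); te <- which(fold == f)
      tt <- two_sample_t(features[tr, , drop = FALSE], labels[tr])
      best <- which.max(abs(tt))
      ev <- evaluate_fold(features[, best, drop = FALSE], labels, tr, te,
                          svm_cost)
      m <- compute_metrics(ev$tp, ev$fn, ev$tn, ev$fp, ev$score, ev$truth)
      rows[[length(rows) + 1]] <- tibble::tibble(
        rep = r, fold = f, n_test = length(ev$truth), feature = best,
        tp = ev$tp, fn = ev$fn, tn = ev$tn, fp = ev$fp,
        sensitivity = m$sensitivity, specificity = m$specificity,
        balanced_accuracy = m$balanced_accuracy, ppv = m$ppv, npv = m$npv,
        auc = m$auc, flagged = m$flagged)
    }
  }
  evaluations <- dplyr::bind_rows(rows)
  structure(list(evaluations = evaluations,
                 metrics = summarize_evaluations(evaluations),
                 config = list(k_folds = k_folds,
                               n_repeats = length(partitions),
                               svm_cost = svm_cost, seed = seed,
                               mode = "single_voxel")),
            class = "icn_cv")
}

# vectorized pooled-variance two-sample t per column
two_sample_t <- function(x, labels) {
  g1 <- x[labels, , drop = FALSE]
  g0 <- x[!labels, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- apply(g1, 2, var); v0 <- apply(g0, 2, var)
  sp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp * (1 / n1 + 1 / n0))
  tt <- (m1 - m0) / se
  tt[se == 0] <- 0
  tt
}
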