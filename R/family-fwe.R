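#' Assemble the family of classification analyses
#'
#' One feature set per signal component (the voxels of its individual maps
#' across subjects) plus one per network-matrix kind (the edge vectors) —
#' the family over which the synchronized-permutation familywise correction
#' runs.
#'
#' @param subject_components List of `subject_components` (one per subject,
#'   identical component order).
#' @param netmats Optional named list of per-kind netmat lists, e.g.
#'   `list(full = list_of_netmats, partial = list_of_netmats)`.
#' @param labels Length-N responder flags (subject order of the lists).
#' @return An object of class `analysis_family`: named list `feature_sets`
#'   of N x M matrices plus `labels`.
#' @export
analysis_family <- function(subject_components, netmats = NULL, labels) {
  labels <- as.logical(labels)
  n <- length(subject_components)
  stopifnot(n == length(labels))
  k_sig <- nrow(subject_components[[1]]$maps)
  sets <- list()
  for (i in seq_len(k_sig)) {
    sets[[sprintf("icn%02d", subject_components[[1]]$component[i])]] <-
      do.call(rbind, lapply(subject_components, function(s) s$maps[i, ]))
  }
  for (kind in names(netmats)) {
    sets[[paste0("netmat_", kind)]] <-
      do.call(rbind, lapply(netmats[[kind]], vectorize_edges))
  }
  if (anyDuplicated(names(sets))) stop("feature-set names must be unique")
  structure(list(feature_sets = sets, labels = labels),
            class = "analysis_family")
}

#' @exportS3Method base::print
print.analysis_family <- function(x, ...) {
  cat(sprintf("<analysis_family> %d feature sets, %d subjects (%d responders)\n",
              length(x$feature_sets), length(x$labels), sum(x$labels)))
  invisible(x)
}

#' Family of cross-validated classifications with synchronized-permutation FWE
#'
#' Runs [repeated_cv()] on every feature set, then corrects for the number
#' of analyses by a max-statistic permutation test: each permutation draws
#' one label shuffle, applies it identically (synchronized) to every feature
#' set, recomputes the repeated-CV mean balanced accuracy per set using the
#' same CV partitions as the observed statistic, and records the maximum
#' over sets. `p_fwe(set) = (1 + #(perm max >= observed)) / (1 + n_perm)`.
#'
#' @param family An [analysis_family()] (or a bare named list of N x M
#'   matrices plus `labels=`).
#' @param labels Responder flags; taken from `family` when it is an
#'   `analysis_family`.
#' @param k_folds,n_repeats,svm_cost,seed As in [repeated_cv()].
#' @param n_perm Number of label permutations (default 2000).
#' @param n_repeats_perm CV repeats used inside the permutation null and for
#'   the observed statistic entering the p-value (default `n_repeats`; the
#'   reported metrics always use all `n_repeats`). The null reuses the first
#'   `n_repeats_perm` observed partitions, which is what keeps the
#'   max-statistic correction exchangeable.
#' @return An object of class `family_result`: `results` tibble (one row per
#'   set: metrics, `observed` statistic, `p_fwe`), `null_max`, metadata.
#' @export
family_fwe <- function(family, labels = NULL, k_folds = 5, n_repeats = 50,
                       svm_cost = 1, n_perm = 2000, n_repeats_perm = NULL,
                       seed = 1L) {
  if (inherits(family, "analysis_family")) {
    labels <- family$labels
    sets <- family$feature_sets
  } else {
    sets <- family
  }
  labels <- as.logical(labels)
  if (n_perm < 100) stop("n_perm must be >= 100")
  n_repeats_perm <- n_repeats_perm %||% n_repeats
  n_repeats_perm <- min(n_repeats_perm, n_repeats)
  sets <- lapply(sets, as.matrix)
  nm <- names(sets) %||% rep("", length(sets))
  nm[nm == ""] <- sprintf("set%02d", which(nm == ""))
  names(sets) <- nm

  partitions <- make_partitions(labels, k_folds, n_repeats,
                                child_seed(seed, 1))
  perm_part <- partitions[seq_len(n_repeats_perm)]

  fits <- lapply(sets, function(x) {
    repeated_cv(x, labels, k_folds = k_folds, svm_cost = svm_cost,
                partitions = partitions)
  })

  # Linear-SVM CV depends on the features only through per-fold Gram
  # matrices; factor them once so each permutation costs O(N^2) per fold
  # regardless of the feature count (exact, not an approximation).
  prepared <- lapply(sets, prepare_fold_factors, partitions = perm_part)
  observed <- vapply(prepared, cv_balacc_prepared, 0,
                     labels = labels, cost = svm_cost)

  null_max <- with_seed(child_seed(seed, 2), {
    vapply(seq_len(n_perm), function(b) {
      yb <- labels[sample.int(length(labels))]
      vals <- vapply(prepared, cv_balacc_prepared, 0,
                     labels = yb, cost = svm_cost)
      # a shuffle can leave every fold of a set without both classes;
      # such a set contributes nothing to that permutation's maximum
      max(c(vals[is.finite(vals)], -Inf))
    }, 0)
  })
  p_fwe <- vapply(observed, function(o) {
    (1 + sum(null_max >= o)) / (1 + n_perm)
  }, 0)

  results <- dplyr::bind_rows(lapply(names(sets), function(nm) {
    g <- glance(fits[[nm]])
    tibble::tibble(feature_set = nm,
                   balanced_accuracy = g$balanced_accuracy,
                   auc = g$auc, sensitivity = g$sensitivity,
                   specificity = g$specificity, ppv = g$ppv, npv = g$npv,
                   observed = observed[[nm]], p_fwe = p_fwe[[nm]])
  }))
  structure(list(results = results, fits = fits, null_max = null_max,
                 config = list(k_folds = k_folds, n_repeats = n_repeats,
                               n_repeats_perm = n_repeats_perm,
                               svm_cost = svm_cost, n_perm = n_perm,
                               seed = seed)),
            class = "family_result")
}

#' @exportS3Method base::print
print.family_result <- function(x, ...) {
  cat(sprintf("<family_result> %d feature sets, %d permutations\n",
              nrow(x$results), x$config$n_perm))
  best <- x$results[which.min(x$results$p_fwe), ]
  cat(sprintf("  best: %s, balanced accuracy %.3f, p_fwe = %.4g\n",
              best$feature_set, best$balanced_accuracy, best$p_fwe))
  invisible(x)
}

#' @rdname family_fwe
#' @param x A `family_result`.
#' @param ... Unused.
#' @export
tidy.family_result <- function(x, ...) x$results

#' @rdname family_fwe
#' @export
glance.family_result <- function(x, ...) {
  best <- x$results[which.min(x$results$p_fwe), ]
  tibble::tibble(n_sets = nrow(x$results),
                 best_set = best$feature_set,
                 best_balanced_accuracy = best$balanced_accuracy,
                 best_p_fwe = best$p_fwe,
                 n_perm = x$config$n_perm)
}

#' Bar chart of family classification performance
#'
#' @param object A `family_result`.
#' @param alpha FWE threshold drawn as a reference (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.family_result <- function(object, alpha = 0.05, ...) {
  df <- object$results
  df$significant <- df$p_fwe <= alpha
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$feature_set, .data$balanced_accuracy),
    y = .data$balanced_accuracy, fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "mean CV balanced accuracy",
                  fill = sprintf("p_fwe <= %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' Permutation p-values for linear SVM weights
#'
#' Fits the linear SVM on the entire data set (features rescaled to [-1, 1]
#' on all subjects), then refits under label permutations; each weight is
#' normalized by its permutation mean and SD, and two-sided p-values come
#' either from the empirical normalized null (`mode = "empirical"`) or from
#' a Gaussian approximation of it (`mode = "gaussian"`). The output is for
#' visualization of which features carry the classifier, not for inference
#' on generalization.
#'
#' @param features N x M feature matrix.
#' @param labels Length-N responder flags.
#' @param n_perm Number of label permutations (default 1000).
#' @param svm_cost SVM cost (default 1).
#' @param mode "empirical" or "gaussian".
#' @param seed Integer seed.
#' @return A tibble: `feature`, `weight`, `z`, `p`; attribute
#'   `purpose = "visualization only"`.
#' @export
weight_significance <- function(features, labels, n_perm = 1000, svm_cost = 1,
                                mode = c("empirical", "gaussian"), seed = 1L) {
  mode <- match.arg(mode)
  features <- as.matrix(features)
  labels <- as.logical(labels)
  sc <- rescale_train_apply(features, features)$train
  w_obs <- svm_weights(sc, labels, svm_cost)
  wperm <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(b) {
      svm_weights(sc, labels[sample.int(length(labels))], svm_cost)
    }, numeric(ncol(sc))))
  })
  mu <- colMeans(wperm)
  sdv <- apply(wperm, 2, sd)
  sdv[sdv == 0] <- Inf
  z <- (w_obs - mu) / sdv
  p <- if (mode == "gaussian") {
    2 * pnorm(-abs(z))
  } else {
    zperm <- abs(sweep(sweep(wperm, 2, mu), 2, sdv, "/"))
    vapply(seq_along(z), function(j) {
      (1 + sum(zperm[, j] >= abs(z[j]))) / (1 + n_perm)
    }, 0)
  }
  out <- tibble::tibble(feature = seq_along(w_obs), weight = w_obs,
                        z = z, p = p)
  attr(out, "purpose") <- "visualization only"
  attr(out, "mode") <- mode
  out
}

# Per (partition, fold): rescale on the training rows, then replace the
# feature matrix by an exact low-dimensional kernel factor Z with
# Z Z' = scaled X scaled X' (row order preserved), so a linear SVM on Z is
# identical to one on the full features.
prepare_fold_factors <- function(x, partitions) {
  x <- as.matrix(x)
  out <- list()
  for (fold in partitions) {
    for (f in sort(unique(fold))) {
      tr <- which(fold != f); te <- which(fold == f)
      sc <- rescale_train_apply(x[tr, , drop = FALSE], x[te, , drop = FALSE])
      full <- matrix(0, nrow(x), ncol(x))
      full[tr, ] <- sc$train
      full[te, ] <- sc$test
      eg <- eigen(tcrossprod(full), symmetric = TRUE)
      r <- sum(eg$values > max(eg$values, 0) * 1e-10)
      z <- eg$vectors[, seq_len(r), drop = FALSE] *
        rep(sqrt(eg$values[seq_len(r)]), each = nrow(x))
      out[[length(out) + 1]] <- list(z = z, tr = tr, te = te)
    }
  }
  out
}

cv_balacc_prepared <- function(prep, labels, cost) {
  tot <- 0; cnt <- 0
  for (p in prep) {
    pred <- fit_predict(p$z[p$tr, , drop = FALSE], labels[p$tr],
                        p$z[p$te, , drop = FALSE], cost)$pred
    truth <- labels[p$te]
    sens <- if (any(truth)) sum(pred & truth) / sum(truth) else NA
    spec <- if (any(!truth)) sum(!pred & !truth) / sum(!truth) else NA
    ba <- (sens + spec) / 2
    if (!is.na(ba)) { tot <- tot + ba; cnt <- cnt + 1 }
  }
  tot / cnt
}

svm_weights <- function(x, y, cost) {
  model <- fit_svm(x, y, cost)
  as.vector(crossprod(model$coefs, model$SV))
}
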