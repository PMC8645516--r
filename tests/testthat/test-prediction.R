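test_that("train-fitted rescaling maps to [-1, 1] and extrapolates", {
  sc <- rescale_train_apply(matrix(c(0, 5, 10), 3), matrix(20, 1))
  expect_equal(sc$train[, 1], c(-1, 0, 1))
  expect_equal(sc$test[1, 1], 3)  # linear extension, no clipping
  # constant training feature maps to 0 everywhere
  sc2 <- rescale_train_apply(matrix(c(4, 4, 4), 3), matrix(9, 1))
  expect_equal(sc2$train[, 1], c(0, 0, 0))
  expect_equal(sc2$test[1, 1], 0)
})

test_that("confusion metrics reproduce the printed identities", {
  # balanced accuracy is the mean of sensitivity and specificity
  m <- compute_metrics(tp = 61, fn = 9, tn = 652, fp = 348)
  expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)

  # counts whose rates match the reported leave-one-out figures
  m2 <- compute_metrics(tp = 17, fn = 4, tn = 11, fp = 8)
  expect_equal(round(100 * m2$sensitivity, 2), 80.95)
  expect_equal(round(100 * m2$specificity, 2), 57.89)
  expect_equal(round(100 * m2$balanced_accuracy, 2), 69.42)

  perfect <- compute_metrics(10, 0, 10, 0, scores = c(rep(1, 10), rep(-1, 10)),
                             truth = rep(c(TRUE, FALSE), each = 10))
  expect_equal(unlist(perfect[c("sensitivity", "specificity",
                                "balanced_accuracy", "ppv", "npv", "auc")]),
               setNames(rep(1, 6), c("sensitivity", "specificity",
                                     "balanced_accuracy", "ppv", "npv",
                                     "auc")))
  # empty denominator flags the row
  expect_true(compute_metrics(0, 0, 5, 1)$flagged)
})

test_that("repeated CV has the right shape, determinism and chance level", {
  set.seed(1)
  lab <- labels_40()
  x <- matrix(rnorm(40 * 8), 40)
  cv <- repeated_cv(x, lab, k_folds = 5, n_repeats = 10, seed = 2)
  expect_equal(nrow(cv$evaluations), 50)
  cv2 <- repeated_cv(x, lab, k_folds = 5, n_repeats = 10, seed = 2)
  expect_identical(cv$evaluations, cv2$evaluations)

  # stratified folds: every fold contains 4-5 responders
  parts <- icnpred:::make_partitions(lab, 5, 20, 3)
  for (p in parts) {
    expect_equal(as.integer(table(p)), rep(8L, 5))
    expect_true(all(table(p[lab]) %in% 4:5))
  }

  # pure-noise features classify at chance (averaged over datasets — a
  # single 40-subject draw carries sizeable sampling variability)
  ba_null <- mean(vapply(1:4, function(i) {
    cv0 <- repeated_cv(matrix(rnorm(40 * 8), 40), lab, k_folds = 5,
                       n_repeats = 5, seed = 20 + i)
    dplyr::filter(tidy(cv0), metric == "balanced_accuracy")$mean
  }, 0))
  expect_lt(abs(ba_null - 0.5), 0.06)

  # separable features classify near-perfectly
  xs <- x; xs[lab, 1:4] <- xs[lab, 1:4] + 3
  cvs <- repeated_cv(xs, lab, k_folds = 5, n_repeats = 5, seed = 2)
  expect_gt(dplyr::filter(tidy(cvs), metric == "balanced_accuracy")$mean,
            0.95)

  # permuted labels bring a real effect back to chance
  xm <- x; xm[lab, 1:4] <- xm[lab, 1:4] + 1
  ba_perm <- mean(vapply(1:6, function(i) {
    cvp <- repeated_cv(xm, sample(lab), k_folds = 5, n_repeats = 4,
                       seed = 30 + i)
    dplyr::filter(tidy(cvp), metric == "balanced_accuracy")$mean
  }, 0))
  expect_lt(abs(ba_perm - 0.5), 0.06)
})

test_that("balanced accuracy equals the mean of sensitivity and specificity", {
  set.seed(2)
  lab <- labels_40()
  x <- matrix(rnorm(40 * 6), 40)
  x[lab, 1] <- x[lab, 1] + 1
  cv <- repeated_cv(x, lab, k_folds = 5, n_repeats = 6, seed = 4)
  ev <- cv$evaluations
  expect_equal(ev$balanced_accuracy, (ev$sensitivity + ev$specificity) / 2)
  # and therefore the averages agree wherever all rows are defined
  expect_equal(mean(ev$balanced_accuracy),
               (mean(ev$sensitivity) + mean(ev$specificity)) / 2)
})

test_that("leave-one-out metrics have the m/n rational structure", {
  set.seed(3)
  lab <- rep(c(TRUE, FALSE), c(11, 9))
  x <- matrix(rnorm(20 * 5), 20)
  x[lab, 1] <- x[lab, 1] + 1.5
  lo <- loocv_cv(x, lab)
  expect_equal(lo$sensitivity * 11, round(lo$sensitivity * 11))
  expect_equal(lo$specificity * 9, round(lo$specificity * 9))
})

test_that("family FWE agrees with a plain permutation test for one set", {
  set.seed(4)
  lab <- rep(c(TRUE, FALSE), c(8, 8))
  x <- matrix(rnorm(16 * 5), 16)
  x[lab, 1] <- x[lab, 1] + 1
  fr <- family_fwe(list(only = x), labels = lab, k_folds = 4, n_repeats = 2,
                   n_perm = 150, seed = 6)
  # independent slow-path permutation test with the same partitions/shuffles
  parts <- icnpred:::make_partitions(lab, 4, 2, icnpred:::child_seed(6, 1))
  obs <- icnpred:::cv_balanced_accuracy(x, lab, parts, 1)
  null <- icnpred:::with_seed(icnpred:::child_seed(6, 2), {
    vapply(seq_len(150), function(b) {
      icnpred:::cv_balanced_accuracy(x, lab[sample.int(16)], parts, 1)
    }, 0)
  })
  p_plain <- (1 + sum(null >= obs)) / 151
  expect_equal(fr$results$p_fwe, p_plain, tolerance = 1e-12)
})

test_that("family FWE p-values are monotone under family growth", {
  set.seed(5)
  lab <- rep(c(TRUE, FALSE), c(10, 10))
  strong <- matrix(rnorm(20 * 6), 20); strong[lab, ] <- strong[lab, ] + 1.2
  noise <- lapply(1:3, function(i) matrix(rnorm(20 * 6), 20))
  small <- family_fwe(list(strong = strong), labels = lab, k_folds = 4,
                      n_repeats = 2, n_perm = 120, seed = 7)
  big <- family_fwe(c(list(strong = strong), noise), labels = lab,
                    k_folds = 4, n_repeats = 2, n_perm = 120, seed = 7)
  expect_gte(big$results$p_fwe[big$results$feature_set == "strong"],
             small$results$p_fwe)
  # the planted set attains the family's minimum p
  expect_equal(which.min(big$results$p_fwe),
               which(big$results$feature_set == "strong"))
})

test_that("SVM weight p-values rank a planted feature and are calibrated", {
  set.seed(6)
  lab <- rep(c(TRUE, FALSE), c(15, 15))
  x <- matrix(rnorm(30 * 40), 30)
  x[lab, 7] <- x[lab, 7] + 2.5
  ws <- weight_significance(x, lab, n_perm = 300, seed = 8)
  expect_equal(which.min(ws$p), 7)
  expect_true(all(ws$p > 0 & ws$p <= 1))
  expect_equal(attr(ws, "purpose"), "visualization only")

  # null labels give approximately uniform p-values (Gaussian mode)
  xnull <- matrix(rnorm(30 * 500), 30)
  wn <- weight_significance(xnull, sample(lab), n_perm = 150, seed = 9,
                            mode = "gaussian")
  ks <- suppressWarnings(stats::ks.test(wn$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("single-voxel ablation selects on training folds only", {
  set.seed(7)
  lab <- labels_40()
  # multivariate-only effect: full model succeeds, best single voxel fails;
  # averaged over a few independent cohorts since one 40-subject draw is
  # dominated by sampling luck
  res <- t(vapply(1:8, function(i) {
    x <- multivariate_only_features(lab)
    c(full = dplyr::filter(tidy(repeated_cv(x, lab, n_repeats = 3,
                                            seed = 10 + i)),
                           metric == "balanced_accuracy")$mean,
      abl = dplyr::filter(tidy(single_voxel_ablation(x, lab, n_repeats = 3,
                                                     seed = 10 + i)),
                          metric == "balanced_accuracy")$mean)
  }, c(full = 0, abl = 0)))
  expect_gt(mean(res[, "full"]), 0.9)
  expect_lt(abs(mean(res[, "abl"]) - 0.5), 0.1)

  # leakage detector on null data: selecting the voxel on the full data
  # before cross-validating systematically inflates accuracy relative to
  # honest training-fold selection, and honest selection averages to
  # chance across datasets (any single dataset can carry a spurious
  # dataset-level association that both schemes see)
  leak <- t(vapply(1:6, function(i) {
    xn <- matrix(rnorm(40 * 200), 40)
    honest <- dplyr::filter(tidy(single_voxel_ablation(xn, lab,
                                                       n_repeats = 3,
                                                       seed = 40 + i)),
                            metric == "balanced_accuracy")$mean
    best_all <- which.max(abs(icnpred:::two_sample_t(xn, lab)))
    leaky <- dplyr::filter(tidy(repeated_cv(xn[, best_all, drop = FALSE],
                                            lab, n_repeats = 3,
                                            seed = 40 + i)),
                           metric == "balanced_accuracy")$mean
    c(honest = honest, leaky = leaky)
  }, c(honest = 0, leaky = 0)))
  expect_gt(mean(leak[, "leaky"]), mean(leak[, "honest"]) + 0.05)
  expect_lt(abs(mean(leak[, "honest"]) - 0.5), 0.15)

  # one dominant univariate feature: ablation matches the full model
  xd <- matrix(rnorm(40 * 30), 40)
  xd[lab, 12] <- xd[lab, 12] + 4
  abl_dom <- single_voxel_ablation(xd, lab, n_repeats = 4, seed = 12)
  expect_gt(dplyr::filter(tidy(abl_dom),
                          metric == "balanced_accuracy")$mean, 0.9)
  expect_true(all(abl_dom$evaluations$feature == 12))
})
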