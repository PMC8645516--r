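test_that("meta-ICA recovers the planted networks", {
  fit <- small_fit()
  truth <- fit$cohort$truth
  cc <- abs(cor(t(fit$icns$maps), t(truth$planted_maps)))
  expect_true(all(cc[cbind(fit$match, seq_len(4))] > 0.9))
  # one-to-one: every planted network claims a different component
  expect_equal(length(unique(fit$match)), 4)
})

test_that("meta-ICA is deterministic and supports the single-run mode", {
  coh <- small_cohort()
  mats <- lapply(coh$runs[1:4], mask_series)
  a <- meta_ica(mats, k = 3, n_runs = 2, seed = 5)
  b <- meta_ica(mats, k = 3, n_runs = 2, seed = 5)
  expect_identical(a$maps, b$maps)
  single <- meta_ica(mats, k = 3, n_runs = 1, seed = 5)
  expect_equal(dim(single$maps), c(3, ncol(a$maps)))
  expect_error(meta_ica(mats, k = 700, n_runs = 1, seed = 5), "rank")
})

test_that("component triage flags edge maps and honours overrides", {
  fit <- small_fit()
  icns <- fit$icns
  mask <- fit$cohort$runs[[1]]$mask
  v <- ncol(icns$maps)
  edge <- icnpred:::mask_edge(mask)[as.vector(mask)]

  # replace component 1 by a map living on the mask boundary with a fast tc
  icns2 <- icns
  m <- rep(0, v); m[edge] <- 1
  icns2$maps[1, ] <- (m - mean(m)) / sd(m)
  n <- nrow(icns2$timecourses)
  icns2$timecourses[, 1] <- rnorm(n)  # white noise: ~75% power above 0.1 Hz
  out <- triage_components(icns2, mask)
  expect_equal(out$labels[1], "noise")
  # planted smooth interior blobs with slow time courses stay signal
  expect_true(all(out$labels[-1] == "signal"))
  # override wins over heuristics
  forced <- triage_components(icns2, mask, override = list("1" = "signal"))
  expect_equal(forced$labels[1], "signal")
})

test_that("constrained reconstruction recovers a planted source", {
  set.seed(8)
  v <- 600; t_len <- 120
  ref <- rnorm(v)
  tc_true <- rnorm(t_len)
  x <- tcrossprod(ref, tc_true) + matrix(rnorm(v * t_len, 0, 0.05), v)
  vtm <- structure(list(values = x, voxel_index = cbind(1:v, 1, 1),
                        grid_shape = c(v, 1, 1),
                        mask = array(TRUE, c(v, 1, 1)), tr_s = 2),
                   class = "voxel_time_matrix")
  fit <- gig_ica_reconstruct(vtm, ref)
  expect_gt(abs(cor(fit$map, ref)), 0.99)
  expect_gt(abs(cor(fit$timecourse, tc_true)), 0.95)

  # two planted sources: the reference steers which one is extracted
  src_a <- rnorm(v); src_b <- rnorm(v)
  x2 <- tcrossprod(src_a, rnorm(t_len)) + tcrossprod(src_b, rnorm(t_len)) +
    matrix(rnorm(v * t_len, 0, 0.05), v)
  vtm2 <- vtm; vtm2$values <- x2
  fit_a <- gig_ica_reconstruct(vtm2, src_a)
  expect_gt(abs(cor(fit_a$map, src_a)), 0.9)
  expect_lt(abs(cor(fit_a$map, src_b)), 0.3)

  vtm0 <- vtm; vtm0$values <- matrix(0, v, t_len)
  expect_error(gig_ica_reconstruct(vtm0, ref), "zero-variance")
})

test_that("back-reconstruction is consistent with the group decomposition", {
  fit <- small_fit()
  subj_maps <- lapply(fit$subjects, function(s) s$maps)
  avg <- Reduce(`+`, subj_maps) / length(subj_maps)
  for (i in seq_len(nrow(avg))) {
    expect_gt(abs(cor(avg[i, ], fit$icns$maps[i, ])), 0.8)
  }
  # within-subject maps near-uncorrelated across components
  for (s in fit$subjects[1:3]) {
    cm <- cor(t(s$maps))
    expect_lt(max(abs(cm[upper.tri(cm)])), 0.3)
  }
})

test_that("individual time courses track the planted ones", {
  fit <- small_fit()
  truth <- fit$cohort$truth
  for (s in seq_along(fit$subjects)[1:4]) {
    tc_hat <- fit$subjects[[s]]$timecourses
    for (k in seq_len(4)) {
      expect_gt(abs(cor(tc_hat[, fit$match[k]],
                        truth$planted_timecourses[[s]][, k])), 0.9)
    }
  }
})
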