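# Shared small synthetic cohorts, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- builder()
  .cohort_cache[[key]]
}

# 12-subject, 4-network cohort with a strong planted edge and a map effect
small_cohort <- function() {
  cached("small", function() {
    spec <- cohort_spec(
      n_subjects = 12, n_responders = 6, grid_shape = c(10, 10, 6),
      n_volumes = 150, k_networks = 4, seed = 42,
      edge_effect = list(pair = c(1, 2), delta_z = 0.8, base_z = 0.1,
                         stronger = "nonresponder"),
      map_effect = list(network = 3, magnitude = 0.15))
    generate_cohort(spec)
  })
}

small_fit <- function() {
  cached("small_fit", function() {
    coh <- small_cohort()
    mats <- lapply(coh$runs, mask_series)
    icns <- meta_ica(mats, k = 4, n_runs = 3, seed = 7)
    subjects <- lapply(seq_along(mats), function(s) {
      reconstruct_subject(mats[[s]], icns,
                          coh$participants$participant_id[s])
    })
    cc <- cor(t(icns$maps), t(coh$truth$planted_maps))
    list(cohort = coh, mats = mats, icns = icns, subjects = subjects,
         # component index matched to each planted network
         match = apply(abs(cc), 2, which.max))
  })
}

# Default-scale cohort (40 subjects, 16 x 16 x 12 grid, T = 200, K = 6)
# run through cleanup, meta-ICA and back-reconstruction.
default_fit <- function() {
  cached("default_fit", function() {
    coh <- generate_cohort(cohort_spec(seed = 101))
    cfg <- default_config()
    prepped <- lapply(coh$runs, function(run) {
      run <- smooth_bold(run, cfg$prep$fwhm_mm, cfg$prep$voxel_size_mm)
      run <- grand_mean_scale(run, cfg$prep$grand_mean)
      vtm <- mask_series(run)
      ns <- build_nuisance(t_len = ncol(vtm$values), tr_s = run$tr_s,
                           cutoff_s = cfg$prep$cutoff_s)
      regress_out(vtm, ns)
    })
    icns <- meta_ica(prepped, k = 6, n_runs = 5, seed = 102)
    subjects <- lapply(seq_along(prepped), function(s) {
      reconstruct_subject(prepped[[s]], icns,
                          coh$participants$participant_id[s])
    })
    # planted maps seen through the same smoothing kernel: the effective
    # spatial ground truth for data that entered the pipeline smoothed
    g <- coh$truth$grid_shape
    smoothed_truth <- t(apply(coh$truth$planted_maps, 1, function(m) {
      run <- bold_run(array(rep(m, 2), c(g, 2)),
                      array(TRUE, g), coh$runs[[1]]$tr_s)
      as.vector(smooth_bold(run, cfg$prep$fwhm_mm,
                            cfg$prep$voxel_size_mm)$data[, , , 1])
    }))
    # planted time courses seen through the same cosine highpass: the
    # effective temporal ground truth for filtered data
    ns <- build_nuisance(t_len = coh$truth$spec$n_volumes,
                         tr_s = coh$runs[[1]]$tr_s,
                         cutoff_s = cfg$prep$cutoff_s)
    qx <- qr(cbind(1, ns$regressors))
    filtered_tc <- lapply(coh$truth$planted_timecourses,
                          function(tc) qr.resid(qx, tc))
    cc <- cor(t(icns$maps), t(smoothed_truth))
    list(cohort = coh, mats = prepped, icns = icns, subjects = subjects,
         smoothed_truth = smoothed_truth, filtered_tc = filtered_tc,
         match = apply(abs(cc), 2, which.max))
  })
}

# labels mimicking the target cohort split
labels_40 <- function() rep(c(TRUE, FALSE), c(21, 19))

# feature matrix with a multivariate-only group effect: pairs of features
# share almost all their noise and carry opposite-signed small shifts, so no
# single feature separates the groups but their contrast does
multivariate_only_features <- function(labels, n_pairs = 20, delta = 0.15,
                                       rho = 0.998) {
  n <- length(labels)
  x <- matrix(0, n, 2 * n_pairs)
  for (p in seq_len(n_pairs)) {
    shared <- rnorm(n)
    e1 <- sqrt(1 - rho) * rnorm(n)
    e2 <- sqrt(1 - rho) * rnorm(n)
    s <- ifelse(labels, delta, -delta)
    x[, 2 * p - 1] <- sqrt(rho) * shared + e1 + s
    x[, 2 * p] <- sqrt(rho) * shared + e2 - s
  }
  x
}
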