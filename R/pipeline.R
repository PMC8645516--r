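stage_try <- function(stage, subject = NULL, expr) {
  tryCatch(expr, error = function(e) {
    who <- if (is.null(subject)) stage else sprintf("%s [%s]", stage, subject)
    stop(sprintf("pipeline stage '%s' failed: %s", who, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes, in order and per the configuration: signal cleanup (smoothing,
#' grand-mean scaling, nuisance regression with cosine highpass), group
#' meta-ICA with triage, per-subject back-reconstruction, full/partial
#' netmats, group permutation inference (TFCE maxT on within-network maps,
#' maxT on edges) and the cross-validated SVM prediction family with
#' synchronized-permutation FWE. Identical cohort + config yield an
#' identical report.
#'
#' @param cohort Output of [generate_cohort()], or a list with `runs`
#'   (list of [bold_run()]) and `participants` (tibble with `participant_id`,
#'   `group`, `age`, `gender`, `caps_pre`).
#' @param config A [default_config()]-style list.
#' @param out_dir Optional directory; when given, netmats (TSV), statistic
#'   maps (NIfTI), the JSON report and the run manifest are written there.
#' @param stages Character subset of
#'   `c("prep", "ica", "netmats", "group", "predict")`.
#' @param nuisance Optional per-subject list of `list(wm=, csf=, removed=)`
#'   time series entering [build_nuisance()].
#' @param k Number of ICA components; defaults to `config$ica$k`.
#' @return A list with `icns`, `subjects`, `netmats`, `group`, `prediction`,
#'   `report` and `manifest`.
#' @export
run_pipeline <- function(cohort, config = default_config(), out_dir = NULL,
                         stages = c("prep", "ica", "netmats", "group",
                                    "predict"),
                         nuisance = NULL, k = NULL) {
  t0 <- Sys.time()
  runs <- cohort$runs
  participants <- cohort$participants
  labels <- participants$group == "responder"
  n <- length(runs)
  k <- k %||% config$ica$k

  mats <- vector("list", n)
  for (s in seq_len(n)) {
    id <- participants$participant_id[s]
    mats[[s]] <- stage_try("prep", id, {
      run <- runs[[s]]
      if ("prep" %in% stages) {
        run <- smooth_bold(run, config$prep$fwhm_mm, config$prep$voxel_size_mm)
        run <- grand_mean_scale(run, config$prep$grand_mean)
        vtm <- mask_series(run)
        nu <- nuisance[[s]] %||% list(wm = NULL, csf = NULL, removed = NULL)
        ns <- build_nuisance(nu$wm, nu$csf, t_len = ncol(vtm$values),
                             tr_s = run$tr_s, cutoff_s = config$prep$cutoff_s,
                             removed = nu$removed)
        regress_out(vtm, ns)
      } else {
        mask_series(run)
      }
    })
  }

  icns <- stage_try("ica", NULL, {
    out <- meta_ica(mats, k = k, n_runs = config$ica$n_runs,
                    seed = child_seed(config$seed, 11))
    triage_components(out, runs[[1]]$mask,
                      hf_threshold = config$ica$hf_threshold,
                      edge_threshold = config$ica$edge_threshold,
                      freq_hz = config$ica$freq_hz)
  })

  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    subjects[[s]] <- stage_try("reconstruct",
                               participants$participant_id[s], {
      reconstruct_subject(mats[[s]], icns,
                          subject_id = participants$participant_id[s])
    })
  }

  nm_full <- nm_partial <- NULL
  if ("netmats" %in% stages || "group" %in% stages || "predict" %in% stages) {
    nm_full <- lapply(subjects, function(sc) {
      stage_try("netmats", sc$subject_id,
                full_corr(sc$timecourses, subject_id = sc$subject_id))
    })
    nm_partial <- lapply(subjects, function(sc) {
      stage_try("netmats", sc$subject_id,
                partial_corr_ridge(sc$timecourses, rho = config$netmats$rho,
                                   subject_id = sc$subject_id))
    })
  }

  design <- glm_design(labels,
                       participants[, c("age", "gender", "caps_pre")])

  group <- NULL
  if ("group" %in% stages) {
    group <- stage_try("group", NULL, {
      scheme <- perm_scheme(n, config$group$n_perm,
                            seed = child_seed(config$seed, 21))
      edge_feats <- cbind(
        do.call(rbind, lapply(nm_full, vectorize_edges)),
        do.call(rbind, lapply(nm_partial, vectorize_edges)))
      n_edge <- ncol(edge_feats) / 2
      edge_family <- list(
        list(cols = seq_len(n_edge), mask = NULL, name = "full"),
        list(cols = n_edge + seq_len(n_edge), mask = NULL, name = "partial"))
      edges <- perm_maxT(edge_feats, design, scheme, family = edge_family)

      sig <- which(icns$labels == "signal")
      map_feats <- do.call(cbind, lapply(seq_along(sig), function(i) {
        do.call(rbind, lapply(subjects, function(sc) sc$maps[i, ]))
      }))
      v <- ncol(subjects[[1]]$maps)
      map_family <- lapply(seq_along(sig), function(i) {
        list(cols = (i - 1) * v + seq_len(v), mask = runs[[1]]$mask,
             name = sprintf("icn%02d", sig[i]))
      })
      maps <- perm_maxT(map_feats, design, scheme,
                        tfce_params = config$group$tfce, family = map_family)
      list(edges = edges, maps = maps,
           edge_index = edge_index(sum(icns$labels == "signal")))
    })
  }

  prediction <- NULL
  if ("predict" %in% stages) {
    prediction <- stage_try("predict", NULL, {
      fam <- analysis_family(subjects,
                             list(full = nm_full, partial = nm_partial),
                             labels)
      family_fwe(fam, k_folds = config$predict$k_folds,
                 n_repeats = config$predict$n_repeats,
                 svm_cost = config$predict$svm_cost,
                 n_perm = config$predict$n_perm,
                 n_repeats_perm = config$predict$n_repeats_perm,
                 seed = child_seed(config$seed, 31))
    })
  }

  manifest <- list(
    config = config, seed = config$seed,
    stage_seeds = list(ica = child_seed(config$seed, 11),
                       group = child_seed(config$seed, 21),
                       predict = child_seed(config$seed, 31)),
    n_subjects = n, n_components = k,
    n_signal = sum(icns$labels == "signal"),
    package_version = as.character(utils::packageVersion("icnpred")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  report <- list(
    participants = as.list(participants[, c("participant_id", "group")]),
    components = list(k_total = icns$k_total, labels = icns$labels),
    prediction = if (!is.null(prediction)) {
      as.list(tidy(prediction))
    },
    group_edges = if (!is.null(group)) {
      list(stat = group$edges$stat, p_fwe = group$edges$p_fwe)
    },
    group_maps_min_p = if (!is.null(group)) {
      min(group$maps$p_fwe)
    },
    parameters = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in seq_len(n)) {
      utils::write.table(
        nm_full[[s]]$z,
        file.path(out_dir, sprintf("%s_netmat_full.tsv",
                                   participants$participant_id[s])),
        sep = "\t", row.names = FALSE, col.names = FALSE)
    }
    if (!is.null(group)) {
      v <- ncol(icns$maps)
      g <- dim(runs[[1]]$mask)
      sig <- which(icns$labels == "signal")
      stat4d <- array(0, dim = c(g, length(sig)))
      for (i in seq_along(sig)) {
        img <- array(0, dim = g)
        img[runs[[1]]$mask] <- group$maps$stat[(i - 1) * v + seq_len(v)]
        stat4d[, , , i] <- img
      }
      img <- RNifti::asNifti(stat4d)
      RNifti::writeNifti(img, file.path(out_dir, "group_stat_maps.nii.gz"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(icns = icns, subjects = subjects,
       netmats = list(full = nm_full, partial = nm_partial),
       group = group, prediction = prediction,
       report = report, manifest = manifest)
}
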