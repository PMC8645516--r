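#' Read a 4D BOLD run from NIfTI
#'
#' @param path Path to a 4D `.nii`/`.nii.gz` image.
#' @param mask_path Optional companion 3D mask image; when `NULL`, all
#'   voxels are in-mask.
#' @param tr_s Optional TR override in seconds; by default read from the
#'   NIfTI header (pixdim[4]), with the JSON sidecar (if present) taking
#'   precedence.
#' @return A [bold_run()].
#' @export
read_bold <- function(path, mask_path = NULL, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop("expected a 4D image: ", path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (is.null(tr_s)) {
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      tr_s <- meta$tr_s %||% meta$RepetitionTime
    }
    if (is.null(tr_s)) {
      pd <- RNifti::pixdim(img)
      if (length(pd) >= 4 && pd[4] > 0) tr_s <- pd[4]
    }
    if (is.null(tr_s)) {
      stop("TR not recorded in header or sidecar; pass tr_s explicitly")
    }
  }
  mask <- if (is.null(mask_path)) {
    array(TRUE, dim = dim(arr)[1:3])
  } else {
    m <- as.array(RNifti::readNifti(mask_path))
    if (!all(dim(m)[1:3] == dim(arr)[1:3])) {
      stop("mask dimensions do not match the BOLD image")
    }
    array(m > 0, dim = dim(arr)[1:3])
  }
  bold_run(arr, mask, as.numeric(tr_s))
}

#' Write a BOLD run to NIfTI (with a JSON sidecar)
#'
#' The sidecar records the TR and the flattening convention (0-based voxel
#' indices, column-major / x-fastest order).
#'
#' @param run A [bold_run()].
#' @param path Output `.nii.gz` path.
#' @param voxel_size_mm Voxel edge lengths written to the header.
#' @return `path`, invisibly.
#' @export
write_bold <- function(run, path, voxel_size_mm = c(2, 2, 2)) {
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(voxel_size_mm, run$tr_s)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(tr_s = run$tr_s, voxel_size_mm = voxel_size_mm,
         index_base = 0, flattening = "column-major (x fastest)"),
    sub("\\.nii(\\.gz)?$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' Write a 3D mask to NIfTI
#'
#' @param mask 3D logical array.
#' @param path Output path.
#' @param voxel_size_mm Voxel edge lengths.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, voxel_size_mm = c(2, 2, 2)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write the participants table
#'
#' Tab-separated with columns participant_id, group, age, gender, caps_pre,
#' caps_post; ids must be unique.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_participants <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (anyDuplicated(df$participant_id)) stop("duplicate participant ids")
  tibble::as_tibble(df)
}

#' @rdname read_participants
#' @param participants A data frame.
#' @export
write_participants <- function(participants, path) {
  utils::write.table(participants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Emits per-subject 4D NIfTI images (with sidecars), the brain mask,
#' `participants.tsv` and `truth.json` (planted maps, time courses, labels,
#' target correlations) into `dir`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(cohort$runs)) {
    write_bold(cohort$runs[[s]],
               file.path(dir, sprintf("%s_bold.nii.gz",
                                      cohort$participants$participant_id[s])))
  }
  write_mask(cohort$runs[[1]]$mask, file.path(dir, "mask.nii.gz"))
  write_participants(cohort$participants, file.path(dir, "participants.tsv"))
  tr <- cohort$truth
  jsonlite::write_json(
    list(planted_maps = tr$planted_maps,
         pattern = tr$pattern,
         grid_shape = tr$grid_shape,
         planted_timecourses = tr$planted_timecourses,
         true_labels = tr$true_labels,
         true_edge_corr = tr$true_edge_corr,
         spec = tr$spec[setdiff(names(tr$spec), "network_geometry")]),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Default pipeline configuration
#'
#' Mirrors every tunable the pipeline exposes: smoothing FWHM 6 mm,
#' grand-mean target 10000, highpass cutoff 128 s, component count 70
#' (desk-scale synthetic runs use the planted count), netmat ridge rho 0.1,
#' 5 folds x 50 repeats, SVM cost 1, permutation counts 2000 (family) /
#' 10000 (group maxT), TFCE H 2 / E 0.5 / 26-connectivity.
#'
#' @param ... Overrides merged over the defaults (nested lists merged one
#'   level deep).
#' @return Named list of configuration blocks.
#' @export
default_config <- function(...) {
  cfg <- list(
    prep = list(fwhm_mm = 6, voxel_size_mm = c(2, 2, 2),
                grand_mean = 10000, cutoff_s = 128),
    ica = list(k = 70, n_runs = 25,
               hf_threshold = 0.5, edge_threshold = 0.5, freq_hz = 0.1),
    netmats = list(rho = 0.1),
    group = list(n_perm = 10000,
                 tfce = list(H = 2, E = 0.5, connectivity = 26)),
    predict = list(k_folds = 5, n_repeats = 50, svm_cost = 1,
                   n_perm = 2000, n_repeats_perm = NULL),
    seed = 1L)
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      modifyList(cfg[[nm]], dots[[nm]])
    } else dots[[nm]]
  }
  cfg
}

#' Read a YAML pipeline configuration
#'
#' Keys absent from the file fall back to [default_config()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}
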