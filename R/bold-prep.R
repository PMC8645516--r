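#' Extract the in-mask voxel-by-time matrix from a BOLD run
#'
#' @param run A [bold_run()].
#' @return An object of class `voxel_time_matrix`: list with `values` (V x T),
#'   `voxel_index` (V x 3 integer matrix of 1-based grid coordinates, ordered
#'   by column-major flattening of the grid), `grid_shape`, `mask`, `tr_s`.
#' @export
mask_series <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  g <- dim(run$data)[1:3]
  flat <- matrix(run$data, ncol = dim(run$data)[4])
  keep <- which(as.vector(run$mask))
  idx <- arrayInd(keep, g)
  structure(list(values = flat[keep, , drop = FALSE],
                 voxel_index = idx, grid_shape = g, mask = run$mask,
                 tr_s = run$tr_s),
            class = "voxel_time_matrix")
}

#' Put an in-mask voxel-by-time matrix back on the grid
#'
#' @param vtm A `voxel_time_matrix`.
#' @return A [bold_run()].
#' @export
unmask_series <- function(vtm) {
  g <- vtm$grid_shape
  t_len <- ncol(vtm$values)
  out <- matrix(0, prod(g), t_len)
  out[as.vector(vtm$mask), ] <- vtm$values
  bold_run(array(out, dim = c(g, t_len)), vtm$mask, vtm$tr_s)
}

# 1D normalized Gaussian convolution along one array dimension.  Edge
# truncation is renormalized (convolve data and ones, divide) so constants
# pass through unchanged.
gauss_smooth_axis <- function(arr, sigma_vox, axis) {
  if (sigma_vox <= 0) return(arr)
  half <- max(1L, ceiling(4 * sigma_vox))
  kern <- exp(-((-half:half)^2) / (2 * sigma_vox^2))
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  x <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(x, nrow = n)
  num <- apply_kernel(m, kern)
  den <- apply_kernel(matrix(1, n, 1), kern)[, 1]
  out <- num / den
  aperm(array(out, dim = d[perm]), order(perm))
}

apply_kernel <- function(m, kern) {
  half <- (length(kern) - 1L) / 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kern)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kern[j] * m[src[ok], , drop = FALSE]
  }
  out
}

#' Spatial Gaussian smoothing of a BOLD run
#'
#' Convolves every volume with an isotropic Gaussian kernel of the given
#' full-width-at-half-maximum, converted to voxel units through the voxel
#' size: sigma = fwhm / (2 sqrt(2 ln 2)) / voxel size. The mask is unchanged.
#'
#' @param run A [bold_run()].
#' @param fwhm_mm Kernel FWHM in millimetres (default 6).
#' @param voxel_size_mm Voxel edge lengths in millimetres (length 1 or 3).
#' @return A smoothed [bold_run()].
#' @export
smooth_bold <- function(run, fwhm_mm = 6, voxel_size_mm = c(2, 2, 2)) {
  stopifnot(inherits(run, "bold_run"))
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (fwhm_mm == 0) return(run)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  out <- run$data
  for (t in seq_len(dim(out)[4])) {
    vol <- out[, , , t]
    for (ax in 1:3) vol <- gauss_smooth_axis(vol, sigma_vox[ax], ax)
    out[, , , t] <- vol
  }
  bold_run(out, run$mask, run$tr_s)
}

#' Grand-mean scaling
#'
#' Rescales the run so its grand mean (mean over in-mask voxels and time)
#' equals `target` (default 10000).
#'
#' @param run A [bold_run()].
#' @param target Target grand mean.
#' @return A rescaled [bold_run()].
#' @export
grand_mean_scale <- function(run, target = 10000) {
  stopifnot(inherits(run, "bold_run"))
  flat <- matrix(run$data, ncol = dim(run$data)[4])
  gm <- mean(flat[as.vector(run$mask), ])
  if (gm <= 0) stop("in-mask grand mean must be positive")
  bold_run(run$data * (target / gm), run$mask, run$tr_s)
}

#' Build the nuisance regressor set
#'
#' Assembles WM mean, CSF mean and a discrete-cosine highpass basis with
#' `k = floor(2 * T * TR / cutoff_s)` functions, then residualizes every
#' column against an already-removed noise subspace (e.g. ICA-AROMA time
#' courses) so that regressing the set out cannot reintroduce that noise.
#'
#' @param wm,csf Tissue-average time series (length T); either may be `NULL`.
#' @param t_len Number of time points T.
#' @param tr_s Repetition time in seconds.
#' @param cutoff_s Highpass cutoff period in seconds (default 128).
#' @param removed Optional T x A matrix of already-removed noise regressors.
#' @return An object of class `nuisance_set`: list with `regressors` (T x R,
#'   named columns) and `orthogonalized_against`.
#' @export
build_nuisance <- function(wm = NULL, csf = NULL, t_len, tr_s,
                           cutoff_s = 128, removed = NULL) {
  for (v in list(wm, csf)) {
    if (!is.null(v) && length(v) != t_len) stop("tissue series length != t_len")
  }
  if (cutoff_s <= 2 * tr_s) stop("cutoff_s must exceed 2 * tr_s")
  k <- floor(2 * t_len * tr_s / cutoff_s)
  cols <- list()
  if (!is.null(wm)) cols$wm <- as.numeric(wm)
  if (!is.null(csf)) cols$csf <- as.numeric(csf)
  if (k >= 1) {
    tt <- seq_len(t_len) - 1
    for (j in seq_len(k)) {
      cols[[sprintf("cos%02d", j)]] <- cos(pi * (2 * tt + 1) * j / (2 * t_len))
    }
  } else {
    warning("highpass cutoff yields no cosine functions; WM/CSF-only set")
  }
  x <- do.call(cbind, cols)
  if (!is.null(removed) && ncol(as.matrix(removed)) > 0) {
    removed <- as.matrix(removed)
    if (nrow(removed) != t_len) stop("removed has wrong number of rows")
    sv <- svd(removed)
    keep <- sv$d > max(sv$d) * 1e-10
    u <- sv$u[, keep, drop = FALSE]
    x <- x - u %*% crossprod(u, x)
  } else {
    removed <- NULL
  }
  structure(list(regressors = x, orthogonalized_against = removed),
            class = "nuisance_set")
}

#' Regress nuisance signal out of a voxel-by-time matrix
#'
#' Replaces every voxel time series by its least-squares residual against
#' an intercept plus the nuisance regressors (confound regression combined
#' with cosine highpass filtering in a single step).
#'
#' @param vtm A `voxel_time_matrix` from [mask_series()].
#' @param nuis A `nuisance_set` from [build_nuisance()].
#' @return The residualized `voxel_time_matrix`.
#' @export
regress_out <- function(vtm, nuis) {
  stopifnot(inherits(vtm, "voxel_time_matrix"), inherits(nuis, "nuisance_set"))
  t_len <- ncol(vtm$values)
  if (nrow(nuis$regressors) != t_len) stop("time dimensions disagree")
  x <- cbind(intercept = 1, nuis$regressors)
  qx <- qr(x)
  res <- t(qr.resid(qx, t(vtm$values)))
  out <- vtm
  out$values <- res
  out
}
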