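# Fixed-point ICA (logcosh nonlinearity, symmetric decorrelation) on a data
# matrix with observations in rows and samples in columns.  Returns k sources
# (rows) over the samples.  Used as the engine inside meta_ica().
fast_ica_core <- function(x, k, max_iter = 500, tol = 1e-5) {
  n <- nrow(x); p <- ncol(x)
  x <- x - rowMeans(x)
  cv <- tcrossprod(x) / p
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-9
  if (sum(pos) < k) stop("requested more components than the data rank")
  kmat <- diag(1 / sqrt(eg$values[seq_len(k)]), k) %*%
    t(eg$vectors[, seq_len(k), drop = FALSE])
  z <- kmat %*% x  # k x p, white
  w <- matrix(rnorm(k * k), k, k)
  w <- sym_decorrelate(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    y <- w %*% z
    gy <- tanh(y)
    w_new <- gy %*% t(z) / p - diag(rowMeans(1 - gy^2), k) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(sources = w %*% z, converged = converged)
}

# spatial-PCA reduction of one subject's V x T matrix to its leading r1
# principal spatial components (columns demeaned over voxels)
reduce_subject <- function(values, r1) {
  x <- sweep(values, 2, colMeans(values))
  ev <- eigen(crossprod(x), symmetric = TRUE)
  r1 <- min(r1, sum(ev$values > max(ev$values) * 1e-10))
  x %*% ev$vectors[, seq_len(r1), drop = FALSE]
}

sym_decorrelate <- function(w) {
  sv <- svd(w)
  sv$u %*% t(sv$v)
}

# unit-variance rows, sign set so the largest-magnitude weight is positive
normalize_maps <- function(maps) {
  maps <- maps - rowMeans(maps)
  maps <- maps / apply(maps, 1, sd)
  sgn <- sign(maps[cbind(seq_len(nrow(maps)), max.col(abs(maps)))])
  maps * sgn
}

#' Group-level meta-ICA
#'
#' Runs `n_runs` spatial ICA decompositions on temporally concatenated,
#' subject-bootstrapped data (fresh random initialization per run), stacks
#' the resulting spatial maps, and applies a final ICA with `k` components to
#' the stack. This resampling-and-recombination scheme yields group component
#' maps that are stable against subject sampling and ICA initialization.
#' With `n_runs = 1` it degenerates to a single concatenated group ICA.
#'
#' Before concatenation each subject is reduced by a spatial-PCA step
#' (`subject_rank` leading components), the standard economy that makes
#' group ICA tractable; the reduction is computed once per subject and
#' reused across bootstrap runs.
#'
#' @param mats List of `voxel_time_matrix` objects (one per subject, same
#'   mask).
#' @param k Number of components.
#' @param n_runs Number of resampled ICA runs (default 25).
#' @param seed Integer seed controlling bootstrap draws and initializations.
#' @param subject_rank Per-subject PCA rank retained before concatenation
#'   (default `max(ceiling(1.5 k), k + 5)`, capped at T - 1).
#' @return An object of class `group_icn_set`: `maps` (k x V, unit-variance
#'   rows, positive peak), `labels` (all "signal" until triaged),
#'   `timecourses` (concatenated group time courses, T_total x k), `tr_s`,
#'   `k_total`, and `provenance`.
#' @export
meta_ica <- function(mats, k, n_runs = 25, seed = 1L, subject_rank = NULL) {
  stopifnot(length(mats) >= 1, k >= 1, n_runs >= 1)
  with_seed(seed, {
    n_sub <- length(mats)
    r1 <- subject_rank %||%
      min(max(ceiling(1.5 * k), k + 5), ncol(mats[[1]]$values) - 1)
    reduced <- lapply(mats, function(m) reduce_subject(m$values, r1))
    if (k > sum(vapply(reduced, ncol, 0L))) {
      stop("requested more components than the data rank")
    }
    run_maps <- vector("list", n_runs)
    failed <- 0
    for (r in seq_len(n_runs)) {
      pick <- if (n_runs == 1) seq_len(n_sub) else
        sample.int(n_sub, n_sub, replace = TRUE)
      x <- t(do.call(cbind, reduced[pick]))
      # fresh random initialization; up to three restarts on non-convergence
      fit <- NULL
      for (attempt in 1:3) {
        cand <- tryCatch(fast_ica_core(x, k), error = function(e) NULL)
        if (!is.null(cand) && (is.null(fit) || cand$converged)) fit <- cand
        if (!is.null(fit) && fit$converged) break
      }
      if (is.null(fit) || !fit$converged) failed <- failed + 1
      if (!is.null(fit)) run_maps[[r]] <- fit$sources
    }
    if (failed > n_runs / 2) {
      stop(sprintf("ICA failed to converge in %d of %d runs", failed, n_runs))
    }
    stack <- do.call(rbind, run_maps)
    maps <- if (n_runs == 1) stack else fast_ica_core(stack, k)$sources
    maps <- normalize_maps(maps)

    xall <- do.call(cbind, lapply(mats, function(m) m$values))  # V x T_total
    tc <- t(solve(tcrossprod(maps), maps %*% xall))             # T_total x k
    structure(list(maps = maps,
                   labels = rep("signal", k),
                   timecourses = tc,
                   tr_s = mats[[1]]$tr_s,
                   k_total = k,
                   provenance = list(n_runs = n_runs, seed = seed,
                                     n_subjects = n_sub,
                                     failed_runs = failed)),
              class = "group_icn_set")
  })
}

#' @exportS3Method base::print
print.group_icn_set <- function(x, ...) {
  cat(sprintf("<group_icn_set> %d components (%d signal), %d voxels\n",
              x$k_total, sum(x$labels == "signal"), ncol(x$maps)))
  invisible(x)
}

# fraction of spectral power above freq_hz (DC excluded)
hf_power_fraction <- function(tc, tr_s, freq_hz) {
  n <- length(tc)
  pw <- Mod(fft(tc - mean(tc)))^2
  half <- 2:floor(n / 2 + 1)
  freqs <- (half - 1) / (n * tr_s)
  sum(pw[half][freqs > freq_hz]) / sum(pw[half])
}

#' Signal/noise triage of group components
#'
#' A simple, documented stand-in for the semi-automatic component
#' classification used in practice: a component is called noise when the
#' high-frequency power fraction of its group time course exceeds
#' `hf_threshold`, or when the fraction of its map energy lying on the mask
#' edge exceeds `edge_threshold`. A manual `override` list (component index
#' to `"signal"` or `"noise"`) always wins.
#'
#' @param icns A `group_icn_set`.
#' @param mask 3D logical brain mask (defines edge voxels).
#' @param hf_threshold High-frequency power fraction above which a component
#'   is noise (default 0.5).
#' @param edge_threshold Edge-energy fraction above which a component is
#'   noise (default 0.5).
#' @param freq_hz High-frequency boundary in Hz (default 0.1).
#' @param override Named list/vector, e.g. `list("3" = "signal")`.
#' @return The `group_icn_set` with `labels` filled in.
#' @export
triage_components <- function(icns, mask, hf_threshold = 0.5,
                              edge_threshold = 0.5, freq_hz = 0.1,
                              override = list()) {
  stopifnot(inherits(icns, "group_icn_set"))
  edge <- mask_edge(mask)[as.vector(mask)]
  labels <- character(icns$k_total)
  for (i in seq_len(icns$k_total)) {
    hf <- hf_power_fraction(icns$timecourses[, i], icns$tr_s, freq_hz)
    en <- icns$maps[i, ]^2
    ef <- sum(en[edge]) / sum(en)
    labels[i] <- if (hf > hf_threshold || ef > edge_threshold) "noise" else "signal"
  }
  for (nm in names(override)) labels[as.integer(nm)] <- override[[nm]]
  icns$labels <- labels
  icns
}

# in-mask voxels with any 6-neighbour outside the mask or the grid
mask_edge <- function(mask) {
  g <- dim(mask)
  pad <- array(FALSE, g + 2)
  pad[2:(g[1] + 1), 2:(g[2] + 1), 2:(g[3] + 1)] <- mask
  inner <- pad[2:(g[1] + 1), 2:(g[2] + 1), 2:(g[3] + 1)]
  nb <- pad[1:g[1], 2:(g[2] + 1), 2:(g[3] + 1)] &
    pad[3:(g[1] + 2), 2:(g[2] + 1), 2:(g[3] + 1)] &
    pad[2:(g[1] + 1), 1:g[2], 2:(g[3] + 1)] &
    pad[2:(g[1] + 1), 3:(g[2] + 2), 2:(g[3] + 1)] &
    pad[2:(g[1] + 1), 2:(g[2] + 1), 1:g[3]] &
    pad[2:(g[1] + 1), 2:(g[2] + 1), 3:(g[3] + 2)]
  inner & !nb
}

# E[log cosh(Z)] for standard normal Z (negentropy baseline)
logcosh_gauss <- 0.3745672

#' Spatially constrained individual-component estimation (GIG-ICA style)
#'
#' Estimates, for one subject, the spatial source that maximizes a negentropy
#' surrogate (logcosh) while staying spatially correlated with a group
#' reference map: projected gradient ascent on
#' `|E[G(y)] - E[G(nu)]| + constraint_weight * corr(y, reference)` over the
#' whitened spatial subspace, initialized at the least-squares projection of
#' the reference onto the data, with deflation against already-extracted
#' sources. The time course is the least-squares projection of the data onto
#' the estimated map.
#'
#' @param vtm A `voxel_time_matrix` (one subject).
#' @param reference Length-V numeric reference map (a row of a
#'   `group_icn_set`'s `maps`).
#' @param max_iter,tol Optimizer controls.
#' @param constraint_weight Weight of the spatial-correlation constraint
#'   (default 1).
#' @param deflate Optional matrix of previously extracted whitened weight
#'   vectors (columns) to decorrelate against.
#' @param whiten Optional precomputed whitening from [gig_whiten()]; computed
#'   from `vtm` when `NULL`.
#' @return List with `map` (length V, unit variance, positive peak),
#'   `timecourse` (length T), `corr_ref`, `converged`, and `w` (whitened
#'   weights, for deflation).
#' @export
gig_ica_reconstruct <- function(vtm, reference, max_iter = 500, tol = 1e-6,
                                constraint_weight = 1, deflate = NULL,
                                whiten = NULL) {
  if (is.null(whiten)) whiten <- gig_whiten(vtm)
  z <- whiten$z
  v <- nrow(z)
  ref <- reference - mean(reference)
  rn <- sqrt(sum(ref^2))
  if (rn == 0) stop("reference map has zero variance")
  a <- crossprod(z, ref / rn) / sqrt(v)  # corr(Zw, ref) = a'w at ||w|| = 1

  proj <- function(w) {
    if (!is.null(deflate) && ncol(deflate) > 0) {
      w <- w - deflate %*% crossprod(deflate, w)
    }
    n <- sqrt(sum(w^2))
    if (n < 1e-12) stop("weight vector collapsed during deflation")
    w / n
  }
  objective <- function(w) {
    y <- z %*% w
    abs(mean(log(cosh(y))) - logcosh_gauss) + constraint_weight * sum(a * w)
  }
  w <- proj(a)
  f <- objective(w)
  step <- 0.5
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    y <- as.vector(z %*% w)
    eg <- mean(log(cosh(y))) - logcosh_gauss
    grad <- sign(eg) * crossprod(z, tanh(y)) / v + constraint_weight * a
    w_new <- proj(w + step * grad)
    f_new <- objective(w_new)
    if (f_new < f) {
      step <- step / 2
      if (step < 1e-8) { converged <- TRUE; break }
      next
    }
    moved <- sqrt(sum((w_new - w)^2))
    w <- w_new; f <- f_new
    if (moved < tol) { converged <- TRUE; break }
  }
  y <- as.vector(z %*% w)
  map <- (y - mean(y)) / sd(y)
  if (map[which.max(abs(map))] < 0) map <- -map
  tc <- as.vector(crossprod(vtm$values, map)) / sum(map^2)
  list(map = map, timecourse = tc,
       corr_ref = cor(map, reference), converged = converged, w = w)
}

#' Whitening of one subject's spatial data for constrained ICA
#'
#' Column-centres the V x T matrix (spatially zero-mean volumes), reduces to
#' the leading `max_rank` principal directions and rescales so that any unit
#' weight vector yields a unit-variance spatial source.
#'
#' @param vtm A `voxel_time_matrix`.
#' @param max_rank Maximum retained rank (default `min(T - 1, 60)`).
#' @return List with `z` (V x r whitened basis).
#' @export
gig_whiten <- function(vtm, max_rank = NULL) {
  x <- vtm$values
  if (all(abs(x) < 1e-12)) stop("zero-variance data")
  x <- sweep(x, 2, colMeans(x))
  r_max <- max_rank %||% min(ncol(x) - 1, 60)
  sv <- svd(x, nu = min(r_max, ncol(x)), nv = 0)
  keep <- which(sv$d[seq_len(min(r_max, length(sv$d)))] >
                  max(sv$d) * 1e-8)
  if (!length(keep)) stop("zero-variance data")
  list(z = sv$u[, keep, drop = FALSE] * sqrt(nrow(x)))
}

#' Back-reconstruct all signal components for one subject
#'
#' Applies [gig_ica_reconstruct()] to every signal-labelled group map in
#' turn, deflating each new source against the ones already extracted so the
#' individual maps stay near-uncorrelated.
#'
#' @param vtm A `voxel_time_matrix` (one subject).
#' @param icns A `group_icn_set` (triaged or not; only "signal" maps used).
#' @param subject_id Identifier carried into the result.
#' @param ... Passed to [gig_ica_reconstruct()].
#' @return An object of class `subject_components`: `maps` (k_signal x V),
#'   `timecourses` (T x k_signal), `corr_ref`, `converged`, `subject_id`.
#' @export
reconstruct_subject <- function(vtm, icns, subject_id = NA_character_, ...) {
  stopifnot(inherits(icns, "group_icn_set"))
  sig <- which(icns$labels == "signal")
  whiten <- gig_whiten(vtm)
  maps <- matrix(NA_real_, length(sig), ncol(icns$maps))
  tcs <- matrix(NA_real_, ncol(vtm$values), length(sig))
  cr <- conv <- numeric(length(sig))
  defl <- NULL
  for (i in seq_along(sig)) {
    fit <- gig_ica_reconstruct(vtm, icns$maps[sig[i], ], deflate = defl,
                               whiten = whiten, ...)
    maps[i, ] <- fit$map
    tcs[, i] <- fit$timecourse
    cr[i] <- fit$corr_ref
    conv[i] <- fit$converged
    defl <- cbind(defl, fit$w)
  }
  structure(list(maps = maps, timecourses = tcs, corr_ref = cr,
                 converged = as.logical(conv), component = sig,
                 subject_id = subject_id),
            class = "subject_components")
}
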