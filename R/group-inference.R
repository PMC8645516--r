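#' Build a two-group design with demeaned nuisance covariates
#'
#' @param group Length-N vector coercible to 0/1 (e.g. "responder" flags).
#' @param covariates Optional N x P matrix or data frame of
#'   covariates-of-no-interest (age, gender, baseline score); each column is
#'   demeaned.
#' @return An object of class `glm_design`: `x` (N x (2 + P) model matrix
#'   [intercept | group | covariates]), `group`, `covariates`, `contrast`
#'   (the default group contrast).
#' @export
glm_design <- function(group, covariates = NULL) {
  g <- as.numeric(as.logical(group))
  if (length(unique(g)) != 2) stop("both groups must be nonempty")
  p <- 0
  cv <- NULL
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    cv <- sweep(cv, 2, colMeans(cv))
    p <- ncol(cv)
  }
  x <- cbind(intercept = 1, group = g, cv)
  if (qr(x)$rank < ncol(x)) {
    stop("rank-deficient design; check covariates for collinearity")
  }
  contrast <- c(0, 1, rep(0, p))
  structure(list(x = x, group = g, covariates = cv, contrast = contrast),
            class = "glm_design")
}

# vectorized OLS t-statistics for every column of y (N x M) under design x
glm_t_matrix <- function(y, x, contrast) {
  y <- as.matrix(y)
  n <- nrow(x); p <- ncol(x)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  beta <- xtx_inv %*% crossprod(x, y)            # p x M
  resid <- y - x %*% beta
  sigma2 <- colSums(resid^2) / (n - p)
  cb <- as.vector(crossprod(contrast, beta))
  se <- sqrt(sigma2 * as.numeric(t(contrast) %*% xtx_inv %*% contrast))
  tt <- cb / se
  tt[se == 0] <- 0
  tt
}

#' GLM t-statistic for a group contrast
#'
#' Ordinary least-squares fit of the response on
#' [intercept | group | covariates] and the t-statistic of a contrast.
#'
#' @param y Length-N response.
#' @param design A [glm_design()].
#' @param contrast Contrast vector over the design columns (default: the
#'   group effect).
#' @return The t-statistic (numeric scalar).
#' @export
glm_t <- function(y, design, contrast = NULL) {
  stopifnot(inherits(design, "glm_design"))
  contrast <- normalize_contrast(design, contrast %||% design$contrast)
  if (length(y) != nrow(design$x)) stop("response length != design rows")
  if (length(y) <= ncol(design$x) + 1) stop("too few observations")
  glm_t_matrix(matrix(y, ncol = 1), design$x, contrast)[1]
}

# accept contrasts given either over [group | covariates] or the full matrix
normalize_contrast <- function(design, contrast) {
  p <- ncol(design$x)
  if (length(contrast) == p) return(contrast)
  if (length(contrast) == p - 1) return(c(0, contrast))
  stop("contrast length does not match the design")
}

#' Permutation scheme for synchronized max-statistic inference
#'
#' @param n Number of subjects.
#' @param n_perm Number of random permutations (default 1000).
#' @param seed Integer seed.
#' @param permutations Optional explicit (n_perm + 1) x n index matrix whose
#'   first row is the identity (e.g. an exhaustive enumeration).
#' @return An object of class `perm_scheme`.
#' @export
perm_scheme <- function(n, n_perm = 1000, seed = 1L, permutations = NULL) {
  if (is.null(permutations)) {
    if (n_perm < 100) warning("n_perm < 100 gives unstable p-values")
    permutations <- with_seed(seed, {
      rbind(seq_len(n),
            t(replicate(n_perm, sample.int(n))))
    })
  } else {
    permutations <- as.matrix(permutations)
    if (!all(permutations[1, ] == seq_len(n))) {
      stop("first permutation row must be the identity")
    }
    if (!all(apply(permutations, 1, function(r) all(sort(r) == seq_len(n))))) {
      stop("every row must be a permutation of 1..n")
    }
    n_perm <- nrow(permutations) - 1L
  }
  structure(list(n_perm = n_perm, seed = seed, permutations = permutations),
            class = "perm_scheme")
}

#' Threshold-free cluster enhancement of a statistic image
#'
#' For each voxel, integrates `extent(h)^E * h^H dh` over thresholds
#' `h = dh, 2dh, ...`, where `extent(h)` is the size of the suprathreshold
#' cluster containing the voxel at height `h`. The negative tail is enhanced
#' separately on the negated image and subtracted.
#'
#' @param stat_map 3D numeric statistic image.
#' @param mask 3D logical mask.
#' @param H Height exponent (default 2).
#' @param E Extent exponent (default 0.5).
#' @param dh Threshold step; default `max(abs(stat)) / 100`.
#' @param connectivity Cluster neighbourhood: 6, 18 or 26 (default 26).
#' @return 3D numeric array of enhanced values (signed).
#' @export
tfce <- function(stat_map, mask = NULL, H = 2, E = 0.5, dh = NULL,
                 connectivity = 26) {
  stopifnot(length(dim(stat_map)) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(stat_map))
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  mx <- max(abs(stat_map[mask]), 0)
  if (mx == 0) return(array(0, dim = dim(stat_map)))
  dh <- dh %||% (mx / 100)
  if (dh <= 0) stop("dh must be > 0")
  pos <- .tfce_enhance(pmax(as.vector(stat_map), 0), as.vector(mask),
                       dim(stat_map), dh, E, H, as.integer(connectivity))
  neg <- .tfce_enhance(pmax(-as.vector(stat_map), 0), as.vector(mask),
                       dim(stat_map), dh, E, H, as.integer(connectivity))
  array(pos - neg, dim = dim(stat_map))
}

#' Synchronized max-statistic permutation inference
#'
#' Fits the group GLM to every feature (voxel of one or more component maps,
#' or network edge), permutes the group labels identically across all
#' features and family units, records per permutation the maximum of the
#' (optionally TFCE-enhanced) statistic over all features, both contrast
#' signs and all family units, and returns familywise-error-corrected
#' p-values `p_fwe = (1 + #(perm max >= observed)) / (1 + n_perm)`.
#'
#' @param features N x M matrix (rows = subjects).
#' @param design A [glm_design()].
#' @param scheme A [perm_scheme()].
#' @param tfce_params Optional list (`H`, `E`, `dh`, `connectivity`) enabling
#'   TFCE for family units that carry a `mask`.
#' @param family Optional list of units, each `list(cols = indices, mask =
#'   3D logical or NULL, name = chr)`; defaults to one unit holding all
#'   features (no TFCE mask).
#' @return An object of class `perm_maxT`: `p_fwe` and `stat` (length M),
#'   `enhanced` (two-sided statistic compared against the null), `null_max`
#'   (length n_perm), `family`, `scheme` metadata.
#' @export
perm_maxT <- function(features, design, scheme, tfce_params = NULL,
                      family = NULL) {
  stopifnot(inherits(design, "glm_design"), inherits(scheme, "perm_scheme"))
  features <- as.matrix(features)
  n <- nrow(features)
  m <- ncol(features)
  if (m < 1) stop("need at least one feature")
  if (nrow(design$x) != n) stop("design rows != feature rows")
  if (ncol(scheme$permutations) != n) stop("scheme size != number of subjects")
  if (is.null(family)) {
    family <- list(list(cols = seq_len(m), mask = NULL, name = "all"))
  }
  for (u in family) {
    if (!is.null(u$mask) && sum(u$mask) != length(u$cols)) {
      stop("family unit mask size does not match its column count")
    }
  }
  use_tfce <- !is.null(tfce_params)

  enhance <- function(tt) {
    # two-sided element statistic within each unit
    out <- numeric(m)
    for (u in family) {
      tu <- tt[u$cols]
      if (use_tfce && !is.null(u$mask)) {
        img <- array(0, dim = dim(u$mask))
        img[u$mask] <- tu
        enh <- do.call(tfce, c(list(stat_map = img, mask = u$mask),
                               tfce_params))
        out[u$cols] <- abs(enh[u$mask])
      } else {
        out[u$cols] <- abs(tu)
      }
    }
    out
  }

  nr <- nrow(scheme$permutations)
  xtpl <- design$x
  gcol <- 2L
  contrast <- design$contrast
  obs_t <- NULL
  obs_enh <- NULL
  null_max <- numeric(nr - 1L)
  for (r in seq_len(nr)) {
    xp <- xtpl
    xp[, gcol] <- design$group[scheme$permutations[r, ]]
    tt <- glm_t_matrix(features, xp, contrast)
    enh <- enhance(tt)
    if (r == 1L) {
      obs_t <- tt
      obs_enh <- enh
    } else {
      null_max[r - 1L] <- max(enh)
    }
  }
  p_fwe <- vapply(obs_enh, function(e) {
    (1 + sum(null_max >= e)) / (1 + length(null_max))
  }, 0)
  structure(list(p_fwe = p_fwe, stat = obs_t, enhanced = obs_enh,
                 null_max = null_max, family = family,
                 n_perm = scheme$n_perm, seed = scheme$seed,
                 tfce_params = tfce_params,
                 note = "raw group labels permuted; covariates held fixed"),
            class = "perm_maxT")
}

#' @exportS3Method base::print
print.perm_maxT <- function(x, ...) {
  cat(sprintf("<perm_maxT> %d features, %d permutations, min p_fwe = %.4g\n",
              length(x$p_fwe), x$n_perm, min(x$p_fwe)))
  invisible(x)
}

#' Tidy permutation-inference results
#'
#' @param x A `perm_maxT` object.
#' @param ... Unused.
#' @return A tibble with `feature`, `unit`, `stat`, `enhanced`, `p_fwe`.
#' @export
tidy.perm_maxT <- function(x, ...) {
  unit <- character(length(x$p_fwe))
  for (u in x$family) unit[u$cols] <- u$name %||% "unit"
  tibble::tibble(feature = seq_along(x$p_fwe), unit = unit,
                 stat = x$stat, enhanced = x$enhanced, p_fwe = x$p_fwe)
}
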