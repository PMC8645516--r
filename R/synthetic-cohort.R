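#' Construct a BOLD run container
#'
#' A `bold_run` holds one subject's 4D BOLD series (X x Y x Z x T), the brain
#' mask and the repetition time. It is the unit of data every preprocessing
#' and decomposition stage consumes.
#'
#' @param data 4D numeric array (X x Y x Z x T), arbitrary BOLD units.
#' @param mask 3D logical array matching the first three dimensions of `data`.
#' @param tr_s Repetition time in seconds.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, mask, tr_s) {
  stopifnot(length(dim(data)) == 4, length(dim(mask)) == 3)
  if (!all(dim(data)[1:3] == dim(mask))) {
    stop("mask dimensions do not match the spatial dimensions of the data")
  }
  if (dim(data)[4] < 2) stop("a BOLD run needs at least 2 volumes")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask is empty")
  flat <- matrix(data, ncol = dim(data)[4])
  if (!all(is.finite(flat[as.vector(mask), ]))) {
    stop("non-finite values inside the mask")
  }
  structure(list(data = data, mask = mask, tr_s = as.numeric(tr_s)),
            class = "bold_run")
}

#' @exportS3Method base::print
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d voxels, %d volumes, TR %.3g s, %d in mask\n",
              d[1], d[2], d[3], d[4], x$tr_s, sum(x$mask)))
  invisible(x)
}

#' Specify a synthetic resting-state cohort
#'
#' Defines the data-generating model for a two-group (responder /
#' non-responder) resting-state cohort: K spatial networks as smooth Gaussian
#' blobs on a voxel grid, per-subject band-limited network time courses drawn
#' from a group-specific correlation model, a planted between-network
#' connectivity difference on one network pair ("FPN"-"SMN" style), a planted
#' multivariate within-network spatial-map difference ("STG" style), and
#' pre/post symptom scores generating the responder labels via the
#' at-least-30-percent-reduction rule.
#'
#' Defaults emulate the cohort the pipeline targets: 40 subjects (21
#' responders / 19 non-responders), 200 volumes at TR 2.3 s, baseline symptom
#' scores centred at 56.1 (SD 23.25), ages 8-17, about 65 percent girls, and
#' a desk-scale 16 x 16 x 12 grid with K = 6 networks so the full pipeline
#' runs in minutes.
#'
#' @param n_subjects,n_responders Cohort size and number of responders.
#' @param grid_shape Integer vector of 3 voxel counts.
#' @param n_volumes Number of time points T.
#' @param tr_s Repetition time in seconds.
#' @param k_networks Number of planted networks K.
#' @param network_geometry Optional list of per-network `list(center, radius)`
#'   in voxel units; autoplaced when `NULL`.
#' @param noise_sd White-noise SD added to every voxel time series
#'   (signal time courses have unit variance; blob peak height is 1).
#' @param baseline Constant intensity added to every voxel (arbitrary BOLD
#'   units). Real BOLD has a large positive baseline; the grand-mean-scaling
#'   step requires one.
#' @param edge_effect List: `pair` (two network indices), `delta_z`
#'   (between-group difference in Fisher-z time-course correlation), `base_z`
#'   (the weaker group's correlation), `stronger` ("nonresponder" or
#'   "responder" — which group carries the larger correlation).
#' @param map_effect List: `network` (index), `magnitude` (per-voxel SD of the
#'   group-dependent spatial perturbation, relative to blob peak 1).
#' @param covariates List: `age_range` (years), `prop_female`,
#'   `baseline_mean`, `baseline_sd` (symptom-score units).
#' @param pre_post_model List of per-group percent-reduction means/SDs:
#'   `responder_mean`, `responder_sd`, `nonresponder_mean`, `nonresponder_sd`.
#' @param response_threshold_pct Percent reduction defining response.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 40,
                        n_responders = 21,
                        grid_shape = c(16L, 16L, 12L),
                        n_volumes = 200,
                        tr_s = 2.3,
                        k_networks = 6,
                        network_geometry = NULL,
                        noise_sd = 0.2,
                        baseline = 100,
                        edge_effect = list(pair = c(1L, 2L), delta_z = 0.5,
                                           base_z = 0.1, stronger = "nonresponder"),
                        map_effect = list(network = NULL, magnitude = 0.15),
                        covariates = list(age_range = c(8, 17), prop_female = 0.65,
                                          baseline_mean = 56.1, baseline_sd = 23.25),
                        pre_post_model = list(responder_mean = 60, responder_sd = 15,
                                              nonresponder_mean = 10, nonresponder_sd = 12),
                        response_threshold_pct = 30,
                        seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               n_responders = as.integer(n_responders),
               grid_shape = as.integer(grid_shape),
               n_volumes = as.integer(n_volumes),
               tr_s = as.numeric(tr_s),
               k_networks = as.integer(k_networks),
               network_geometry = network_geometry,
               noise_sd = as.numeric(noise_sd),
               baseline = as.numeric(baseline),
               edge_effect = edge_effect,
               map_effect = resolve_map_effect(map_effect,
                                               as.integer(k_networks)),
               covariates = covariates,
               pre_post_model = pre_post_model,
               response_threshold_pct = as.numeric(response_threshold_pct),
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

# default effect network: the third network when it exists, else the last
resolve_map_effect <- function(map_effect, k) {
  if (is.null(map_effect)) return(NULL)
  if (is.null(map_effect$network)) map_effect$network <- min(3L, k)
  map_effect
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_responders > n_subjects) stop("n_responders must be <= n_subjects")
    if (any(c(n_subjects, n_responders, n_volumes, k_networks) < 1)) {
      stop("all counts must be >= 1")
    }
    if (length(grid_shape) != 3 || any(grid_shape < 1)) {
      stop("grid_shape must be 3 positive voxel counts")
    }
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (!is.null(edge_effect)) {
      if (any(edge_effect$pair < 1) || any(edge_effect$pair > k_networks) ||
          edge_effect$pair[1] == edge_effect$pair[2]) {
        stop("edge_effect$pair must name two distinct networks")
      }
      top <- abs(tanh(edge_effect$base_z)) + abs(tanh(edge_effect$base_z +
                                                        edge_effect$delta_z))
      if (top >= 2) stop("edge_effect exceeds the achievable correlation range")
    }
    if (!is.null(map_effect) &&
        (map_effect$network < 1 || map_effect$network > k_networks)) {
      stop("map_effect$network out of range")
    }
  })
  if (!is.null(spec$network_geometry)) {
    vol <- sum(vapply(spec$network_geometry,
                      function(g) 4 / 3 * pi * g$radius^3, 0))
    if (vol > prod(spec$grid_shape)) {
      stop("grid volume smaller than the total blob volume")
    }
  }
  spec
}

# Auto-place K blob centers on the grid: jittered lattice, radius scaled so
# blobs do not overlap (pairwise map correlation < 0.3 by construction).
default_geometry <- function(grid_shape, k) {
  nx <- ceiling(k^(1 / 2))
  ny <- ceiling(k / nx)
  centers <- list()
  i <- 0
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      i <- i + 1
      if (i > k) break
      centers[[i]] <- c((ix - 0.5) / nx * grid_shape[1],
                        (iy - 0.5) / ny * grid_shape[2],
                        (0.35 + 0.3 * (i %% 2)) * grid_shape[3])
    }
  }
  sep <- min(grid_shape[1] / nx, grid_shape[2] / ny)
  radius <- sep / 3.2
  lapply(centers, function(ctr) list(center = ctr, radius = radius))
}

# Gaussian-profile blob maps, one row per network, on the flattened grid.
planted_map_matrix <- function(grid_shape, geometry) {
  coords <- as.matrix(expand.grid(x = seq_len(grid_shape[1]) - 0.5,
                                  y = seq_len(grid_shape[2]) - 0.5,
                                  z = seq_len(grid_shape[3]) - 0.5))
  maps <- vapply(geometry, function(g) {
    d2 <- rowSums(sweep(coords, 2, g$center)^2)
    exp(-d2 / (2 * (g$radius / 1.5)^2))
  }, numeric(nrow(coords)))
  t(maps)  # k x V
}

# Group-specific target correlation matrix for the network time courses.
target_correlation <- function(spec, group) {
  k <- spec$k_networks
  r <- diag(k)
  ee <- spec$edge_effect
  if (!is.null(ee)) {
    z <- ee$base_z
    if (identical(group, ee$stronger)) z <- z + ee$delta_z
    rho <- tanh(z)
    i <- ee$pair[1]; j <- ee$pair[2]
    r[i, j] <- r[j, i] <- rho
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) {
    rep <- tryCatch(as.matrix(Matrix::nearPD(r, corr = TRUE)$mat),
                    error = function(e) NULL)
    if (is.null(rep)) {
      stop(sprintf("infeasible correlation matrix: edge (%d, %d) target %.3f",
                   ee$pair[1], ee$pair[2], tanh(ee$base_z + ee$delta_z)))
    }
    message("target correlation matrix repaired to nearest positive definite")
    r <- rep
  }
  r
}

# Band-limited unit-variance time courses with target cross-correlation:
# correlated white draws, Gaussian low-pass smoothing along time (shared
# filter preserves cross-correlations), then column standardization.
draw_timecourses <- function(t_len, r_target, smooth_sd_tr = 1.5) {
  k <- nrow(r_target)
  l <- chol(r_target)
  x <- matrix(rnorm(t_len * k), t_len, k) %*% l
  half <- ceiling(4 * smooth_sd_tr)
  kern <- exp(-((-half:half)^2) / (2 * smooth_sd_tr^2))
  kern <- kern / sum(kern)
  pad <- rbind(x[rev(seq_len(half)), , drop = FALSE], x,
               x[t_len + 1 - seq_len(half), , drop = FALSE])
  sm <- apply(pad, 2, function(col) stats::filter(col, kern, sides = 2))
  sm <- sm[half + seq_len(t_len), , drop = FALSE]
  scale(sm)[, , drop = FALSE]
}

#' Label treatment response from pre/post symptom scores
#'
#' A subject is a responder when the symptom score dropped by at least
#' `threshold_pct` percent of the pre-treatment score.
#'
#' @param pre,post Pre- and post-treatment total scores (vectorized).
#' @param threshold_pct Percent-reduction criterion (default 30).
#' @return Logical vector of responder flags.
#' @export
#' @examples
#' label_from_scores(56.1, 38.0)  # 32.3% reduction -> TRUE
#' label_from_scores(50, 35)      # exactly 30% -> TRUE
label_from_scores <- function(pre, post, threshold_pct = 30) {
  if (any(pre <= 0)) stop("pre-treatment score must be > 0")
  (pre - post) / pre * 100 >= threshold_pct
}

# Percent reductions per group, truncated so that the threshold rule yields
# exactly the requested group sizes for every seed.
draw_reductions <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    cand <- rnorm(length(need), mean, sd)
    ok <- cand >= lower & cand < upper
    out[need[ok]] <- cand[ok]
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic cohort with full ground truth
#'
#' Builds, deterministically from the spec (including its seed), the list of
#' per-subject 4D BOLD runs, the participants table, and a `synthetic_truth`
#' object recording everything that was planted: spatial maps, per-subject
#' time courses, responder labels, target edge correlations and covariates.
#' Each subject's series is planted maps x time courses (reshaped onto the
#' grid) plus white noise; the map-effect network's spatial map carries a
#' group-dependent multivariate perturbation.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `runs` (list of [bold_run()]), `participants`
#'   (a tibble with participant_id, group, age, gender, caps_pre, caps_post),
#'   and `truth` (class `synthetic_truth`).
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  with_seed(spec$seed, {
    g <- spec$grid_shape
    v <- prod(g)
    geom <- spec$network_geometry %||% default_geometry(g, spec$k_networks)
    maps <- planted_map_matrix(g, geom)
    cm <- cor(t(maps))
    off <- abs(cm[upper.tri(cm)])
    if (any(off >= 0.3)) {
      stop(sprintf("planted maps overlap too much (max |r| = %.2f >= 0.3)",
                   max(off)))
    }
    mask <- array(TRUE, dim = g)

    labels <- rep(FALSE, spec$n_subjects)
    labels[sample.int(spec$n_subjects, spec$n_responders)] <- TRUE
    groups <- ifelse(labels, "responder", "nonresponder")

    r_resp <- target_correlation(spec, "responder")
    r_non <- target_correlation(spec, "nonresponder")

    # group-dependent multivariate spatial pattern on the effect network
    pattern <- rep(0, v)
    if (!is.null(spec$map_effect)) {
      base <- maps[spec$map_effect$network, ]
      supp <- base > 0.05 * max(base)
      pattern[supp] <- rnorm(sum(supp), 0, spec$map_effect$magnitude)
    }

    cv <- spec$covariates
    age <- round(runif(spec$n_subjects, cv$age_range[1], cv$age_range[2]), 1)
    gender <- as.integer(runif(spec$n_subjects) < cv$prop_female)
    pre <- pmax(10, rnorm(spec$n_subjects, cv$baseline_mean, cv$baseline_sd))

    pp <- spec$pre_post_model
    red <- numeric(spec$n_subjects)
    red[labels] <- draw_reductions(sum(labels), pp$responder_mean,
                                   pp$responder_sd,
                                   spec$response_threshold_pct, 100)
    red[!labels] <- draw_reductions(sum(!labels), pp$nonresponder_mean,
                                    pp$nonresponder_sd,
                                    -100, spec$response_threshold_pct)
    post <- pre * (1 - red / 100)

    runs <- vector("list", spec$n_subjects)
    tcs <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      r_tgt <- if (labels[s]) r_resp else r_non
      tc <- draw_timecourses(spec$n_volumes, r_tgt)
      tcs[[s]] <- tc
      maps_s <- maps
      if (!is.null(spec$map_effect)) {
        sgn <- if (labels[s]) 1 else -1
        maps_s[spec$map_effect$network, ] <-
          maps_s[spec$map_effect$network, ] + sgn * pattern
      }
      y <- crossprod(maps_s, t(tc))  # V x T
      y <- y + rnorm(length(y), 0, spec$noise_sd) + (spec$baseline %||% 0)
      runs[[s]] <- bold_run(array(y, dim = c(g, spec$n_volumes)), mask,
                            spec$tr_s)
    }

    participants <- tibble::tibble(
      participant_id = sprintf("sub-%02d", seq_len(spec$n_subjects)),
      group = groups,
      age = age,
      gender = gender,
      caps_pre = round(pre, 1),
      caps_post = round(post, 1))
    # rounding must not flip any label across the threshold
    flip <- label_from_scores(participants$caps_pre, participants$caps_post,
                              spec$response_threshold_pct) != labels
    if (any(flip)) {
      participants$caps_post[flip] <- post[flip]
      participants$caps_pre[flip] <- pre[flip]
    }

    truth <- structure(list(
      planted_maps = maps,
      pattern = pattern,
      geometry = geom,
      grid_shape = g,
      planted_timecourses = tcs,
      true_labels = labels,
      true_edge_corr = list(responder = r_resp, nonresponder = r_non),
      covariates = participants[, c("age", "gender", "caps_pre")],
      spec = spec), class = "synthetic_truth")

    list(runs = runs, participants = participants, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
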