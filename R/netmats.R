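new_netmat <- function(z, kind, rho = NA_real_, subject_id = NA_character_) {
  dimnames(z) <- NULL
  structure(list(z = z, kind = kind, rho = rho, subject_id = subject_id),
            class = "netmat")
}

#' @exportS3Method base::print
print.netmat <- function(x, ...) {
  cat(sprintf("<netmat> %s, %d x %d%s\n", x$kind, nrow(x$z), ncol(x$z),
              if (x$kind == "partial") sprintf(", rho = %g", x$rho) else ""))
  invisible(x)
}

# clip |r| below 1 so atanh stays finite
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Full-correlation network matrix
#'
#' Pairwise Pearson correlation between component time courses, Fisher
#' r-to-z transformed (|r| clipped to 1 - 1e-7 before atanh), zero diagonal.
#'
#' @param tc T x k matrix of time courses (columns = components).
#' @param subject_id Identifier carried into the result.
#' @return A `netmat` of kind `"full"`.
#' @export
full_corr <- function(tc, subject_id = NA_character_) {
  tc <- as.matrix(tc)
  if (ncol(tc) < 2 || nrow(tc) <= ncol(tc)) {
    stop("need T > k >= 2 time courses")
  }
  sds <- apply(tc, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("constant time course for component %s",
                 paste(which(sds == 0), collapse = ", ")))
  }
  z <- fisher_z(cor(tc))
  diag(z) <- 0
  new_netmat(z, "full", subject_id = subject_id)
}

#' Ridge-regularized partial-correlation network matrix
#'
#' Partial correlations from the inverse of the ridge-regularized covariance
#' of the standardized time courses: with `C` the covariance and
#' `P = (C + rho * mean(diag(C)) * I)^-1`, the partial correlation is
#' `-P_ij / sqrt(P_ii P_jj)`, Fisher r-to-z transformed. The regularization
#' is scaled to the covariance magnitude, the netmats convention; `rho = 0`
#' gives the textbook unregularized partial correlation.
#'
#' @param tc T x k matrix of time courses.
#' @param rho Ridge parameter (default 0.1).
#' @param subject_id Identifier carried into the result.
#' @return A `netmat` of kind `"partial"`.
#' @export
partial_corr_ridge <- function(tc, rho = 0.1, subject_id = NA_character_) {
  tc <- as.matrix(tc)
  if (nrow(tc) <= 2) stop("need T > 2")
  if (rho < 0) stop("rho must be >= 0")
  xs <- scale(tc)
  cmat <- crossprod(xs) / (nrow(xs) - 1)
  reg <- cmat + rho * mean(diag(cmat)) * diag(ncol(cmat))
  p <- tryCatch(solve(reg), error = function(e) {
    stop("covariance is singular; use rho > 0")
  })
  d <- sqrt(diag(p))
  r <- -p / tcrossprod(d)
  z <- fisher_z(r)
  diag(z) <- 0
  new_netmat(z, "partial", rho = rho, subject_id = subject_id)
}

#' Vectorize a network matrix into the canonical edge order
#'
#' Strict lower triangle in fixed row-major order: pairs (i, j) with i > j,
#' ordered by row i then column j — (2,1), (3,1), (3,2), (4,1), ... —
#' identical across subjects, length k(k-1)/2.
#'
#' @param nm A `netmat` (or a bare symmetric matrix).
#' @return Named numeric vector of edge values.
#' @export
vectorize_edges <- function(nm) {
  z <- if (inherits(nm, "netmat")) nm$z else as.matrix(nm)
  idx <- edge_index(nrow(z))
  setNames(z[idx], sprintf("e%02d_%02d", idx[, 1], idx[, 2]))
}

#' Edge index map for [vectorize_edges()]
#'
#' @param k Number of components.
#' @return Two-column integer matrix (i, j) giving, for each edge-vector
#'   position, its row/column in the k x k matrix.
#' @export
edge_index <- function(k) {
  i <- unlist(lapply(2:k, function(r) rep(r, r - 1)))
  j <- unlist(lapply(2:k, function(r) seq_len(r - 1)))
  cbind(i = i, j = j)
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_edges()] (zero diagonal).
#'
#' @param edges Edge vector of length k(k-1)/2.
#' @param k Number of components.
#' @return k x k symmetric matrix.
#' @export
edges_to_matrix <- function(edges, k) {
  z <- matrix(0, k, k)
  z[edge_index(k)] <- edges
  z + t(z)
}

#' Tidy a network matrix into an edge tibble
#'
#' @param x A `netmat`.
#' @param ... Unused.
#' @return A tibble with one row per unordered edge: `i`, `j`, `z`, `kind`,
#'   `subject_id`.
#' @export
tidy.netmat <- function(x, ...) {
  idx <- edge_index(nrow(x$z))
  tibble::tibble(i = idx[, 1], j = idx[, 2],
                 z = unname(vectorize_edges(x)),
                 kind = x$kind, subject_id = x$subject_id)
}

#' Heatmap of a network matrix
#'
#' @param object A `netmat`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.netmat <- function(object, ...) {
  k <- nrow(object$z)
  df <- tidyr::expand_grid(i = seq_len(k), j = seq_len(k))
  df$z <- as.vector(object$z)[(df$j - 1) * k + df$i]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Fisher z",
                  title = sprintf("%s correlation netmat", object$kind)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
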