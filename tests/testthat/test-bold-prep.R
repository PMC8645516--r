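make_run <- function(arr, tr = 2.3) {
  bold_run(arr, array(TRUE, dim(arr)[1:3]), tr)
}

test_that("Gaussian smoothing preserves constants and has the right width", {
  g <- c(21, 21, 21)  # large enough that the kernel never meets an edge
  const <- make_run(array(7, c(g, 2)))
  sm <- smooth_bold(const, 6, 2)
  expect_lt(max(abs(sm$data - 7)), 1e-10)

  imp <- array(0, c(g, 2)); imp[11, 11, 11, ] <- 1
  sm <- smooth_bold(make_run(imp), 6, 2)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 2  # 1.274 voxels
  expect_equal(sm$data[12, 11, 11, 1] / sm$data[11, 11, 11, 1],
               exp(-1 / (2 * sigma^2)), tolerance = 1e-10)
  expect_equal(sm$data[13, 11, 11, 1] / sm$data[11, 11, 11, 1],
               exp(-4 / (2 * sigma^2)), tolerance = 1e-10)

  run <- make_run(array(rnorm(prod(g) * 2), c(g, 2)))
  expect_identical(smooth_bold(run, 0, 2)$data, run$data)
  expect_error(smooth_bold(run, 6, 0), "positive")
})

test_that("grand-mean scaling hits the target exactly", {
  arr <- array(500, c(4, 4, 3, 5))
  out <- grand_mean_scale(make_run(arr), 10000)
  expect_equal(out$data[1, 1, 1, 1], 10000)
  flat <- matrix(out$data, ncol = 5)
  expect_equal(mean(flat), 10000, tolerance = 1e-6)
  already <- grand_mean_scale(out, 10000)
  expect_equal(already$data, out$data)
  expect_error(grand_mean_scale(make_run(arr - 600), 10000), "positive")
})

test_that("nuisance set has the DCT count and honours orthogonalization", {
  ns <- build_nuisance(t_len = 200, tr_s = 2.3, cutoff_s = 128)
  expect_equal(ncol(ns$regressors), 7)  # floor(2*200*2.3/128)

  set.seed(1)
  wm <- rnorm(200); csf <- rnorm(200)
  ns2 <- build_nuisance(wm, csf, t_len = 200, tr_s = 2.3, cutoff_s = 128)
  expect_equal(ncol(ns2$regressors), 9)
  # removed empty -> columns unchanged
  expect_equal(ns2$regressors[, "wm"], wm)

  rem <- cbind(rnorm(200), rnorm(200))
  ns3 <- build_nuisance(wm, csf, t_len = 200, tr_s = 2.3, cutoff_s = 128,
                        removed = rem)
  cross <- crossprod(ns3$regressors, rem)
  norms <- outer(sqrt(colSums(ns3$regressors^2)), sqrt(colSums(rem^2)))
  expect_lt(max(abs(cross) / norms), 1e-8)

  # a column lying entirely in span(removed) is residualized to ~0
  ns4 <- build_nuisance(wm = rem[, 1] * 2, csf = NULL, t_len = 200,
                        tr_s = 2.3, cutoff_s = 128, removed = rem)
  expect_lt(sqrt(sum(ns4$regressors[, "wm"]^2)), 1e-8)

  expect_warning(build_nuisance(t_len = 20, tr_s = 1, cutoff_s = 128),
                 "cosine")
  expect_error(build_nuisance(t_len = 100, tr_s = 2.3, cutoff_s = 4),
               "cutoff")
})

fake_vtm <- function(values, tr = 2.3) {
  structure(list(values = values,
                 voxel_index = cbind(seq_len(nrow(values)), 1, 1),
                 grid_shape = c(nrow(values), 1, 1),
                 mask = array(TRUE, c(nrow(values), 1, 1)), tr_s = tr),
            class = "voxel_time_matrix")
}

test_that("confound regression removes regressors and slow drifts", {
  set.seed(2)
  ns <- build_nuisance(wm = rnorm(200), t_len = 200, tr_s = 2.3,
                       cutoff_s = 128)
  # row equal to a regressor -> residual ~ 0
  vtm <- fake_vtm(rbind(ns$regressors[, "wm"]))
  expect_lt(max(abs(regress_out(vtm, ns)$values)), 1e-8)

  # signal + 2*WM with WM orthogonal to signal -> signal recovered
  wm <- rnorm(200)
  sig0 <- rnorm(200)
  x <- cbind(1, ns$regressors[, -1], wm)
  sig <- qr.resid(qr(x), sig0)  # orthogonal to everything in the model
  ns_wm <- build_nuisance(wm = wm, t_len = 200, tr_s = 2.3, cutoff_s = 128)
  out <- regress_out(fake_vtm(rbind(sig + 2 * wm)), ns_wm)
  expect_lt(max(abs(out$values[1, ] - sig)), 1e-8)

  # slow sinusoid (period 256 s > 128 s cutoff) almost fully removed
  tt <- seq_len(200)
  slow <- sin(2 * pi * tt * 2.3 / 256)
  out <- regress_out(fake_vtm(rbind(slow)), ns_wm)
  expect_lt(sum(out$values^2) / sum(slow^2), 0.01)
})

test_that("cleanup is idempotent", {
  set.seed(3)
  ns <- build_nuisance(wm = rnorm(100), t_len = 100, tr_s = 2.3,
                       cutoff_s = 128)
  vtm <- fake_vtm(matrix(rnorm(500), 5))
  once <- regress_out(vtm, ns)
  twice <- regress_out(once, ns)
  expect_lt(max(abs(twice$values - once$values)), 1e-10)
})

test_that("orthogonalized nuisance cannot reintroduce removed signal", {
  set.seed(4)
  t_len <- 150
  removed <- scale(cbind(rnorm(t_len), rnorm(t_len)), scale = FALSE)
  data <- matrix(rnorm(6 * t_len), 6) +
    tcrossprod(runif(6), removed[, 1])  # data contaminated by noise comp
  ns <- build_nuisance(wm = rnorm(t_len), t_len = t_len, tr_s = 2.3,
                       cutoff_s = 128, removed = removed)

  # path 1: subtract the removed subspace first, then clean
  u <- svd(removed)$u
  cleaned <- data - data %*% u %*% t(u)
  r1 <- regress_out(fake_vtm(cleaned), ns)$values
  # path 2: clean the contaminated data with [removed | nuisance] jointly
  ns_joint <- build_nuisance(wm = ns$regressors[, "wm"], t_len = t_len,
                             tr_s = 2.3, cutoff_s = 128)
  x <- cbind(1, removed, ns$regressors)
  r2 <- t(qr.resid(qr(x), t(data)))
  expect_lt(max(abs(r1 - r2)), 1e-8)
  # and the final residual stays orthogonal to the removed subspace
  expect_lt(max(abs(r1 %*% removed)), 1e-6)
})
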