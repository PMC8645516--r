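test_that("GLM group t equals the pooled two-sample t", {
  d <- glm_design(c(0, 0, 0, 1, 1, 1))
  y <- c(1, 2, 3, 3, 4, 5)
  oracle <- t.test(y[4:6], y[1:3], var.equal = TRUE)$statistic
  expect_equal(glm_t(y, d), unname(oracle), tolerance = 1e-12)

  # with demeaned covariates the group t matches lm()
  set.seed(1)
  g <- rep(0:1, each = 10)
  cov <- cbind(age = rnorm(20), sex = rbinom(20, 1, 0.5))
  y2 <- rnorm(20) + 0.8 * g
  d2 <- glm_design(g, cov)
  fit <- summary(lm(y2 ~ g + scale(cov, scale = FALSE)))
  expect_equal(glm_t(y2, d2), fit$coefficients["g", "t value"],
               tolerance = 1e-10)

  # response orthogonal to all regressors -> t ~ 0
  x <- d2$x
  y0 <- qr.resid(qr(x), rnorm(20))
  expect_lt(abs(glm_t(y0, d2)), 1e-8)

  expect_error(glm_design(rep(1, 6)), "nonempty")
  expect_error(glm_design(g, cbind(a = g, b = 2 * g)), "rank")
})

test_that("TFCE matches the analytic single-voxel limit and is local", {
  img <- array(0, c(9, 9, 9))
  expect_equal(tfce(img), array(0, c(9, 9, 9)))

  img[5, 5, 5] <- 3
  e <- tfce(img, H = 2, E = 0.5, dh = 0.01)
  expect_equal(e[5, 5, 5], 3^3 / 3, tolerance = 0.02)  # sum h^2 dh -> h^3/3

  # disjoint second cluster leaves the first unchanged
  img2 <- img
  img2[1, 1, 1] <- 2.5
  e2 <- tfce(img2, H = 2, E = 0.5, dh = 0.01)
  expect_equal(e2[5, 5, 5], e[5, 5, 5])
  # negative values enhanced on the flipped sign
  e3 <- tfce(-img, H = 2, E = 0.5, dh = 0.01)
  expect_equal(e3[5, 5, 5], -e[5, 5, 5])
})

test_that("cluster growth raises TFCE through the extent term", {
  img <- array(0, c(12, 6, 6))
  img[4, 3, 3] <- 2
  single <- tfce(img, dh = 0.02)[4, 3, 3]
  img[5, 3, 3] <- 2  # neighbour at the same height doubles extent
  pair <- tfce(img, dh = 0.02)[4, 3, 3]
  expect_equal(pair / single, sqrt(2), tolerance = 1e-6)  # E = 0.5
})

test_that("single-element maxT p equals the exhaustive permutation p", {
  set.seed(7)
  y <- rnorm(8)
  g <- rep(c(0, 1), each = 4)
  d <- glm_design(g)

  combs <- utils::combn(8, 4)
  tall <- apply(combs, 2, function(ix) {
    gg <- rep(0, 8); gg[ix] <- 1
    abs(t.test(y[gg == 1], y[gg == 0], var.equal = TRUE)$statistic)
  })
  t_obs <- tall[apply(combs, 2, function(ix) all(ix == 5:8))]
  p_exh <- mean(tall >= t_obs - 1e-10)

  # feed the full enumeration (as index permutations) into perm_maxT
  base <- c(which(g == 1), which(g == 0))
  rows <- t(apply(combs, 2, function(ix) {
    v <- integer(8); v[c(ix, setdiff(1:8, ix))] <- base; v
  }))
  ident <- apply(rows, 1, function(r) all(g[r] == g))
  sch <- perm_scheme(8, permutations = rbind(1:8, rows[!ident, ]))
  pm <- perm_maxT(matrix(y, ncol = 1), d, sch)
  # identical up to one permutation's worth of numerically tied statistics
  expect_lt(abs(pm$p_fwe - p_exh), 1.5 / 70)
})

test_that("maxT inference is synchronized and family-monotone", {
  set.seed(8)
  n <- 24
  g <- rep(0:1, each = 12)
  d <- glm_design(g)
  feats <- matrix(rnorm(n * 10), n)
  feats[, 3] <- feats[, 3] + g * 1.5
  sch <- perm_scheme(n, 300, seed = 5)
  p1 <- perm_maxT(feats, d, sch)$p_fwe

  # permuting feature order permutes p-values, nothing else
  ord <- sample(10)
  p2 <- perm_maxT(feats[, ord], d, sch)$p_fwe
  expect_equal(p2, p1[ord])

  # enlarging the family can only raise p-values
  p3 <- perm_maxT(cbind(feats, matrix(rnorm(n * 15), n)), d, sch)$p_fwe
  expect_true(all(p3[1:10] >= p1 - 1e-12))
})

test_that("a strong planted edge is ranked first by the edge test", {
  coh <- small_cohort()  # delta z = 0.8 on planted pair (1, 2)
  edges <- do.call(rbind, lapply(coh$truth$planted_timecourses, function(tc) {
    vectorize_edges(full_corr(tc))
  }))
  lab <- coh$truth$true_labels
  d <- glm_design(!lab)  # contrast: nonresponder > responder
  sch <- perm_scheme(length(lab), 500, seed = 9)
  pm <- perm_maxT(edges, d, sch)
  idx <- edge_index(4)
  planted <- which(idx[, 1] == 2 & idx[, 2] == 1)
  expect_equal(which.min(pm$p_fwe), planted)
  expect_gt(pm$stat[planted], 0)
})
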