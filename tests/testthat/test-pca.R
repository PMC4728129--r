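# Probabilistic PCA with missing values, promax rotation, projection,
# local PCA and ordination quality.

test_that("on complete data the EM fit matches standard PCA", {
  set.seed(20)
  x <- simulate_feature_matrix(100, 33, k = 3, seed = 20)
  m <- vbpca_fit(x, n_components = 2)
  expect_true(m$converged)
  pc <- prcomp(scale(x))
  for (j in 1:2)
    expect_gt(abs(cor(m$scores[, j], pc$x[, j])), 0.99)
  shares_pc <- pc$sdev[1:2]^2 / sum(pc$sdev^2)
  expect_equal(m$shares, shares_pc, tolerance = 0.01)
  expect_true(all(diff(m$shares) <= 1e-8))
})

test_that("masked low-rank structure is recovered", {
  set.seed(21)
  z <- matrix(rnorm(120), 120, 1)
  w <- matrix(rnorm(33), 1, 33)
  x <- z %*% w + 0.1 * matrix(rnorm(120 * 33), 120, 33)
  xm <- apply_missingness(x, 0.2, seed = 21)
  m <- vbpca_fit(xm, n_components = 2)
  dir_true <- as.numeric(w) * apply(x, 2, sd)^-1  # loading on z-scale
  cosine <- abs(sum(m$loadings[, 1] * dir_true)) /
    (sqrt(sum(m$loadings[, 1]^2)) * sqrt(sum(dir_true^2)))
  expect_gt(cosine, 0.95)
})

test_that("isotropic noise has no dominant components", {
  set.seed(22)
  x <- matrix(rnorm(150 * 33), 150, 33)
  m <- vbpca_fit(x, n_components = 2)
  expect_true(all(m$shares < 1 / 33 + 0.05))
})

test_that("promax rotation preserves the data approximation", {
  set.seed(23)
  x <- simulate_feature_matrix(80, 20, k = 2, factor_sd = 2, seed = 23)
  m <- vbpca_fit(x, n_components = 2)
  recon_before <- m$scores %*% t(m$loadings)
  r <- promax_rotate(m)
  recon_after <- r$scores %*% t(r$loadings)
  expect_lt(sqrt(sum((recon_before - recon_after)^2)), 1e-8)

  # already-simple loadings: rotation is (close to) the identity
  simple <- list(loadings = rbind(matrix(c(1, 0), 5, 2, byrow = TRUE) * 0.9,
                                  matrix(c(0, 1), 5, 2, byrow = TRUE) * 0.9),
                 scores = matrix(rnorm(20), 10, 2), sigma2 = 0.01,
                 shares = c(0.4, 0.3), col_means = rep(0, 10),
                 col_sds = rep(1, 10), center = rep(0, 10),
                 standardize = TRUE, converged = TRUE, n_iter = 1,
                 rotation = NULL)
  class(simple) <- "pca_model"
  rs <- promax_rotate(simple)
  expect_lt(max(abs(abs(rs$loadings) - abs(simple$loadings))), 1e-6)
})

test_that("two-block structure is simple after rotation", {
  set.seed(24)
  z <- matrix(rnorm(200 * 2), 200, 2)
  L <- rbind(cbind(runif(10, 0.8, 1.2), 0), cbind(0, runif(10, 0.8, 1.2)))
  x <- z %*% t(L) + 0.25 * matrix(rnorm(200 * 20), 200, 20)
  m <- promax_rotate(vbpca_fit(x, n_components = 2))
  dom <- apply(abs(m$loadings), 1, max) /
    sqrt(rowSums(m$loadings^2))
  expect_true(all(dom > 0.8))
})

test_that("projection reproduces fit scores and handles missingness", {
  set.seed(25)
  x <- simulate_feature_matrix(90, 33, k = 3, seed = 25)
  m <- vbpca_fit(x, n_components = 2)
  proj <- vbpca_project(m, x)
  expect_equal(proj, m$scores, tolerance = 1e-6, ignore_attr = TRUE)

  mean_cell <- matrix(m$col_means, 1)
  expect_lt(max(abs(vbpca_project(m, mean_cell))), 0.05)

  # known-score synthetic cell with 30% of entries masked: near-noiseless
  # rank-2 data, so the observed entries pin the score down
  z2 <- matrix(rnorm(120 * 2), 120, 2)
  w2 <- qr.Q(qr(matrix(rnorm(33 * 2), 33, 2))) * 2
  x2 <- z2 %*% t(w2) + 0.05 * matrix(rnorm(120 * 33), 120, 33)
  m2 <- vbpca_fit(x2, n_components = 2)
  cellm <- x2[5, ]; cellm[sample(33, 10)] <- NA
  sc <- vbpca_project(m2, matrix(cellm, 1))
  err <- sqrt(sum((sc - m2$scores[5, ])^2)) / sd(m2$scores[, 1])
  expect_lt(err, 0.3)

  empty <- matrix(NA_real_, 1, 33)
  expect_true(all(is.na(vbpca_project(m, empty))))
})

test_that("local PCA share and ordination quality behave", {
  set.seed(26)
  z <- matrix(rnorm(40 * 2), 40, 2)
  planar <- z %*% matrix(rnorm(2 * 10), 2, 10)
  expect_equal(local_pca_variance(planar), 1, tolerance = 1e-9)

  iso <- matrix(rnorm(50 * 33), 50, 33)
  expect_lt(local_pca_variance(iso), 0.25)

  corr <- iso
  corr[, 1:10] <- corr[, 1] + 0.3 * matrix(rnorm(50 * 10), 50, 10)
  expect_gt(local_pca_variance(corr), local_pca_variance(iso))
  expect_error(local_pca_variance(iso[1:2, ]))

  pts2 <- matrix(rnorm(60 * 2), 60, 2)
  expect_equal(ordination_quality(pts2, pts2), 1, tolerance = 1e-12)

  full <- simulate_feature_matrix(100, 33, k = 2, factor_sd = 2, seed = 9)
  rand <- matrix(rnorm(200), 100, 2)
  expect_lt(ordination_quality(rand, full), 0.1)
  pc <- prcomp(scale(full))$x[, 1:2]
  rp <- scale(full) %*% qr.Q(qr(matrix(rnorm(33 * 2), 33, 2)))
  expect_gte(ordination_quality(pc, scale(full)),
             ordination_quality(rp, scale(full)))
})
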