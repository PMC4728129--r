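# Multiple imputation, cloud geometry, and the AGNES coefficient.

test_that("imputation reproduces complete data and beats the marginal", {
  set.seed(30)
  # strong factor structure: other variables carry real information
  x <- simulate_feature_matrix(80, 10, k = 2, factor_sd = 2, seed = 30)
  imps <- impute_matrix(x, n_imputations = 3, seed = 1)
  expect_length(imps, 3)
  for (im in imps) expect_identical(im, x)

  xm <- apply_missingness(x, 0.2, seed = 5)
  mask <- is.na(xm)
  imps <- impute_matrix(xm, n_imputations = 10, seed = 2)
  # observed entries never change
  expect_equal(imps[[1]][!mask], x[!mask])
  # the pooled (across-imputation mean) estimate beats mean imputation
  pooled <- Reduce(`+`, imps) / length(imps)
  err <- sqrt(mean((pooled[mask] - x[mask])^2))
  mu <- matrix(colMeans(xm, na.rm = TRUE), nrow(x), ncol(x), byrow = TRUE)
  base <- sqrt(mean((mu[mask] - x[mask])^2))
  expect_lt(err, base)
  # posterior draws differ across imputations for every masked entry
  spread <- apply(vapply(imps, function(im) im[mask],
                         numeric(sum(mask))), 1, sd)
  expect_true(all(spread > 0))
  # reproducible from (seed, index)
  again <- impute_matrix(xm, n_imputations = 10, seed = 2)
  expect_identical(imps, again)
})

test_that("cloud median distance has the expected geometry", {
  sq <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)
  expect_equal(cloud_median_distance(sq), 1)  # median of {1 x4, sqrt2 x2}
  expect_equal(cloud_median_distance(2 * sq), 2)

  set.seed(31)
  a <- matrix(rnorm(200 * 5), 200, 5)
  ratios <- replicate(20, {
    ia <- sample(200, 50); ib <- sample(200, 50)
    cloud_median_distance(1.4 * a[ib, , drop = FALSE]) /
      cloud_median_distance(a[ia, , drop = FALSE])
  })
  expect_equal(mean(ratios), 1.4, tolerance = 0.05)
})

test_that("AGNES coefficient matches its merge-height definition", {
  set.seed(32)
  # two tight, well-separated blobs
  blobs <- rbind(matrix(rnorm(60, 0, 0.01), 30, 2),
                 matrix(rnorm(60, 10, 0.01), 30, 2))
  expect_gt(agnes_coefficient(blobs), 0.95)

  # three equidistant points: all merge heights equal, coefficient 0
  tri <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), ncol = 2, byrow = TRUE)
  expect_equal(agnes_coefficient(tri), 0, tolerance = 1e-9)

  # scale invariance and agreement with the first-principles oracle
  pts <- matrix(rnorm(40 * 3), 40, 3)
  expect_equal(agnes_coefficient(pts), agnes_coefficient(5 * pts),
               tolerance = 1e-9)
  expect_equal(agnes_coefficient(pts), agnes_oracle(pts),
               tolerance = 1e-9)
})

test_that("AGNES coefficient grows as subpopulations separate", {
  set.seed(33)
  base <- matrix(rnorm(80 * 2), 80, 2)
  coefs <- vapply(c(0, 2, 4, 8), function(sep) {
    x <- base; x[41:80, 1] <- x[41:80, 1] + sep
    agnes_coefficient(x)
  }, numeric(1))
  expect_true(all(diff(coefs) > 0))
})

test_that("the imputation + subsampling engine yields per-group values", {
  set.seed(34)
  x <- rbind(simulate_feature_matrix(30, 8, seed = 1),
             simulate_feature_matrix(30, 8, seed = 2))
  xm <- apply_missingness(x, 0.15, seed = 3)
  g <- rep(c("a", "b"), each = 30)
  res <- imputed_subsample_stat(xm, g,
                                function(p) cloud_median_distance(p, "manhattan"),
                                n_imputations = 4, n_subsamples = 3,
                                subsample_size = 20, seed = 1)
  expect_equal(nrow(res), 4 * 3 * 2)
  expect_true(all(res$value > 0))
})
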