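# Correlation screening, FDR, and principal-variables rankings.

test_that("pairwise correlations enumerate all pairs and handle misses", {
  set.seed(12)
  x <- matrix(rnorm(50 * 33), 50, 33, dimnames = list(NULL, FEATURE_NAMES))
  tab <- pairwise_correlations(x)
  expect_equal(nrow(tab), choose(33, 2))
  expect_equal(nrow(tab), 528)

  y <- cbind(a = 1:20, b = 2 * (1:20), c = rnorm(20))
  t2 <- pairwise_correlations(y)
  ab <- t2[t2$var1 == "a" & t2$var2 == "b", ]
  expect_equal(ab$r, 1, tolerance = 1e-12)
  expect_lt(ab$p, 1e-20)

  # constant column and sparse overlap are reported missing
  z <- cbind(u = rep(1, 10), v = rnorm(10), w = c(rnorm(2), rep(NA, 8)))
  t3 <- pairwise_correlations(z)
  expect_true(is.na(t3$r[t3$var1 == "u" & t3$var2 == "v"]))
  expect_true(is.na(t3$r[t3$var1 == "v" & t3$var2 == "w"]))
})

test_that("null data rarely shows sizeable correlations", {
  set.seed(13)
  x <- matrix(rnorm(100 * 20), 100, 20)
  tab <- pairwise_correlations(x)
  expect_gte(mean(abs(tab$r) < 0.3), 0.95)
})

test_that("BH adjustment matches hand-worked and brute-force cases", {
  r <- fdr_adjust(c(0.01, 0.04, 0.03, 0.005), alpha = 0.05)
  expect_true(all(r$significant))
  expect_equal(r$threshold, 0.04)

  expect_equal(fdr_adjust(rep(0.01, 528))$n_significant, 528L)
  expect_equal(fdr_adjust(rep(1, 20))$n_significant, 0L)
  expect_length(fdr_adjust(numeric(0))$significant, 0)

  set.seed(14)
  for (rep in 1:50) {
    m <- sample(1:6, 1)
    p <- round(runif(m), 3)
    expect_equal(fdr_adjust(p, 0.05)$significant, bh_oracle(p, 0.05))
    # cross-check against the stats implementation
    expect_equal(fdr_adjust(p, 0.05)$significant,
                 p.adjust(p, "BH") <= 0.05)
  }
})

test_that("single-variable explained variance has the 1/p noise floor", {
  p <- 33
  corr <- diag(p)
  corr[2:p, 2:p] <- 0.5; diag(corr) <- 1
  ev <- explained_variance_single(corr)
  expect_equal(unname(ev[1]), 1 / 33, tolerance = 1e-12)

  two <- matrix(1, 2, 2)
  expect_equal(unname(explained_variance_single(two)), c(1, 1))

  set.seed(15)
  x <- matrix(rnorm(200 * 10), 200, 10)
  shares <- explained_variance_single(cor(x))
  expect_true(all(shares > 0.10 & shares < 0.25))
})

test_that("subset explained variance behaves at its extremes", {
  set.seed(16)
  x <- matrix(rnorm(300 * 33), 300, 33)
  expect_equal(explained_variance_subset(x, 1:33), 1)
  # independent columns: the subset explains only itself, plus the
  # finite-sample R^2 expectation k/(n-1) for each of the other columns
  n <- nrow(x)
  expected <- (5 + 28 * 5 / (n - 1)) / 33
  expect_equal(explained_variance_subset(x, 1:5), expected,
               tolerance = 0.05)

  # two-factor construction: the factor proxies explain most variance
  z <- matrix(rnorm(300 * 2), 300, 2)
  load <- matrix(rnorm(2 * 31), 2, 31)
  y <- cbind(z, z %*% load + 0.3 * matrix(rnorm(300 * 31), 300, 31))
  expect_gte(explained_variance_subset(y, 1:2), 0.8)
})
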