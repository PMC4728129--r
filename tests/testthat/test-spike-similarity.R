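# Victor-Purpura metric, distance matrices, classical MDS and
# nearest-neighbor group pulls.

test_that("vp_distance matches closed-form cases", {
  expect_equal(vp_distance(c(10, 20, 30), c(10, 20, 30)), 0)
  expect_equal(vp_distance(10, numeric(0)), 1)
  expect_equal(vp_distance(numeric(0), numeric(0)), 0)
  expect_equal(vp_distance(10, 15, q = 0.1), 0.5)     # min(2, 0.1 * 5)
  expect_equal(vp_distance(10, 60, q = 0.1), 2)       # shift capped at 2
  expect_equal(vp_distance(c(1, 2), c(1, 2, 50)), 1)  # one insertion
  # q = 0 reduces to the count difference
  expect_equal(vp_distance(c(1, 5, 9), c(100, 300), q = 0), 1)
})

test_that("vp_distance agrees with the brute-force recursion", {
  set.seed(7)
  for (rep in 1:60) {
    a <- sort(runif(sample(0:8, 1), 0, 200))
    b <- sort(runif(sample(0:8, 1), 0, 200))
    q <- sample(c(0.02, 0.1, 1), 1)
    expect_equal(vp_distance(a, b, q), vp_oracle(a, b, q), tolerance = 1e-10)
  }
})

test_that("vp_distance is a metric bounded by delete-all", {
  set.seed(8)
  for (rep in 1:40) {
    tr <- lapply(1:3, function(i) sort(runif(sample(0:6, 1), 0, 100)))
    d_ab <- vp_distance(tr[[1]], tr[[2]])
    d_ba <- vp_distance(tr[[2]], tr[[1]])
    d_ac <- vp_distance(tr[[1]], tr[[3]])
    d_cb <- vp_distance(tr[[3]], tr[[2]])
    expect_gte(d_ab, 0)
    expect_equal(d_ab, d_ba)
    expect_lte(d_ab, d_ac + d_cb + 1e-12)                 # triangle
    expect_lte(d_ab, length(tr[[1]]) + length(tr[[2]]))   # delete-all
  }
})

test_that("step trains concatenate in ascending current order", {
  got <- concat_step_trains(trains = list(c(50), c(60)),
                            currents = c(20, 40), sweep_ms = 500)
  expect_equal(got, c(50, 560))
  # shuffled sweep order yields the same combined train
  shuf <- concat_step_trains(trains = list(c(60), c(50)),
                             currents = c(40, 20), sweep_ms = 500)
  expect_equal(shuf, got)
  expect_length(concat_step_trains(trains = list(numeric(0), numeric(0)),
                                   currents = c(20, 40), sweep_ms = 500), 0)
})

test_that("distance matrices are symmetric and oracle-exact", {
  set.seed(9)
  trains <- lapply(1:5, function(i) sort(runif(sample(1:6, 1), 0, 300)))
  names(trains) <- paste0("c", 1:5)
  D <- distance_matrix(trains, q = 0.1)
  expect_equal(unclass(D), t(unclass(D)), ignore_attr = TRUE)
  expect_true(all(diag(D) == 0))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(D[i, j], vp_oracle(trains[[i]], trains[[j]], 0.1))
  same <- distance_matrix(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_true(all(unclass(same) == 0))
})

test_that("classical MDS embeds planar configurations exactly", {
  pts <- matrix(c(0, 0, 3, 0, 0, 4), ncol = 2, byrow = TRUE)
  D <- as.matrix(dist(pts))
  xy <- classical_mds(D, dims = 2)
  expect_equal(as.matrix(dist(xy)), D, tolerance = 1e-9, ignore_attr = TRUE)

  # duplicated points stay coincident
  D2 <- as.matrix(dist(rbind(pts, pts[1, ])))
  xy2 <- classical_mds(D2)
  expect_equal(xy2[1, ], xy2[4, ], tolerance = 1e-9)

  # irregular tetrahedron (distinct eigenvalues, so the truncation is
  # unique): 2D distances match the double-centered eigen oracle
  set.seed(77)
  tet <- matrix(rnorm(12), ncol = 3) * c(1, 2, 3, 4)
  Dt <- as.matrix(dist(tet))
  xyt <- classical_mds(Dt)
  B <- -0.5 * (diag(4) - 1 / 4) %*% Dt^2 %*% (diag(4) - 1 / 4)
  ev <- eigen(B, symmetric = TRUE)
  oracle <- ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))
  expect_equal(as.matrix(dist(xyt)), as.matrix(dist(oracle)),
               tolerance = 1e-8)

  z <- classical_mds(matrix(0, 4, 4))
  expect_true(all(z == 0))
})

test_that("nearest neighbor groups match the exhaustive sort", {
  set.seed(10)
  co <- matrix(rnorm(40), ncol = 2,
               dimnames = list(sprintf("c%02d", 1:20), NULL))
  g <- nearest_neighbor_group(co, "c05", k = 5)
  expect_length(g, 6)
  expect_equal(g[1], "c05")
  dd <- sqrt(colSums((t(co) - co["c05", ])^2))
  oracle <- setdiff(names(sort(dd)), "c05")[1:5]
  expect_setequal(g[-1], oracle)

  expect_equal(nearest_neighbor_group(co, "c01", k = 0), "c01")
  dup <- co; dup[2:6, ] <- rep(co[1, ], each = 5)
  rownames(dup) <- rownames(co)
  gd <- nearest_neighbor_group(dup, "c01", k = 5)
  expect_setequal(gd, sprintf("c%02d", 1:6))
  expect_error(nearest_neighbor_group(co, "c01", k = 20))
})
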