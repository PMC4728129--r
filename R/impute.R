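# Gaussian chained-equations multiple imputation and the
# imputation + subsampling machinery for cloud geometry, clustering
# coefficient and local PCA comparisons.

#' Multiple imputation by Gaussian chained equations
#'
#' For each of `n_imputations` replicates: missing entries are
#' initialized from the marginal column distributions, then each column
#' with missing values is repeatedly regressed on all other columns with
#' a posterior draw of the coefficients and residual variance (Bayesian
#' linear imputation), and missing entries are replaced by posterior
#' predictive draws. Every replicate is reproducible from
#' `(seed, replicate index)`.
#'
#' @param x Numeric matrix with NAs (missing fraction < 50\%).
#' @param n_imputations Number of completed matrices (default 50).
#' @param n_sweeps Chained-equation passes per replicate (default 5).
#' @param seed Integer seed.
#' @param ridge Ridge added to the normal equations for stability.
#' @return List of complete matrices. Columns with fewer than 3 observed
#'   values are mean-imputed with a warning.
#' @export
impute_matrix <- function(x, n_imputations = 50, n_sweeps = 5, seed = 1L,
                          ridge = 1e-4) {
  x <- as.matrix(x)
  if (mean(!is.finite(x)) >= 0.5) stop("missing fraction must be < 50%")
  obs <- is.finite(x)
  if (all(obs)) return(replicate(n_imputations, x, simplify = FALSE))
  p <- ncol(x)
  mu <- apply(x, 2, mean, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sparse_cols <- which(colSums(obs) < 3)
  if (length(sparse_cols))
    warning("columns with < 3 observations are mean-imputed: ",
            paste(sparse_cols, collapse = ", "))
  lapply(seq_len(n_imputations), function(m) {
    local_rng(seed * 131L + m, {
      xi <- x
      for (j in seq_len(p)) {
        nm <- which(!obs[, j])
        if (!length(nm)) next
        xi[nm, j] <- if (j %in% sparse_cols) mu[j]
          else stats::rnorm(length(nm), mu[j], sdv[j])
      }
      fill_cols <- setdiff(which(colSums(!obs) > 0), sparse_cols)
      for (sweep_i in seq_len(n_sweeps)) {
        for (j in fill_cols) {
          oi <- which(obs[, j]); ni <- which(!obs[, j])
          X <- cbind(1, xi[, -j, drop = FALSE])
          Xo <- X[oi, , drop = FALSE]
          y <- xi[oi, j]
          A <- crossprod(Xo) + ridge * diag(ncol(X))
          bhat <- solve(A, crossprod(Xo, y))
          res <- y - Xo %*% bhat
          df <- max(length(oi) - ncol(X), 3)
          sig2 <- sum(res^2) / stats::rchisq(1, df)
          Ainv <- solve(A)
          beta <- bhat + t(chol(sig2 * (Ainv + t(Ainv)) / 2)) %*%
            stats::rnorm(ncol(X))
          xi[ni, j] <- X[ni, , drop = FALSE] %*% beta +
            stats::rnorm(length(ni), 0, sqrt(sig2))
        }
      }
      xi
    })
  })
}

#' Median pairwise distance of a point cloud
#'
#' @param points Numeric matrix (>= 2 rows).
#' @param metric `"euclidean"` or `"manhattan"` (city-block).
#' @return Median over all pairwise distances.
#' @export
cloud_median_distance <- function(points,
                                  metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  stopifnot(nrow(points) >= 2)
  stats::median(stats::dist(points, method = metric))
}

#' Agglomerative nesting (AGNES) coefficient
#'
#' Average-linkage agglomerative clustering; the coefficient is the mean
#' over points of `1 - (height of the point's first merge) / (height of
#' the final merge)`. Values near 1 indicate strong clustering; near 0, a
#' structureless (e.g. equidistant) configuration. Scale-invariant.
#'
#' @param points Numeric matrix (>= 3 rows).
#' @param metric Dissimilarity metric.
#' @return Coefficient in `[0, 1]`.
#' @export
agnes_coefficient <- function(points,
                              metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (nrow(points) < 3) stop("need at least 3 points")
  ag <- cluster::agnes(stats::dist(points, method = metric),
                       method = "average")
  unname(ag$ac)
}

#' Imputation + subsampling analysis engine
#'
#' The resampling scheme for comparing cloud geometry and internal
#' structure between groups on incomplete data: the feature matrix is
#' column-standardized, multiply imputed, and within each imputation each
#' group is subsampled (without replacement) to a fixed size several
#' times; a statistic is computed on every subsample. With 50 imputations
#' and 10 subsamples this yields 500 values per group.
#'
#' @param x Feature matrix (cells x variables) with NAs.
#' @param groups Factor/character vector, one entry per row.
#' @param stat Function of a complete numeric matrix returning a scalar
#'   (e.g. median city-block distance, AGNES coefficient, local-PCA
#'   share).
#' @param n_imputations,n_subsamples,subsample_size Resampling scheme
#'   (defaults 50, 10, 50).
#' @param seed Integer seed.
#' @return data.frame with `group`, `imputation`, `subsample`, `value`.
#' @export
imputed_subsample_stat <- function(x, groups, stat,
                                   n_imputations = 50, n_subsamples = 10,
                                   subsample_size = 50, seed = 1L) {
  stopifnot(nrow(x) == length(groups))
  xs <- scale(x)
  imps <- impute_matrix(xs, n_imputations = n_imputations, seed = seed)
  glev <- unique(as.character(groups))
  out <- list()
  for (m in seq_along(imps)) {
    xi <- imps[[m]]
    draws <- local_rng(seed * 977L + m, {
      lapply(glev, function(g) {
        rows <- which(groups == g)
        ss <- min(subsample_size, length(rows))
        lapply(seq_len(n_subsamples), function(s) sample(rows, ss))
      })
    })
    for (gi in seq_along(glev)) for (s in seq_len(n_subsamples)) {
      out[[length(out) + 1L]] <- data.frame(
        group = glev[gi], imputation = m, subsample = s,
        value = stat(xi[draws[[gi]][[s]], , drop = FALSE]))
    }
  }
  do.call(rbind, out)
}

#' Compare cloud sizes between two groups on incomplete data
#'
#' Runs [imputed_subsample_stat()] with the median city-block pairwise
#' distance and compares the two groups' sets of medians with a Welch
#' t-test.
#'
#' @inheritParams imputed_subsample_stat
#' @return List with the per-group mean +/- SD of the medians, the ratio
#'   of group means, and the Welch `p_value`.
#' @export
cloud_size_compare <- function(x, groups, n_imputations = 50,
                               n_subsamples = 10, subsample_size = 50,
                               seed = 1L) {
  res <- imputed_subsample_stat(
    x, groups, function(pts) cloud_median_distance(pts, "manhattan"),
    n_imputations, n_subsamples, subsample_size, seed)
  glev <- unique(res$group)
  stopifnot(length(glev) == 2)
  v1 <- res$value[res$group == glev[1]]
  v2 <- res$value[res$group == glev[2]]
  tt <- stats::t.test(v2, v1)
  list(group_means = stats::setNames(c(mean(v1), mean(v2)), glev),
       group_sds = stats::setNames(c(stats::sd(v1), stats::sd(v2)), glev),
       ratio = mean(v2) / mean(v1), p_value = tt$p.value, values = res)
}
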