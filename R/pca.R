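# Probabilistic PCA with missing values (EM over observed entries),
# promax rotation, projection of new data, and local PCA summaries.

#' Probabilistic PCA with missing values
#'
#' Fits the probabilistic PCA model `x = W t + mu + noise` by
#' expectation-maximization over the observed entries only, the standard
#' approach for principal component estimation when a substantial fraction
#' of a feature matrix is missing. Columns are standardized on their
#' observed entries first (configurable). Initialization is deterministic
#' (SVD of the mean-imputed matrix); convergence is declared when the
#' relative change in expected reconstruction error drops below `tol`.
#' After convergence the loadings are rotated to principal axes (making
#' them orthogonal with non-increasing explained-variance shares, computed
#' on observed entries only).
#'
#' @param x Numeric matrix, cells x variables, NAs allowed (missing
#'   fraction must be below 50\%).
#' @param n_components Number of components (default 2).
#' @param tol Relative convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 5000).
#' @param standardize Standardize columns on observed entries (default
#'   TRUE).
#' @return A `pca_model`: list with `loadings` (p x k), `scores` (n x k),
#'   `sigma2`, `shares` (explained-variance fractions), `col_means`,
#'   `col_sds`, `center`, `converged`, `n_iter`, `rotation` (NULL until
#'   [promax_rotate()] is applied).
#' @export
vbpca_fit <- function(x, n_components = 2, tol = 1e-6, max_iter = 5000,
                      standardize = TRUE) {
  x <- as.matrix(x)
  miss_frac <- mean(!is.finite(x))
  if (miss_frac >= 0.5) stop("missing fraction must be below 50%")
  n <- nrow(x); p <- ncol(x); k <- n_components
  col_means <- apply(x, 2, mean, na.rm = TRUE)
  col_sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  col_sds[!is.finite(col_sds) | col_sds == 0] <- 1
  xs <- if (standardize) sweep(sweep(x, 2, col_means), 2, col_sds, "/")
        else sweep(x, 2, col_means)
  obs <- is.finite(xs)
  x0 <- xs; x0[!obs] <- 0
  sv <- svd(x0, nu = 0, nv = k)
  W <- sv$v %*% diag(sv$d[seq_len(k)] / sqrt(n), k)
  mu <- rep(0, p)
  sigma2 <- max(mean(x0[obs]^2) - sum(sv$d[seq_len(k)]^2) / (n * p), 1e-4)
  Tm <- matrix(0, n, k)
  err_old <- Inf; converged <- FALSE; it <- 0
  obs_list <- apply(obs, 1, which, simplify = FALSE)
  repeat {
    it <- it + 1
    # E-step
    SS <- matrix(0, k, k); seen <- vector("list", n)
    for (i in seq_len(n)) {
      oi <- obs_list[[i]]
      Wo <- W[oi, , drop = FALSE]
      M <- solve(crossprod(Wo) + sigma2 * diag(k))
      ti <- M %*% crossprod(Wo, xs[i, oi] - mu[oi])
      Tm[i, ] <- ti
      seen[[i]] <- sigma2 * M + tcrossprod(ti)
    }
    # M-step: mean, loadings, noise
    R <- xs - Tm %*% t(W)
    mu <- vapply(seq_len(p), function(j)
      mean(R[obs[, j], j]), numeric(1))
    for (j in seq_len(p)) {
      ii <- which(obs[, j])
      A <- Reduce(`+`, seen[ii])
      b <- crossprod(Tm[ii, , drop = FALSE], xs[ii, j] - mu[j])
      W[j, ] <- solve(A, b)
    }
    recon <- sweep(Tm %*% t(W), 2, mu, "+")
    resid2 <- (xs - recon)^2
    err <- sum(resid2[obs])
    tr_term <- 0
    for (i in seq_len(n)) {
      oi <- obs_list[[i]]
      Wo <- W[oi, , drop = FALSE]
      tr_term <- tr_term +
        sum((seen[[i]] - tcrossprod(Tm[i, ])) * crossprod(Wo))
    }
    sigma2 <- max((err + tr_term) / sum(obs), 1e-9)
    if (is.finite(err_old) && abs(err_old - err) <= tol * err_old) {
      converged <- TRUE; break
    }
    if (it >= max_iter) break
    err_old <- err
  }
  # refresh scores against the final loadings (the loop's E-step ran
  # before the last M-step), then rotate to principal axes
  for (i in seq_len(n)) {
    oi <- obs_list[[i]]
    Wo <- W[oi, , drop = FALSE]
    M <- solve(crossprod(Wo) + sigma2 * diag(k))
    Tm[i, ] <- M %*% crossprod(Wo, xs[i, oi] - mu[oi])
  }
  eg <- eigen(crossprod(W), symmetric = TRUE)
  W <- W %*% eg$vectors
  Tm <- Tm %*% eg$vectors
  tot <- sum(xs[obs]^2)
  shares <- vapply(seq_len(k), function(j) {
    comp <- tcrossprod(Tm[, j], W[, j])
    sum(comp[obs] * (2 * (xs[obs] - mu[col(xs)[obs]]) - comp[obs])) / tot
  }, numeric(1))
  shares <- pmax(pmin(shares, 1), 0)
  structure(list(loadings = W, scores = Tm, sigma2 = sigma2,
                 shares = shares, col_means = col_means,
                 col_sds = col_sds, center = mu,
                 standardize = standardize,
                 converged = converged, n_iter = it, rotation = NULL,
                 var_names = colnames(x)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", ncol(x$loadings), "components,",
      if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations; shares:",
      paste(signif(x$shares, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Promax oblique rotation of a fitted PCA model
#'
#' Varimax orthogonal rotation followed by oblique Procrustes rotation
#' toward the power-`m` simplified target (the conventional promax
#' procedure). Scores are counter-rotated so the data approximation
#' `scores %*% t(loadings)` is unchanged.
#'
#' @param model A `pca_model` with >= 2 components.
#' @param m Promax power (default 4).
#' @return The model with rotated `loadings` and `scores` and the total
#'   `rotation` matrix recorded.
#' @export
promax_rotate <- function(model, m = 4) {
  stopifnot(inherits(model, "pca_model"), ncol(model$loadings) >= 2)
  vm <- stats::varimax(model$loadings, normalize = FALSE)
  pm <- stats::promax(unclass(vm$loadings), m = m)
  Rtot <- vm$rotmat %*% pm$rotmat
  model$loadings <- model$loadings %*% Rtot
  model$scores <- model$scores %*% t(solve(Rtot))
  model$rotation <- Rtot
  model
}

#' Project new cells into a fitted PCA space
#'
#' Regression-based scoring on the observed entries of each new cell,
#' using the model loadings, means and SDs; the same formula the EM fit
#' uses for its own E-step, so projecting the training data reproduces
#' the fit scores. Rotation, if applied to the model, is applied to the
#' projected scores as well.
#'
#' @param model A `pca_model`.
#' @param newdata Matrix with the same variable set (NAs allowed).
#' @return Matrix of scores (rows with no observed variables are NA).
#' @export
vbpca_project <- function(model, newdata) {
  x <- as.matrix(newdata)
  stopifnot(ncol(x) == length(model$col_means))
  xs <- sweep(x, 2, model$col_means)
  if (model$standardize) xs <- sweep(xs, 2, model$col_sds, "/")
  W <- model$loadings; k <- ncol(W)
  if (!is.null(model$rotation)) {
    # score in the unrotated basis, then rotate like the fit scores
    W <- W %*% solve(model$rotation)
  }
  out <- t(vapply(seq_len(nrow(xs)), function(i) {
    oi <- which(is.finite(xs[i, ]))
    if (!length(oi)) return(rep(NA_real_, k))
    Wo <- W[oi, , drop = FALSE]
    M <- solve(crossprod(Wo) + model$sigma2 * diag(k))
    as.numeric(M %*% crossprod(Wo, xs[i, oi] - model$center[oi]))
  }, numeric(k)))
  if (!is.null(model$rotation)) out <- out %*% t(solve(model$rotation))
  rownames(out) <- rownames(newdata)
  out
}

#' Share of variance captured by the first components of a local PCA
#'
#' Standard PCA on standardized complete data for one group of cells;
#' returns `(lambda_1 + ... + lambda_k) / sum(lambda)`.
#'
#' @param x Complete numeric matrix (one group).
#' @param n_components Components to sum (default 2).
#' @return Scalar share in `[0, 1]`.
#' @export
local_pca_variance <- function(x, n_components = 2) {
  if (nrow(x) < 3) stop("need at least 3 cells")
  if (anyNA(x)) stop("local PCA needs complete (imputed) data")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  sum(pc$sdev[seq_len(n_components)]^2) / sum(pc$sdev^2)
}

#' Quality of a 2D ordination relative to the full space
#'
#' Squared Pearson correlation between all pairwise distances in the 2D
#' embedding and in the full-dimensional space.
#'
#' @param coords_2d Embedding coordinates (n x 2).
#' @param full_points Full-space data (n x p), same row order.
#' @param metric Distance metric for both spaces.
#' @return Scalar R^2, or NA for degenerate (constant) distances.
#' @export
ordination_quality <- function(coords_2d, full_points,
                               metric = "euclidean") {
  stopifnot(nrow(coords_2d) == nrow(full_points))
  d2 <- as.numeric(stats::dist(coords_2d, method = metric))
  df <- as.numeric(stats::dist(full_points, method = metric))
  if (stats::sd(d2) == 0 || stats::sd(df) == 0) return(NA_real_)
  stats::cor(d2, df)^2
}
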