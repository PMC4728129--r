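# Correlation screening with FDR control and principal-variable
# explained-variance rankings.

#' All pairwise correlations of a feature matrix
#'
#' Computes pairwise-complete-observation correlations for every variable
#' pair (C(p,2) rows). Pairs with fewer than `min_n` shared observations,
#' or involving a constant variable, are reported with missing statistics.
#'
#' @param x Numeric matrix, cells x variables (NAs allowed).
#' @param method `"pearson"` or `"spearman"`.
#' @param min_n Minimum shared observations to test a pair (default 3).
#' @return data.frame with `var1`, `var2`, `r`, `p`, `n`.
#' @export
pairwise_correlations <- function(x, method = c("pearson", "spearman"),
                                  min_n = 3) {
  method <- match.arg(method)
  p <- ncol(x)
  nm <- colnames(x) %||% paste0("V", seq_len(p))
  pairs <- utils::combn(p, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    ok <- is.finite(x[, i]) & is.finite(x[, j])
    n <- sum(ok)
    if (n < min_n || stats::sd(x[ok, i]) == 0 || stats::sd(x[ok, j]) == 0)
      return(c(r = NA_real_, p = NA_real_, n = n))
    ct <- suppressWarnings(
      stats::cor.test(x[ok, i], x[ok, j], method = method, exact = FALSE))
    c(r = unname(ct$estimate), p = ct$p.value, n = n)
  })
  data.frame(var1 = nm[pairs[1, ]], var2 = nm[pairs[2, ]],
             r = res["r", ], p = res["p", ], n = as.integer(res["n", ]))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up procedure: sort the m p-values, find the largest k with
#' `p_(k) <= k * alpha / m`, and call all p-values up to `p_(k)`
#' significant. Also returns the implied per-test p threshold (the
#' largest passing p-value).
#'
#' @param pvalues Numeric vector in `[0, 1]`; NAs count toward `m` but are
#'   never significant.
#' @param alpha Target false discovery rate.
#' @return List with `significant` (logical mask), `threshold` (implied p
#'   cutoff, NA when nothing passes) and `n_significant`.
#' @export
fdr_adjust <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (m == 0)
    return(list(significant = logical(0), threshold = NA_real_,
                n_significant = 0L))
  ok <- which(is.finite(pvalues))
  sig <- rep(FALSE, m)
  if (length(ok)) {
    ps <- pvalues[ok]
    ord <- order(ps)
    crit <- seq_along(ps) * alpha / m
    pass <- which(ps[ord] <= crit)
    if (length(pass)) {
      kmax <- max(pass)
      sig[ok[ord[seq_len(kmax)]]] <- TRUE
    }
  }
  thr <- if (any(sig)) max(pvalues[sig]) else NA_real_
  list(significant = sig, threshold = thr, n_significant = sum(sig))
}

#' Variance explained by each single variable (principal variables)
#'
#' For each variable, the share of total dataset variance it explains is
#' the mean over all p variables of the squared correlation with it (the
#' squared-RM criterion for singleton subsets; the self term contributes
#' 1/p). An ideally uncorrelated variable therefore scores the noise
#' floor `1/p`.
#'
#' @param corr p x p correlation matrix (NAs tolerated: the mean is taken
#'   over available entries).
#' @return Named numeric vector of shares in `[0, 1]`, one per variable.
#' @export
explained_variance_single <- function(corr) {
  stopifnot(nrow(corr) == ncol(corr))
  diag(corr) <- 1
  apply(corr^2, 1, mean, na.rm = TRUE)
}

#' Variance explained by a subset of variables
#'
#' Mean over all p variables of the multiple-R^2 from regressing each
#' variable on the subset (variables inside the subset contribute 1).
#' Requires complete (or imputed) data; a singular design is
#' ridge-stabilized with a warning.
#'
#' @param x Complete numeric matrix, cells x variables.
#' @param subset Column names or indices of the explanatory subset.
#' @return Scalar share in `[0, 1]`.
#' @export
explained_variance_subset <- function(x, subset) {
  stopifnot(length(subset) >= 1)
  if (is.character(subset)) subset <- match(subset, colnames(x))
  if (anyNA(subset)) stop("unknown variable in subset")
  if (anyNA(x)) stop("subset explained variance needs complete data")
  p <- ncol(x)
  S <- scale(x[, subset, drop = FALSE])
  xtx <- crossprod(S)
  if (kappa(xtx) > 1e10) {
    warning("singular subset design; ridge-stabilized")
    xtx <- xtx + diag(1e-8 * nrow(S), ncol(S))
  }
  r2 <- vapply(seq_len(p), function(j) {
    if (j %in% subset) return(1)
    y <- scale(x[, j])
    beta <- solve(xtx, crossprod(S, y))
    fit <- S %*% beta
    1 - sum((y - fit)^2) / sum(y^2)
  }, numeric(1))
  mean(r2)
}
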