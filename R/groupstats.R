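# Group comparisons with effect sizes, sequential regression variance
# partitioning, and the rank-renormalization transform.

#' Directional variance-ratio (F) test
#'
#' Tests whether group `b` is more variable than group `a` (the
#' variability screen: "did the SD increase?"). Directional by default;
#' `alternative = "two.sided"` recovers the standard F test.
#'
#' @param a,b Numeric vectors.
#' @param alternative Passed to [stats::var.test()] (comparing `b`
#'   against `a`).
#' @return `htest` object from [stats::var.test()].
#' @export
variance_ratio_test <- function(a, b, alternative = "greater") {
  stats::var.test(b, a, alternative = alternative)
}

#' Per-variable group comparisons
#'
#' For every variable: group means and SDs; a rank-sum (Mann-Whitney)
#' test and Welch t-test between two contrast groups; a directional
#' variance-ratio test between the same contrast; one-way ANOVA across
#' all groups with the eta-squared effect size
#' (`SS_between / SS_total`); and the direction of change. Multiple
#' testing across variables is adjusted per test family as configured.
#'
#' @param x Feature matrix (cells x variables, NAs allowed).
#' @param groups Factor/character per row.
#' @param contrast Two group levels for the 2-group tests (default: first
#'   and last level in order of appearance).
#' @param var_alternative Alternative for the variance-ratio screen
#'   (default `"greater"`: does the second contrast group vary more?).
#' @param adjust `"BH"`, `"bonferroni"` or `"none"`.
#' @param min_n Minimum observations per group for a variable to be
#'   tested.
#' @return data.frame, one row per variable: group means/SDs, `p_mw`,
#'   `p_welch`, `p_var`, `p_anova`, `eta2`, `direction`, and adjusted
#'   versions of the p-value columns.
#' @export
group_compare <- function(x, groups, contrast = NULL,
                          var_alternative = "greater",
                          adjust = c("BH", "bonferroni", "none"),
                          min_n = 3) {
  adjust <- match.arg(adjust)
  groups <- as.character(groups)
  glev <- unique(groups)
  stopifnot(length(glev) >= 2)
  if (is.null(contrast)) contrast <- c(glev[1], glev[length(glev)])
  nm <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  rows <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    means <- tapply(v, groups, mean, na.rm = TRUE)[glev]
    sds <- tapply(v, groups, stats::sd, na.rm = TRUE)[glev]
    a <- v[groups == contrast[1] & is.finite(v)]
    b <- v[groups == contrast[2] & is.finite(v)]
    p_mw <- p_welch <- p_var <- NA_real_
    if (length(a) >= min_n && length(b) >= min_n) {
      p_mw <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
      p_welch <- stats::t.test(a, b)$p.value
      p_var <- variance_ratio_test(a, b, var_alternative)$p.value
    }
    ok <- is.finite(v)
    counts <- table(groups[ok])
    p_anova <- eta2 <- NA_real_
    if (sum(counts >= min_n) >= 2) {
      keep <- ok & groups %in% names(counts)[counts >= min_n]
      fit <- stats::aov(v[keep] ~ factor(groups[keep]))
      at <- summary(fit)[[1]]
      p_anova <- at[["Pr(>F)"]][1]
      eta2 <- at[["Sum Sq"]][1] / sum(at[["Sum Sq"]])
    }
    data.frame(variable = nm[j],
               t(stats::setNames(as.numeric(means),
                                 paste0("mean_", glev))),
               t(stats::setNames(as.numeric(sds), paste0("sd_", glev))),
               n_a = length(a), n_b = length(b),
               p_mw = p_mw, p_welch = p_welch, p_var = p_var,
               p_anova = p_anova, eta2 = eta2,
               direction = sign(mean(b) - mean(a)),
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust != "none") {
    for (cn in c("p_mw", "p_welch", "p_var", "p_anova"))
      out[[paste0(cn, "_adj")]] <- stats::p.adjust(out[[cn]],
                                                   method = adjust)
  }
  rownames(out) <- NULL
  out
}

#' Sequential (type-I) regression variance partitioning
#'
#' Fits a linear model with the predictors entered in the given order and
#' reports each term's sequential sum of squares as a share of the total
#' response variance, with the per-term F-test p-value. Optionally
#' interaction terms up to `interaction_order` are appended after the
#' main effects. Shares are order-dependent by construction.
#'
#' @param data data.frame or matrix containing response and predictors
#'   (complete cases are used).
#' @param response Response column name.
#' @param predictors Predictor column names, in entry order.
#' @param include_interactions Append interaction terms (default FALSE).
#' @param interaction_order Maximum interaction order (default 2).
#' @return data.frame: `term`, `df`, `ss`, `share`, `F`, `p`; plus rows
#'   for residuals. Aliased (collinear) terms are dropped with a warning.
#' @export
sequential_regression <- function(data, response, predictors,
                                  include_interactions = FALSE,
                                  interaction_order = 2) {
  df <- as.data.frame(data)
  names(df) <- make.names(names(df))
  response_s <- make.names(response)
  predictors_s <- make.names(predictors)
  stopifnot(response_s %in% names(df), all(predictors_s %in% names(df)))
  use <- stats::complete.cases(df[, c(response_s, predictors_s)])
  df <- df[use, ]
  main <- paste(predictors_s, collapse = " + ")
  fml <- if (include_interactions)
    sprintf("%s ~ %s + (%s)^%d - (%s)", response_s, main, main,
            interaction_order, main)
  else sprintf("%s ~ %s", response_s, main)
  fit <- stats::lm(stats::as.formula(fml), data = df)
  if (any(is.na(stats::coef(fit))))
    warning("collinear design: aliased terms dropped")
  at <- stats::anova(fit)
  ss_total <- sum(at[["Sum Sq"]])
  out <- data.frame(term = rownames(at), df = at[["Df"]],
                    ss = at[["Sum Sq"]],
                    share = at[["Sum Sq"]] / ss_total,
                    F = at[["F value"]], p = at[["Pr(>F)"]])
  rownames(out) <- NULL
  attr(out, "n") <- nrow(df)
  out
}

#' Rank renormalization (de-banding transform)
#'
#' Homeomorphic transform for banded measurements: values are rank
#' transformed and mapped back to the original units through a
#' least-squares cubic polynomial of the rank, with a final monotone
#' correction so the output ordering is exactly the input ordering (ties
#' broken by stable input order).
#'
#' @param values Numeric vector with >= 4 finite values (NAs pass
#'   through).
#' @return Transformed vector, same length and units.
#' @export
rank_renormalize <- function(values) {
  ok <- which(is.finite(values))
  if (length(ok) < 4) stop("need at least 4 finite values")
  x <- values[ok]
  r <- rank(x, ties.method = "first")
  fit <- stats::lm(x ~ stats::poly(r, 3, raw = TRUE))
  yhat <- as.numeric(stats::fitted(fit))
  # enforce strict monotonicity in rank order
  ord <- order(r)
  ys <- yhat[ord]
  eps <- max(diff(range(x)), 1) * 1e-9
  ys <- cummax(ys) + seq_along(ys) * eps
  out <- values
  out[ok][ord] <- ys
  out
}
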