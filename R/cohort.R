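# Cohort-level generation: full recordings, direct feature matrices, and
# completely-at-random masking.

#' Generate a full synthetic cohort
#'
#' Draws ground-truth parameters for every cell of the design and
#' simulates the requested protocols. Reproducible: cell seeds are derived
#' deterministically from the design seed.
#'
#' @param design A [cohort_design()].
#' @param protocols Which protocols to simulate for each cell.
#' @return List with `cells` (per-cell list: `params`, `recordings`,
#'   labels) and `truth` (data.frame of generative parameters per cell).
#' @export
make_cohort <- function(design,
                        protocols = c("iv_steps", "current_steps",
                                      "cosine", "synaptic",
                                      "spontaneous")) {
  stopifnot(inherits(design, "cohort_design"))
  cells <- list(); truth <- list(); idx <- 0L
  for (key in names(design$n_cells)) {
    nk <- design$n_cells[[key]]
    if (nk < 1) next
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    st <- parts[1]; cd <- parts[2]
    for (j in seq_len(nk)) {
      idx <- idx + 1L
      cseed <- (design$seed * 1000L + idx * 13L) %% .Machine$integer.max
      par <- make_cell_params(st, cd, cseed, design$distributions)
      id <- sprintf("cell_%03d", idx)
      recs <- simulate_cell(par, cell_id = id, stage_group = st,
                            condition = cd,
                            spont_duration_s = design$spont_duration_s,
                            protocols = protocols)
      cells[[id]] <- list(params = par, recordings = recs,
                          cell_id = id, stage_group = st, condition = cd)
      truth[[id]] <- data.frame(cell_id = id, stage_group = st,
                                condition = cd,
                                as.data.frame(par[!(names(par) == "seed")]))
    }
  }
  list(cells = cells, truth = do.call(rbind, truth))
}

#' Extract the feature matrix for a whole cohort
#'
#' @param cohort Result of [make_cohort()].
#' @return A `feature_matrix`: numeric matrix (cells x 33) with
#'   `stage_group` / `condition` attributes (data.frame) describing rows.
#' @export
extract_cohort_features <- function(cohort) {
  rows <- lapply(cohort$cells, function(cc) extract_all(cc$recordings))
  m <- do.call(rbind, lapply(rows, as.numeric))
  colnames(m) <- FEATURE_NAMES
  rownames(m) <- names(cohort$cells)
  feature_matrix(m,
                 groups = data.frame(
                   cell_id = names(cohort$cells),
                   stage_group = vapply(cohort$cells, `[[`, "",
                                        "stage_group"),
                   condition = vapply(cohort$cells, `[[`, "", "condition")))
}

#' Construct a feature matrix with group labels
#'
#' @param values Numeric matrix, cells in rows, variables in columns.
#' @param groups data.frame with one row per cell (`cell_id`,
#'   `stage_group`, `condition`).
#' @return The matrix with class `feature_matrix` and a `groups`
#'   attribute.
#' @export
feature_matrix <- function(values, groups = NULL) {
  stopifnot(is.matrix(values))
  if (is.null(groups))
    groups <- data.frame(cell_id = rownames(values) %||%
                           sprintf("cell_%03d", seq_len(nrow(values))),
                         stage_group = NA_character_,
                         condition = NA_character_)
  attr(values, "groups") <- groups
  class(values) <- c("feature_matrix", class(values))
  values
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mask feature-matrix entries completely at random
#'
#' Sets entries to NA at the given rate, never removing the last observed
#' value of a row or column.
#'
#' @param matrix Numeric matrix (possibly already containing NAs).
#' @param rate Masking fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return The matrix with additional NAs.
#' @export
apply_missingness <- function(matrix, rate, seed = 1L) {
  if (rate >= 1) stop("missingness rate must be < 1")
  if (rate <= 0) return(matrix)
  local_rng(seed, {
    obs <- which(is.finite(matrix))
    n_mask <- stats::rbinom(1, length(obs), rate)
    cand <- sample(obs, length(obs))
    masked <- 0L
    for (ij in cand) {
      if (masked >= n_mask) break
      i <- (ij - 1) %% nrow(matrix) + 1; j <- (ij - 1) %/% nrow(matrix) + 1
      row_left <- sum(is.finite(matrix[i, ])) ; col_left <-
        sum(is.finite(matrix[, j]))
      if (row_left > 1 && col_left > 1) {
        matrix[i, j] <- NA
        masked <- masked + 1L
      }
    }
    matrix
  })
}

#' Simulate a feature matrix directly from a latent-factor model
#'
#' Generates `n x p` data as `Z L' + noise` with `k` latent factors and
#' optional per-group SD inflation — a fast stand-in for the full
#' simulate-and-extract pipeline when only the statistical stage is under
#' study (cloud geometry, PCA, imputation). Synthetic by construction;
#' it makes no claim about real recordings.
#'
#' @param n Cells. @param p Variables (default 33). @param k Latent
#'   factors. @param factor_sd SDs of the factor loadings' contribution.
#' @param noise_sd Residual SD. @param sd_scale Global SD inflation
#'   applied to the whole group (1 = none).
#' @param missing_rate MCAR masking rate.
#' @param seed Integer seed.
#' @return A numeric matrix with `FEATURE_NAMES` columns when `p == 33`.
#' @export
simulate_feature_matrix <- function(n, p = 33, k = 4, factor_sd = 1,
                                    noise_sd = 1, sd_scale = 1,
                                    missing_rate = 0, seed = 1L) {
  x <- local_rng(seed, {
    L <- matrix(stats::rnorm(p * k, 0, factor_sd), p, k)
    Z <- matrix(stats::rnorm(n * k), n, k)
    Z %*% t(L) + matrix(stats::rnorm(n * p, 0, noise_sd), n, p)
  })
  x <- x * sd_scale
  if (p == 33) colnames(x) <- FEATURE_NAMES
  rownames(x) <- sprintf("cell_%03d", seq_len(n))
  if (missing_rate > 0)
    x <- apply_missingness(x, missing_rate, seed + 1L)
  x
}
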