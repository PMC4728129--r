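# End-to-end orchestration: simulate -> extract -> analyze -> report,
# with reproducible configuration and plain-text artifacts.

#' Pipeline run configuration
#'
#' @param design A [cohort_design()].
#' @param out_dir Output directory for artifacts.
#' @param alpha FDR level for the correlation screen.
#' @param n_imputations,n_subsamples,subsample_size Resampling scheme for
#'   the cloud-geometry / heterogeneity analyses.
#' @param vp_q Victor-Purpura timing cost (per ms).
#' @param n_components PCA components.
#' @param seed Analysis-stage seed (simulation seeds live in the design).
#' @return A `run_config` list.
#' @export
run_config <- function(design = cohort_design(), out_dir = tempfile("run_"),
                       alpha = 0.05, n_imputations = 50, n_subsamples = 10,
                       subsample_size = 50, vp_q = 0.1, n_components = 2,
                       seed = 1L) {
  structure(list(design = design, out_dir = out_dir, alpha = alpha,
                 n_imputations = n_imputations,
                 n_subsamples = n_subsamples,
                 subsample_size = subsample_size, vp_q = vp_q,
                 n_components = n_components, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full census pipeline
#'
#' Streams through the cohort cell by cell (simulate all protocols,
#' extract the 33 variables, keep the concatenated step spike train,
#' discard the traces), applies the designed missingness, then runs the
#' analysis battery: pairwise correlations with FDR, the
#' principal-variables ranking, PCA with missing values + promax +
#' scores (with stimulated cells projected into the naive-fit space when
#' both conditions are present), per-variable group statistics,
#' imputation-based cloud-size and heterogeneity comparisons, and the
#' spike-train distance matrix with its 2D embedding. Artifacts are
#' written as CSV/JSON under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @param protocols Protocols to simulate per cell.
#' @return (Invisibly) a list of all in-memory artifacts; see the
#'   `manifest.json` in the output directory for the file map.
#' @export
run_pipeline <- function(config,
                         protocols = c("iv_steps", "current_steps",
                                       "cosine", "synaptic",
                                       "spontaneous")) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate/extract"
  res <- tryCatch({
    feats <- list(); labels <- list(); step_trains <- list(); idx <- 0L
    for (key in names(design$n_cells)) {
      nk <- design$n_cells[[key]]
      if (nk < 1) next
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      for (j in seq_len(nk)) {
        idx <- idx + 1L
        cseed <- (design$seed * 1000L + idx * 13L) %% .Machine$integer.max
        par <- make_cell_params(parts[1], parts[2], cseed,
                                design$distributions)
        id <- sprintf("cell_%03d", idx)
        recs <- simulate_cell(par, cell_id = id, stage_group = parts[1],
                              condition = parts[2],
                              spont_duration_s = design$spont_duration_s,
                              protocols = protocols)
        feats[[id]] <- extract_all(recs)
        labels[[id]] <- data.frame(cell_id = id, stage_group = parts[1],
                                   condition = parts[2])
        if (!is.null(recs$current_steps))
          step_trains[[id]] <- concat_step_trains(recs$current_steps)
        rm(recs)
      }
    }
    fm <- do.call(rbind, lapply(feats, as.numeric))
    colnames(fm) <- FEATURE_NAMES; rownames(fm) <- names(feats)
    groups <- do.call(rbind, labels)
    if (design$missing_rate > 0)
      fm <- apply_missingness(fm, design$missing_rate,
                              seed = design$seed + 99L)

    stage <- "analyze"
    corr <- pairwise_correlations(fm)
    fdr <- fdr_adjust(corr$p, config$alpha)
    corr$significant <- fdr$significant
    cm <- suppressWarnings(stats::cor(fm, use = "pairwise.complete.obs"))
    pv <- sort(explained_variance_single(cm), decreasing = TRUE)

    # variables observed in too few cells cannot enter the factor or
    # cloud-geometry analyses (the feature table itself keeps them)
    keep_cols <- colSums(is.finite(fm)) >= 3
    fma <- fm[, keep_cols, drop = FALSE]

    naive_rows <- which(groups$condition != "stimulated")
    fit_rows <- if (length(naive_rows) >= 10) naive_rows
                else seq_len(nrow(fm))
    model <- vbpca_fit(fma[fit_rows, , drop = FALSE],
                       n_components = config$n_components)
    if (config$n_components >= 2) model <- promax_rotate(model)
    scores <- vbpca_project(model, fma)
    rownames(scores) <- rownames(fm)

    gstats <- NULL
    if (length(unique(groups$stage_group)) >= 2 ||
        length(unique(groups$condition)) >= 2) {
      gr <- if (length(unique(groups$stage_group)) >= 2)
        groups$stage_group else groups$condition
      gstats <- group_compare(fm, gr)
    }
    cloud <- NULL
    gkey <- paste(groups$stage_group, groups$condition, sep = ".")
    if (length(unique(gkey)) >= 2) {
      two <- names(sort(table(gkey), decreasing = TRUE))[1:2]
      sel <- gkey %in% two
      cloud <- cloud_size_compare(fma[sel, , drop = FALSE], gkey[sel],
                                  n_imputations = config$n_imputations,
                                  n_subsamples = config$n_subsamples,
                                  subsample_size = config$subsample_size,
                                  seed = config$seed)
    }
    vp <- mds <- NULL
    nonempty <- vapply(step_trains, length, integer(1)) > 0
    if (sum(nonempty) >= 3) {
      vp <- distance_matrix(step_trains[nonempty], q = config$vp_q)
      mds <- classical_mds(vp, dims = 2)
    }

    stage <- "write"
    art <- list(features = fm, groups = groups, correlations = corr,
                fdr = fdr, principal_variables = pv, pca = model,
                scores = scores, group_stats = gstats, cloud = cloud,
                vp_distances = vp, mds = mds, config = config)
    write_artifacts(art, config$out_dir)
    art
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

write_artifacts <- function(art, out_dir) {
  fm <- art$features
  utils::write.csv(data.frame(cell_id = rownames(fm), fm,
                              check.names = FALSE),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(variables = FEATURE_NAMES,
         units = c("pF", "GOhm", "MOhm", "pA", "mV", "pA", "mV", "pA",
                   "mV", "pA", "ms", "mV", "mV", "ms", "ms", "pA",
                   "count", "ms", "ratio", "ratio", "count", "ms", "ms",
                   "wave", "waves", "log-index", "ms", "ms", "pA.s",
                   "ratio", "ratio", "Hz", "pA"),
         missing_sentinel = "NA"),
    file.path(out_dir, "features_schema.json"), auto_unbox = TRUE)
  utils::write.csv(art$groups, file.path(out_dir, "groups.csv"),
                   row.names = FALSE)
  utils::write.csv(art$correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(variable = names(art$principal_variables),
               explained_share = as.numeric(art$principal_variables)),
    file.path(out_dir, "principal_variables.csv"), row.names = FALSE)
  utils::write.csv(data.frame(variable = art$pca$var_names %||%
                                seq_len(nrow(art$pca$loadings)),
                              art$pca$loadings),
                   file.path(out_dir, "pca_loadings.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(cell_id = rownames(art$scores), art$scores),
                   file.path(out_dir, "pca_scores.csv"), row.names = FALSE)
  if (!is.null(art$group_stats))
    utils::write.csv(art$group_stats, file.path(out_dir, "group_stats.csv"),
                     row.names = FALSE)
  if (!is.null(art$vp_distances)) {
    utils::write.csv(as.data.frame(unclass(art$vp_distances)),
                     file.path(out_dir, "vp_distances.csv"),
                     row.names = TRUE)
    utils::write.csv(data.frame(cell_id = rownames(art$mds), art$mds),
                     file.path(out_dir, "mds_coords.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ephyscensus")),
    seed = art$config$seed, design_seed = art$config$design$seed,
    n_cells = nrow(fm), n_variables = ncol(fm),
    missing_fraction = mean(!is.finite(fm)),
    n_correlation_pairs = nrow(art$correlations),
    n_significant = art$fdr$n_significant,
    pca_shares = art$pca$shares,
    cloud = if (!is.null(art$cloud))
      art$cloud[c("group_means", "ratio", "p_value")] else NULL,
    files = list.files(art$config$out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Summarize a completed pipeline run
#'
#' Prints a human-readable summary: dataset shape and missingness, the
#' strongest FDR-significant correlations, the top principal variables,
#' PCA explained-variance shares, per-group component means, significant
#' group differences with eta-squared, and the cloud-size comparison.
#'
#' @param run Artifact list returned by [run_pipeline()].
#' @param n_top How many correlations/variables to print.
#' @return (Invisibly) a list with the printed tables.
#' @export
report_run <- function(run, n_top = 10) {
  if (is.null(run) || is.null(run$features))
    stop("empty run artifacts: nothing to report")
  fm <- run$features
  cat("Census run:", nrow(fm), "cells x", ncol(fm), "variables;",
      sprintf("%.1f%% missing\n", 100 * mean(!is.finite(fm))))
  sig <- run$correlations[run$correlations$significant %in% TRUE, ]
  sig <- sig[order(-abs(sig$r)), ]
  cat("\nFDR-significant correlations:", nrow(sig),
      "of", nrow(run$correlations), "pairs")
  if (nrow(sig)) {
    cat(" (implied p threshold ", signif(run$fdr$threshold, 2), ")\n",
        sep = "")
    top <- utils::head(sig, n_top)
    for (i in seq_len(nrow(top)))
      cat(sprintf("  %-24s ~ %-24s r = %+.2f (n = %d)\n", top$var1[i],
                  top$var2[i], top$r[i], top$n[i]))
  } else cat("\n")
  cat("\nTop principal variables (share of total variance):\n")
  pv <- utils::head(run$principal_variables, n_top)
  for (i in seq_along(pv))
    cat(sprintf("  %-28s %.1f%%\n", names(pv)[i], 100 * pv[i]))
  cat("\nPCA: components explain",
      paste(sprintf("%.1f%%", 100 * run$pca$shares), collapse = " and "),
      "of observed variance\n")
  gr <- paste(run$groups$stage_group, run$groups$condition, sep = ".")
  cm <- stats::aggregate(run$scores, list(group = gr), mean,
                         na.rm = TRUE)
  cat("\nPer-group mean component scores:\n")
  print(cm, digits = 2)
  out <- list(significant = sig, principal_variables = pv,
              group_scores = cm)
  if (!is.null(run$group_stats)) {
    gs <- run$group_stats
    hits <- gs[is.finite(gs$p_anova) & gs$p_anova < 0.05, ]
    cat("\nVariables differing across groups (ANOVA p < 0.05):",
        nrow(hits), "\n")
    if (nrow(hits))
      for (i in seq_len(nrow(hits)))
        cat(sprintf("  %-28s p = %-8.2g eta2 = %.2f\n", hits$variable[i],
                    hits$p_anova[i], hits$eta2[i]))
    out$group_hits <- hits
  }
  if (!is.null(run$cloud))
    cat(sprintf("\nCloud size (median city-block): %s; ratio %.2f, p = %.2g\n",
                paste(sprintf("%s %.1f", names(run$cloud$group_means),
                              run$cloud$group_means), collapse = " vs "),
                run$cloud$ratio, run$cloud$p_value))
  invisible(out)
}
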