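# Spike-train similarity across cells: Victor-Purpura cost-based metric,
# classical multidimensional scaling, and nearest-neighbor group pulls.

#' Concatenate step-protocol spike trains into one long train
#'
#' Responses to step injections of all amplitudes are combined, in
#' ascending current order, into a single recording by offsetting each
#' sweep's spike times by its position times the sweep duration.
#'
#' @param rec A `current_steps` recording, or NULL when `trains` and
#'   `currents` are given directly.
#' @param trains Optional list of spike-time vectors (one per sweep).
#' @param currents Injected current per sweep (pA), used for ordering.
#' @param sweep_ms Sweep duration (ms); taken from the recording when
#'   available.
#' @return Numeric vector of spike times (ms) in the concatenated
#'   recording.
#' @export
concat_step_trains <- function(rec = NULL, trains = NULL, currents = NULL,
                               sweep_ms = NULL) {
  if (!is.null(rec)) {
    stopifnot(rec$protocol == "current_steps")
    if (is.null(trains))
      trains <- lapply(apply(rec$sweeps, 2, detect_spikes, fs = rec$fs,
                             simplify = FALSE), `[[`, "times")
    currents <- currents %||% rec$stimulus$current_pA
    sweep_ms <- sweep_ms %||% (nrow(rec$sweeps) * 1000 / rec$fs)
  }
  trains <- lapply(trains, function(tr)
    if (inherits(tr, "spike_train")) tr$times else tr)
  ord <- order(currents)
  out <- unlist(lapply(seq_along(ord), function(k)
    trains[[ord[k]]] + (k - 1) * sweep_ms))
  as.numeric(out %||% numeric(0))
}

#' Victor-Purpura spike-train distance
#'
#' Dynamic-programming edit distance between two spike trains: inserting
#' or deleting a spike costs 1, shifting a spike by `dt` ms costs
#' `q * |dt|`, and any shift is capped at 2 (a delete plus an insert).
#' With `q = 0` the distance reduces to the difference in spike counts;
#' large `q` approaches counting non-coincident spikes.
#'
#' @param a,b Spike-time vectors (ms).
#' @param q Cost per ms of spike-timing adjustment (default 0.1/ms).
#' @return Nonnegative scalar distance.
#' @export
vp_distance <- function(a, b, q = 0.1) {
  stopifnot(q >= 0)
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(na + nb)
  a <- sort(a); b <- sort(b)
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- numeric(nb + 1)
    cur[1] <- i
    shift <- pmin(q * abs(a[i] - b), 2)
    for (j in seq_len(nb)) {
      cur[j + 1] <- min(cur[j] + 1, prev[j + 1] + 1, prev[j] + shift[j])
    }
    prev <- cur
  }
  prev[nb + 1]
}

#' Pairwise spike-train distance matrix for a set of cells
#'
#' @param trains Named list of spike-time vectors (one concatenated train
#'   per cell).
#' @param q Timing-adjustment cost per ms.
#' @return A symmetric `dist_matrix` (zero diagonal) with a `metric`
#'   attribute `"vp_q<q>"`.
#' @export
distance_matrix <- function(trains, q = 0.1) {
  n <- length(trains)
  stopifnot(n >= 2)
  ids <- names(trains) %||% as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- vp_distance(trains[[i]], trains[[j]], q)
  }
  attr(d, "metric") <- paste0("vp_q", q)
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centered eigendecomposition of the squared-distance matrix,
#' returning the top coordinates with a deterministic sign convention:
#' each axis is flipped so its largest-magnitude coordinate is positive.
#'
#' @param d Symmetric distance matrix.
#' @param dims Number of output dimensions (default 2).
#' @return Matrix of coordinates (n x dims); all zeros for an all-zero
#'   distance matrix.
#' @export
classical_mds <- function(d, dims = 2) {
  d <- unclass(d); attr(d, "metric") <- NULL
  n <- nrow(d)
  if (all(d == 0)) {
    out <- matrix(0, n, dims, dimnames = list(rownames(d), NULL))
    return(out)
  }
  xy <- stats::cmdscale(stats::as.dist(d), k = dims)
  if (ncol(xy) < dims)
    xy <- cbind(xy, matrix(0, n, dims - ncol(xy)))
  for (j in seq_len(ncol(xy))) {
    s <- sign(xy[which.max(abs(xy[, j])), j])
    if (s < 0) xy[, j] <- -xy[, j]
  }
  rownames(xy) <- rownames(d)
  xy
}

#' Pull a reference cell's nearest neighbors in an embedding
#'
#' @param coords Coordinate matrix (cells x dims) with row names.
#' @param reference_id Row name (or index) of the reference cell.
#' @param k Number of neighbors to pull (group size is `k + 1`).
#' @return Character vector of ids: the reference followed by its `k`
#'   nearest by Euclidean distance, ties broken by id order.
#' @export
nearest_neighbor_group <- function(coords, reference_id, k = 5) {
  ids <- rownames(coords) %||% as.character(seq_len(nrow(coords)))
  if (k >= nrow(coords)) stop("k must be smaller than the number of cells")
  ref <- if (is.character(reference_id)) match(reference_id, ids)
         else as.integer(reference_id)
  if (is.na(ref)) stop("unknown reference cell")
  dd <- sqrt(colSums((t(coords) - coords[ref, ])^2))
  ord <- order(dd, ids)
  ord <- ord[ord != ref]
  c(ids[ref], ids[utils::head(ord, k)])
}
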