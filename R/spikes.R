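# Spike detection and per-spike shape measurement on current-clamp sweeps.

#' Detect spikes in a current-clamp sweep
#'
#' Subtracts a running-median baseline, thresholds the residual at the
#' larger of an absolute amplitude floor and a MAD-scaled level, keeps
#' local maxima separated by a refractory gap, and rejects shapes that are
#' too small or too broad (or too narrow) based on the measured width at
#' half-height. All thresholds are configuration.
#'
#' @param sweep Numeric vector, membrane potential (mV).
#' @param fs Sampling rate (Hz).
#' @param min_amp_mV Minimum spike amplitude above baseline (default 10).
#' @param mad_k MAD multiplier for the adaptive threshold component.
#' @param width_bounds_ms Acceptable width-at-half-height range.
#' @param refractory_ms Minimum separation between detected peaks.
#' @param baseline_ms Running-median window for baseline estimation.
#' @return A `spike_train`: list with `times` (ms, strictly increasing),
#'   and per-spike `kink`, `peak`, `amplitude` (mV), `rise` and `width`
#'   (ms).
#' @export
detect_spikes <- function(sweep, fs = FS_HZ, min_amp_mV = 10, mad_k = 6,
                          width_bounds_ms = c(0.2, 10),
                          refractory_ms = 1.5, baseline_ms = 25) {
  if (any(!is.finite(sweep))) stop("non-finite samples in sweep")
  dt <- 1000 / fs
  k <- round(baseline_ms / dt); if (k %% 2 == 0) k <- k + 1
  base <- stats::runmed(sweep, k, endrule = "median")
  z <- sweep - base
  # threshold on a lightly smoothed residual (noise shrinks by sqrt(5),
  # a >= 0.5 ms spike barely attenuates), then refine peaks on the raw
  # residual
  zs <- smooth_ma(z, 5L)
  thr <- max(min_amp_mV, mad_k * stats::mad(zs))
  n <- length(z)
  cand <- which(zs > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[zs[cand] >= zs[cand - 1] & zs[cand] >= zs[cand + 1]]
  # collapse runs closer than the refractory gap, keeping the tallest
  keep <- integer(0)
  if (length(cand)) {
    ord <- cand[order(-zs[cand])]
    taken <- rep(FALSE, n)
    gap <- round(refractory_ms / dt)
    for (i in ord) {
      lo <- max(1, i - gap); hi <- min(n, i + gap)
      if (!any(taken[lo:hi])) { keep <- c(keep, i); taken[i] <- TRUE }
    }
    keep <- sort(keep)
    # snap each detection to the raw-residual peak nearby
    keep <- vapply(keep, function(i) {
      lo <- max(1L, as.integer(i) - 3L); hi <- min(n, as.integer(i) + 3L)
      lo + which.max(z[lo:hi]) - 1L
    }, integer(1))
    keep <- unique(keep)
  }
  shapes <- lapply(keep, function(i) spike_shape(sweep, (i - 1) * dt, fs))
  ok <- vapply(shapes, function(s) {
    !is.na(s["amplitude"]) && s["amplitude"] >= min_amp_mV &&
      !is.na(s["width"]) && s["width"] >= width_bounds_ms[1] &&
      s["width"] <= width_bounds_ms[2]
  }, logical(1))
  keep <- keep[ok]; shapes <- shapes[ok]
  train <- list(times = (keep - 1) * dt,
                kink = vapply(shapes, `[[`, numeric(1), "kink"),
                peak = sweep[keep],
                amplitude = vapply(shapes, `[[`, numeric(1), "amplitude"),
                rise = vapply(shapes, `[[`, numeric(1), "rise"),
                width = vapply(shapes, `[[`, numeric(1), "width"))
  class(train) <- "spike_train"
  train
}

#' Measure the shape of one spike
#'
#' The kink (spike-initiation) point is located at the maximum of the
#' second time-derivative of the potential in a pre-peak window; amplitude
#' is peak minus kink potential; rise time spans 10\% to 90\% of the
#' kink-to-peak excursion; width is measured at the potential midway
#' between kink and peak. Crossings are linearly interpolated between
#' samples.
#'
#' @param sweep Potential trace (mV).
#' @param spike_time Peak time (ms from sweep start).
#' @param fs Sampling rate (Hz).
#' @param pre_window_ms How far before the peak to search for the kink.
#' @return Named numeric: `kink`, `amplitude` (mV), `rise`, `width` (ms);
#'   all `NA` when the peak is too close to a sweep edge.
#' @export
spike_shape <- function(sweep, spike_time, fs = FS_HZ, pre_window_ms = 8) {
  dt <- 1000 / fs
  p <- round(spike_time / dt) + 1L
  n <- length(sweep)
  na <- c(kink = NA_real_, amplitude = NA_real_, rise = NA_real_,
          width = NA_real_)
  if (p <= 3 || p >= n - 2) return(na)
  lo <- max(2L, p - round(pre_window_ms / dt))
  if (p - lo < 3) return(na)
  seg <- lo:p
  d2 <- sweep[seg + 1L] - 2 * sweep[seg] + sweep[seg - 1L]
  # smooth only as much as the noise demands: heavy smoothing drags the
  # curvature maximum up the rising phase on clean traces
  noisy <- stats::mad(diff(sweep[max(1, lo - 50):lo])) > 0.3
  if (noisy && length(d2) > 7) d2 <- smooth_ma(smooth_ma(d2, 5L), 3L)
  kidx <- seg[which.max(d2)]
  kink <- sweep[kidx]
  peak <- sweep[p]
  amp <- peak - kink
  if (!is.finite(amp) || amp <= 0) return(na)
  lvl10 <- kink + 0.1 * amp; lvl90 <- kink + 0.9 * amp
  half <- kink + 0.5 * amp
  t10 <- cross_before(sweep, p, lvl10, kidx, dt)
  t90 <- cross_before(sweep, p, lvl90, kidx, dt)
  up <- cross_before(sweep, p, half, kidx, dt)
  dn <- cross_after(sweep, p, half, dt)
  c(kink = kink, amplitude = amp,
    rise = if (is.na(t10) || is.na(t90)) NA_real_ else t90 - t10,
    width = if (is.na(up) || is.na(dn)) NA_real_ else dn - up)
}

smooth_ma <- function(x, k) {
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) -> y
  y[is.na(y)] <- x[is.na(y)]
  y
}

# last upward crossing of `level` before sample p (>= from), in ms
cross_before <- function(v, p, level, from, dt) {
  i <- p
  while (i > from && v[i - 1L] > level) i <- i - 1L
  if (i == from && v[i] > level) return(NA_real_)
  if (v[i] <= level) return((i - 1) * dt)
  frac <- (level - v[i - 1L]) / (v[i] - v[i - 1L])
  (i - 2 + frac) * dt
}

# first downward crossing of `level` after sample p, in ms
cross_after <- function(v, p, level, dt) {
  n <- length(v); i <- p
  while (i < n && v[i + 1L] > level) i <- i + 1L
  if (i == n) return(NA_real_)
  frac <- (v[i] - level) / (v[i] - v[i + 1L])
  (i - 1 + frac) * dt
}
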