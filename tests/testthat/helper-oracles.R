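# Independent oracles used across the suite. These deliberately avoid the
# package's own implementations.

# Victor-Purpura cost by plain recursion (exponential; fine for <= 8
# spikes). Insert/delete cost 1, shift cost min(q|dt|, 2).
vp_oracle <- function(a, b, q) {
  a <- sort(a); b <- sort(b)
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    min(rec(i - 1, j) + 1,
        rec(i, j - 1) + 1,
        rec(i - 1, j - 1) + min(q * abs(a[i] - b[j]), 2))
  }
  rec(length(a), length(b))
}

# Benjamini-Hochberg step-up, spelled out directly from the definition.
bh_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * alpha / m) k <- i
  sig <- rep(FALSE, m)
  if (k > 0) sig[ord[seq_len(k)]] <- TRUE
  sig
}

# AGNES coefficient from first principles: average-linkage merge heights
# via hclust, each point's first-merge height against the final height.
agnes_oracle <- function(points) {
  d <- dist(points)
  hc <- stats::hclust(d, method = "average")
  n <- nrow(points)
  first <- rep(NA_real_, n)
  members <- list()
  for (s in seq_len(nrow(hc$merge))) {
    mem <- c()
    for (side in hc$merge[s, ])
      mem <- c(mem, if (side < 0) -side else members[[side]])
    members[[s]] <- mem
    for (p in mem) if (is.na(first[p])) first[p] <- hc$height[s]
  }
  mean(1 - first / max(hc$height))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a minimal current-clamp recording wrapper for hand-built sweeps
fake_recording <- function(sweeps, protocol, stimulus, params = NULL) {
  ephyscensus:::new_recording(protocol, sweeps, stimulus, params)
}

# raised-cosine spike waveform identical in shape maths to the generator,
# used to place spikes at exact known positions in hand-built sweeps;
# the waveform rises from the local baseline (floor_level)
inject_spike <- function(trace, at_ms, amp, rise_1090 = 0.4, width = 1.5,
                         floor_level = -65, fs = 10000) {
  w <- ephyscensus:::spike_waveform(amp, rise_1090, width)
  i0 <- round(at_ms * fs / 1000) + 1L
  idx <- i0 + seq_along(w) - 1L
  keep <- idx <= length(trace)
  trace[idx[keep]] <- pmax(trace[idx[keep]], floor_level + w[keep])
  trace
}
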