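# Extraction of the 33 canonical electrophysiological variables.

#' Canonical names of the 33 cell variables
#'
#' Order matches the conventional numbering: 1--4 passive (seal test),
#' 5--10 IV-curve, 11--20 step injections, 21--26 cosine injections,
#' 27--31 synaptic stimulation, 32--33 spontaneous events.
#' @export
FEATURE_NAMES <- c(
  "Cm", "Rm", "Ra", "I hold",
  "I Na activation", "I Na", "I KS activation", "I KS",
  "I KT activation", "I KT",
  "Tail", "Spike threshold", "Spike amplitude", "Spike rise-time",
  "Spike width", "I best", "N spikes step", "Spike ISI",
  "Spike ISI accommodation", "Spike accommodation",
  "N spikes cosine", "Spiking resonance", "Spiking resonance width",
  "Wave buildup", "Wave decay", "Jitter",
  "Synaptic resonance", "Synaptic resonance width", "Synaptic charge",
  "Synaptic PPF", "Monosynapticity",
  "Minis frequency", "Minis amplitude")

#' Measure ionic currents from a passive-subtracted IV recording
#'
#' For every voltage step: the peak (most negative) current in the early
#' window is the transient sodium current; the early-window maximum is the
#' peak potassium current; the mean over the late window is the
#' steady-state (stable) potassium current; and the transient potassium
#' current is peak potassium minus steady state. Window defaults follow
#' the convention of reading the printed window bounds as samples at
#' 10 kHz (0--18.5 ms and 116.5--136.5 ms), both inside the 150 ms step.
#'
#' @param rec An `iv_steps` recording.
#' @param early_ms,steady_ms Measurement windows (ms after step onset).
#' @return data.frame with `command_mV`, `i_na`, `i_k_peak`, `i_ks`,
#'   `i_kt` (pA).
#' @export
measure_iv_currents <- function(rec, early_ms = c(0, 18.5),
                                steady_ms = c(116.5, 136.5)) {
  stopifnot(rec$protocol == "iv_steps")
  dt <- 1000 / rec$fs
  n <- nrow(rec$sweeps)
  if (n * dt < steady_ms[2]) stop("sweep shorter than the steady window")
  w1 <- which((seq_len(n) - 1) * dt >= early_ms[1] &
                (seq_len(n) - 1) * dt <= early_ms[2])
  w2 <- which((seq_len(n) - 1) * dt >= steady_ms[1] &
                (seq_len(n) - 1) * dt <= steady_ms[2])
  res <- t(apply(rec$sweeps, 2, function(tr) {
    i_na <- min(tr[w1]); i_pk <- max(tr[w1]); i_ks <- mean(tr[w2])
    c(i_na = i_na, i_k_peak = i_pk, i_ks = i_ks, i_kt = i_pk - i_ks)
  }))
  cbind(rec$stimulus["command_mV"], as.data.frame(res))
}

#' Spike-train features from the step injection protocol
#'
#' Computes the repolarization tail constant (median over sweeps of an
#' exponential fit to the post-injection decay), first-spike shape
#' variables from the lowest spiking current, and inter-spike-interval /
#' amplitude accommodation from the sweep with the most spikes closest to
#' the inferred optimal current.
#'
#' @param rec A `current_steps` recording.
#' @param trains Optional list of `spike_train`s (one per sweep); detected
#'   automatically when omitted.
#' @param i_best Optimal current (pA) used to break ties between sweeps
#'   with equal spike counts; may be NA.
#' @return Named numeric with elements `tail`, `threshold`, `amplitude`,
#'   `rise`, `width`, `isi`, `isi_accom`, `amp_accom`.
#' @export
step_train_features <- function(rec, trains = NULL, i_best = NA) {
  stopifnot(rec$protocol == "current_steps")
  if (is.null(trains))
    trains <- apply(rec$sweeps, 2, detect_spikes, fs = rec$fs,
                    simplify = FALSE)
  out <- c(tail = NA_real_, threshold = NA_real_, amplitude = NA_real_,
           rise = NA_real_, width = NA_real_, isi = NA_real_,
           isi_accom = NA_real_, amp_accom = NA_real_)
  out["tail"] <- repolarization_tail(rec)
  counts <- vapply(trains, function(tr) length(tr$times), integer(1))
  cur <- rec$stimulus$current_pA
  sp <- which(counts > 0 & cur > 0)
  if (length(sp)) {
    first <- trains[[min(sp)]]
    out["threshold"] <- first$kink[1]
    out["amplitude"] <- first$amplitude[1]
    out["rise"] <- first$rise[1]
    out["width"] <- first$width[1]
    best_sweeps <- which(counts == max(counts))
    b <- if (is.finite(i_best))
      best_sweeps[which.min(abs(cur[best_sweeps] - i_best))]
    else best_sweeps[1]
    tb <- trains[[b]]
    if (length(tb$times) >= 2) {
      isis <- diff(tb$times)
      out["isi"] <- isis[1]
      out["amp_accom"] <- tb$amplitude[2] / tb$amplitude[1]
      if (length(isis) >= 2) out["isi_accom"] <- isis[2] / isis[1]
    }
  }
  out
}

# median exponential time constant of the post-injection repolarization;
# the decay segment is smoothed before the log-linear fit so sample noise
# does not bias the slope
repolarization_tail <- function(rec, fit_ms = 180) {
  dt <- 1000 / rec$fs
  off <- rec$stimulus$offset_ms[1]
  i0 <- round(off / dt) + 2L
  i1 <- min(nrow(rec$sweeps), i0 + round(fit_ms / dt))
  taus <- apply(rec$sweeps, 2, function(v) {
    seg <- smooth_ma(v[i0:i1], 21L)
    v_inf <- stats::median(seg[max(1, length(seg) - 300):length(seg)])
    y <- seg - v_inf
    if (max(abs(y[1:10])) < 2) return(NA_real_)  # no appreciable decay
    s <- sign(y[1]); y <- y * s
    use <- which(y > max(y) * 0.1)
    if (length(use) < 20) return(NA_real_)
    tt <- (use - 1) * dt
    fit <- stats::lm(log(y[use]) ~ tt)
    tau <- -1 / stats::coef(fit)[2]
    if (!is.finite(tau) || tau <= 0) NA_real_ else tau
  })
  if (all(is.na(taus))) NA_real_ else stats::median(taus, na.rm = TRUE)
}

#' Spike-timing jitter index across repeated sweeps
#'
#' Each train is represented as a delta train on the sampling grid,
#' convolved with a Gaussian (sigma = 2 ms by default) and normalized to
#' unit L2 norm; the index is `ln(1 - mean pairwise scalar product)`.
#' Identical trains give products of 1; the mean is clamped to
#' `1 - 1e-12` before the log. Empty sweeps are excluded; fewer than two
#' non-empty trains give NA.
#'
#' @param trains List of spike-time vectors (ms).
#' @param sigma_ms Gaussian smoothing SD (ms).
#' @param fs Sampling rate defining the grid (Hz).
#' @return Scalar jitter index (<= 0), or NA.
#' @export
jitter_index <- function(trains, sigma_ms = 2, fs = FS_HZ) {
  times <- lapply(trains, function(tr)
    if (inherits(tr, "spike_train")) tr$times else tr)
  times <- times[vapply(times, length, integer(1)) > 0]
  if (length(times) < 2) return(NA_real_)
  dt <- 1000 / fs
  tmax <- max(unlist(times)) + 6 * sigma_ms
  grid <- seq(0, tmax, by = dt)
  smooth <- vapply(times, function(tt) {
    a <- rowSums(vapply(tt, function(s) stats::dnorm(grid, s, sigma_ms),
                        numeric(length(grid))))
    a / sqrt(sum(a^2))
  }, numeric(length(grid)))
  m <- length(times)
  prods <- crossprod(smooth)
  mean_prod <- mean(prods[upper.tri(prods)])
  log(1 - min(mean_prod, 1 - 1e-12))
}

#' Total synaptic charge per inter-stimulus interval
#'
#' Blanks stimulation artifacts, averages the repeats of each ISI
#' condition, subtracts the pre-stimulus baseline, and integrates the
#' current from the first shock to a configurable time after the last
#' shock.
#'
#' @param rec A `synaptic` recording.
#' @param blank_ms Post-shock blanking window (artifact removal).
#' @param tail_ms Integration time after the last shock.
#' @return data.frame with `isi_ms` and `q_pAs` (pA s).
#' @export
synaptic_charge_curve <- function(rec, blank_ms = 2, tail_ms = 300) {
  stopifnot(rec$protocol == "synaptic")
  dt <- 1000 / rec$fs
  isis <- sort(unique(rec$stimulus$isi_ms))
  t0 <- rec$stimulus$first_stim_ms[1]
  q <- vapply(isis, function(ii) {
    idx <- which(rec$stimulus$isi_ms == ii)
    avg <- rowMeans(rec$sweeps[, idx, drop = FALSE])
    stim_t <- t0 + (0:4) * ii
    for (s in stim_t) {
      b <- round(s / dt) + 1L
      avg[b:min(length(avg), b + round(blank_ms / dt))] <- NA
    }
    # bridge the blanked artifact windows by linear interpolation so the
    # integral does not lose response charge under them
    if (anyNA(avg))
      avg <- stats::approx(which(!is.na(avg)), avg[!is.na(avg)],
                           xout = seq_along(avg), rule = 2)$y
    base <- stats::median(avg[seq_len(round((t0 - 10) / dt))])
    i1 <- round(t0 / dt) + 1L
    i2 <- min(length(avg), round((stim_t[5] + tail_ms) / dt))
    seg <- avg[i1:i2] - base
    sum(seg) * dt / 1000
  }, numeric(1))
  data.frame(isi_ms = isis, q_pAs = q)
}

#' Monosynapticity ratio
#'
#' Ratio of the mean evoked current in the early (monosynaptic, 5--14 ms
#' post-shock) window to the mean current in the late (polysynaptic,
#' 15--145 ms) window, averaged over the shocks of the long-ISI
#' conditions (>= 100 ms). The late window is clipped at the next shock
#' when the ISI is shorter than its nominal end. Larger values indicate a
#' more purely monosynaptic input.
#'
#' @param rec A `synaptic` recording.
#' @param mono_ms,poly_ms Window bounds (ms after each shock).
#' @param min_isi_ms Only ISI conditions at least this long are used.
#' @return Scalar ratio, or NA when the polysynaptic mean is ~ 0.
#' @export
monosynapticity <- function(rec, mono_ms = c(5, 14), poly_ms = c(15, 145),
                            min_isi_ms = 100) {
  stopifnot(rec$protocol == "synaptic")
  dt <- 1000 / rec$fs
  isis <- sort(unique(rec$stimulus$isi_ms))
  isis <- isis[isis >= min_isi_ms]
  if (!length(isis)) stop("no long-ISI sweeps present")
  t0 <- rec$stimulus$first_stim_ms[1]
  monos <- polys <- numeric(0)
  for (ii in isis) {
    idx <- which(rec$stimulus$isi_ms == ii)
    avg <- rowMeans(rec$sweeps[, idx, drop = FALSE])
    base <- stats::median(avg[seq_len(round((t0 - 10) / dt))])
    for (k in 0:4) {
      s <- t0 + k * ii
      poly_end <- min(poly_ms[2], if (k < 4) ii - 1 else poly_ms[2])
      if (poly_end <= poly_ms[1]) next
      wm <- round((s + mono_ms) / dt) + 1L
      wp <- round((s + c(poly_ms[1], poly_end)) / dt) + 1L
      monos <- c(monos, mean(avg[wm[1]:wm[2]]) - base)
      polys <- c(polys, mean(avg[wp[1]:wp[2]]) - base)
    }
  }
  pm <- mean(polys)
  if (!is.finite(pm) || abs(pm) < 1e-6) return(NA_real_)
  mean(monos) / pm
}

#' Detect spontaneous EPSCs (minis) and summarize them
#'
#' Matched-filter detection: the trace is convolved with an alpha-shaped
#' template, candidate events are local maxima of the filtered trace above
#' a MAD-scaled threshold with a minimum separation, and amplitudes are
#' read from the raw trace relative to a local pre-event baseline.
#'
#' @param trace Voltage-clamp current trace (pA), positive-going events.
#' @param fs Sampling rate (Hz).
#' @param duration_s Recording duration (defaults to trace length).
#' @param tau_ms Template time constant.
#' @param thr_mad Threshold in robust SDs of the filtered trace.
#' @param min_sep_ms Minimum separation between events.
#' @return List with `frequency_hz`, `amplitude_pa` (NA when no events),
#'   `n_events`, `event_times_ms`.
#' @export
detect_minis <- function(trace, fs = FS_HZ, duration_s = length(trace) / fs,
                         tau_ms = 2, thr_mad = 5, min_sep_ms = 10) {
  dt <- 1000 / fs
  kern_t <- seq(0, 10 * tau_ms, by = dt)
  kern <- (kern_t / tau_ms) * exp(1 - kern_t / tau_ms)
  kern <- kern / sum(kern)
  f <- as.numeric(stats::filter(trace, rev(kern), sides = 1))
  f[is.na(f)] <- 0
  sig <- stats::mad(f, na.rm = TRUE)
  thr <- max(thr_mad * sig, 1e-9)
  n <- length(f)
  cand <- which(f > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[f[cand] >= f[cand - 1] & f[cand] >= f[cand + 1]]
  keep <- integer(0)
  if (length(cand)) {
    ord <- cand[order(-f[cand])]
    taken <- rep(FALSE, n)
    gap <- round(min_sep_ms / dt)
    for (i in ord) {
      lo <- max(1, i - gap); hi <- min(n, i + gap)
      if (!any(taken[lo:hi])) { taken[i] <- TRUE; keep <- c(keep, i) }
    }
    keep <- sort(keep)
  }
  if (!length(keep))
    return(list(frequency_hz = 0, amplitude_pa = NA_real_, n_events = 0L,
                event_times_ms = numeric(0)))
  # the causal matched filter peaks one kernel length after event onset;
  # its response to a unit-amplitude template is a known gain, so event
  # amplitudes are read from the filtered peak (robust to sample noise)
  shape <- (kern_t / tau_ms) * exp(1 - kern_t / tau_ms)
  gain <- max(stats::filter(c(shape, rep(0, length(kern))), rev(kern),
                            sides = 1), na.rm = TRUE)
  lag <- length(kern) - 1L
  base_f <- stats::median(f)
  amps <- (f[keep] - base_f) / gain
  list(frequency_hz = length(keep) / duration_s,
       amplitude_pa = mean(amps), n_events = length(keep),
       event_times_ms = (keep - 1) * dt)
}

#' Extract all 33 variables for one cell
#'
#' Runs every protocol-specific extraction whose recording is present and
#' assembles a named feature vector; variables from absent protocols are
#' NA. Passive variables 1--4 come from the recording metadata (the
#' seal-test values carried by the simulator or supplied with real data).
#'
#' @param recordings Named list of `recording`s, any subset of
#'   `iv_steps`, `current_steps`, `cosine`, `synaptic`, `spontaneous`.
#' @return A named numeric vector of length 33 (class `cell_features`)
#'   with attributes `cell_id`, `stage_group`, `condition`.
#' @export
extract_all <- function(recordings) {
  f <- stats::setNames(rep(NA_real_, 33), FEATURE_NAMES)
  if (!length(recordings)) {
    warning("no protocols present; returning all-missing features")
    class(f) <- "cell_features"
    return(f)
  }
  p <- recordings[[1]]$params
  if (!is.null(p)) {
    f["Cm"] <- p$cm; f["Rm"] <- p$rm; f["Ra"] <- p$ra
    f["I hold"] <- (-65 - p$e_rest) / p$rm
  }
  if (!is.null(recordings$iv_steps)) {
    iv <- measure_iv_currents(recordings$iv_steps)
    fna <- fit_iv_sigmoid(iv$command_mV, iv$i_na)
    f["I Na activation"] <- fna$derived$half_activation
    f["I Na"] <- fna$derived$max_current
    fks <- fit_iv_ks(iv$command_mV, iv$i_ks)
    f["I KS activation"] <- fks$derived$activation
    f["I KS"] <- fks$derived$max_current
    fkt <- fit_iv_sigmoid(iv$command_mV, iv$i_kt)
    f["I KT activation"] <- fkt$derived$half_activation
    f["I KT"] <- fkt$derived$max_current
  }
  if (!is.null(recordings$current_steps)) {
    rec <- recordings$current_steps
    trains <- apply(rec$sweeps, 2, detect_spikes, fs = rec$fs,
                    simplify = FALSE)
    counts <- vapply(trains, function(tr) length(tr$times), numeric(1))
    fc <- fit_spikes_vs_current(rec$stimulus$current_pA, counts)
    f["I best"] <- if (fc$converged) fc$derived$argmax else NA_real_
    f["N spikes step"] <- fc$derived$max_value
    st <- step_train_features(rec, trains, i_best = f["I best"])
    f["Tail"] <- st["tail"]; f["Spike threshold"] <- st["threshold"]
    f["Spike amplitude"] <- st["amplitude"]
    f["Spike rise-time"] <- st["rise"]; f["Spike width"] <- st["width"]
    f["Spike ISI"] <- st["isi"]
    f["Spike ISI accommodation"] <- st["isi_accom"]
    f["Spike accommodation"] <- st["amp_accom"]
  }
  if (!is.null(recordings$cosine)) {
    cf <- cosine_features(recordings$cosine)
    f["N spikes cosine"] <- cf$n_spikes
    f["Spiking resonance"] <- cf$resonance
    f["Spiking resonance width"] <- cf$resonance_width
    f["Wave buildup"] <- cf$wave_buildup
    f["Wave decay"] <- cf$wave_decay
    f["Jitter"] <- cf$jitter
  }
  if (!is.null(recordings$synaptic)) {
    qc <- synaptic_charge_curve(recordings$synaptic)
    fs_ <- fit_synaptic_resonance(qc$isi_ms, qc$q_pAs)
    if (fs_$converged) {
      f["Synaptic resonance"] <- fs_$derived$argmax
      f["Synaptic resonance width"] <- fs_$derived$c
      f["Synaptic charge"] <- fs_$derived$max_value
      f["Synaptic PPF"] <- fs_$derived$ppf
    }
    f["Monosynapticity"] <- monosynapticity(recordings$synaptic)
  }
  if (!is.null(recordings$spontaneous)) {
    sp <- recordings$spontaneous
    mm <- detect_minis(sp$sweeps[, 1], fs = sp$fs,
                       duration_s = sp$stimulus$duration_s[1])
    f["Minis frequency"] <- mm$frequency_hz
    f["Minis amplitude"] <- mm$amplitude_pa
  }
  attr(f, "cell_id") <- recordings[[1]]$cell_id
  attr(f, "stage_group") <- recordings[[1]]$stage_group
  attr(f, "condition") <- recordings[[1]]$condition
  class(f) <- "cell_features"
  f
}

# cosine-protocol features: per-bout and per-wave spike bookkeeping
cosine_features <- function(rec) {
  stopifnot(rec$protocol == "cosine")
  bout_on <- rec$stimulus$bout_onsets_ms[[1]]
  periods <- rec$stimulus$periods_ms[[1]]
  bout_ms <- 200
  trains <- apply(rec$sweeps, 2, detect_spikes, fs = rec$fs,
                  simplify = FALSE)
  counts <- t(vapply(trains, function(tr)
    vapply(seq_along(bout_on), function(b)
      sum(tr$times >= bout_on[b] & tr$times < bout_on[b] + bout_ms),
      numeric(1)), numeric(length(bout_on))))
  mean_bout <- colMeans(counts)
  n_waves <- floor(bout_ms / periods)
  n_spikes_per_wave <- mean(mean_bout / n_waves)
  ft <- fit_cosine_tuning(periods, mean_bout)
  # per-wave counts in the highest-frequency (shortest-period) bout
  b_hi <- which.min(periods); Tb <- periods[b_hi]
  wv <- seq_len(n_waves[b_hi])
  per_wave <- rowMeans(vapply(trains, function(tr) {
    rel <- tr$times[tr$times >= bout_on[b_hi] &
                      tr$times < bout_on[b_hi] + bout_ms] - bout_on[b_hi]
    vapply(wv, function(x) sum(rel >= (x - 1) * Tb & rel < x * Tb),
           numeric(1))
  }, numeric(length(wv))))
  fw <- fit_wave_train(wv, per_wave)
  cos_trains <- lapply(trains, `[[`, "times")
  list(n_spikes = n_spikes_per_wave,
       resonance = if (ft$converged) ft$derived$argmax else NA_real_,
       resonance_width = if (ft$converged) ft$derived$b else NA_real_,
       wave_buildup = if (fw$converged) fw$derived$argmax else NA_real_,
       wave_decay = if (fw$converged) fw$derived$c else NA_real_,
       jitter = jitter_index(cos_trains))
}
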